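>PPI251 synthetic P-element consensus stand-in
ATCGAGGCTACAACAAGGAAGCACCTCAGCCCGGCAATGATCGATCTCATGCGACGCCATTGCTTCTGTG
CCTCAGCACGACCGTGCTGCTCAAGCGCTTCCTCGCCGGCTAGAAATGAGAGGAGTTGACCTGCGACGGC
GGACTGACCAGGATGCTCCACGTGAGGCTCTCATTCCCCGTGGTCGAAACTTGGACAGAAGGCAGAATGA
CGACCACCGACGCCATAAAGTTGCAGTGTACCTTATTAGGATCGGCAGACAGTCTCTACACTTTTATCAA
TCCACAGCGCGGTCTTCTCTCAAGTGAGCTGATTCGTTGCTGGGGTGCCACGCTCATGCGGCCACTTAGG
TCGGCCGCCGCTCGTGCGGGAGTCGCCCCAAGCTTGCATTCCGAAGGTATGGGACTCTCCAAGTCTTCTT
CCTCGGTAGGCTTCGAGAAACTGTAACAACGGCAACTTCACTGCCCGGCACGACGCTTCTAGATCTTAGC
GCAACCCATAGAACACGCATGTTCCTCGTACGTGACGTAGATAAAATGCGGATCGTTCTTTCCCAGCCCC
ACCAAGACAAGGTGTGGAATGGGGATGATACTGGTGGAGAACCGGTCAATACAGACTCTTCGCCTACGTT
CACACACGTCTTATTAGTTAAGGACACGCATTCGAAAGAGGACCATAATCTTGGCGTATTCGAGATGACC
AGCCAGAAGAAAAGTTGTCACCGCTTTTCGCATGCCAATCTGGTCTGCGGTTTAAAACACCGTCCGGGCA
TTATCTATTTTCGTGACGGACCATTTGATGATTACGAGGGCGGACAAAGATCCAACATCGTGCATGGATA
TCAGAGTAGCGGTTCACTATTATACTGCGGCTTGGGGATGCGCAGGCTTTGTTATGTACCCGTCAAACCA
GTCAGTTTCCCACTTTTCCTACTTCACATTTTAGTAGTGTTCTCTCGCCTGAGGCAGTCGATGAACTCAC
TATTGATCCGGGTGAGCAAGGATCAGGGATTGAGGAGCCGTATCTACTGCCATGGTATAGACCTCAGGAA
TCCAAACGAGGCTAGTAATGTCCAAAGTGTATCAACCAGATTCCATGGTCAGATGCGGGTACTGCGACCC
GACGTAGTTTCCCCAACGAAAAAATATAAGAGAGCAAAGCCGATAAAGTGCGCCTCGAACCCCTTTTGAA
CGACATATCTCACTGGTGCCCAAGTAATAAGCTCTACGTTTATAGTCGCCGCAGGCAATTGTCGATTTGC
CGGTGGTTGTTCGGTTTTCTCTGTTGTGGGCAATCGAACGATGATCGGGATTGGTGGTCTCGAGAACGAG
TGTATTACGTCATACTGGTCTATGAGTGTAGCGGGTCGCGGTGAAAACATGCCTATGGGAGTTTGTAAAC
GAAGTTCGCAGATTTCGTTGATTCAGCAGCTCAGTGGCGTCAGTAGTAAGCACTCCTCGCGGGCCTGGAT
CACAGTTTACGTGACAAGTGCTTTGGTGACAGCTCCACTGCTTACTACTCTAGATCCATCCCTATATCCT
TCGACGCGGGGATATAAATGGGAAAACGGAAACTCACGTGATCGGAGCCCGCAATCGATTATTCCCGACA
AGTTGTGGCGAAAGAAAGATAACAGCTTACTATCGTTCCGTCTACGGGTTAAGGGTGCTTGCAATTTGCC
AGCGAGCAGTGAATGGAAATGTGAGGGGATGATGACTCCTACCAATCGATACCTATTTTACAGACTCGTC
GGATATGATCTGGATGGAGGGAGAAGGTCCGACAGTCTACCTGGAAAAACGAGAAACGATCTGCTTCGGC
CTATTGTACGAAGACACCAAAGAGAATTAGTATCGAGAGCGGGCTGCCGCGCGAATAGGCTATTTTCGCT
GGGCAACACAGTCCGGAGACGGGCCCCACATGTACTGGCCCAACAGCTATGGTTGAGTATATGGGCATGT
CCGCGAGGAGAAAAAGCAGATTTAAAATATGGGCCAGAACGAAGACCATGTAAGCCCCGACCAAACGTTG
CGAGTGGCGTGTGACAGTACACAGAACTAAAGTTGATTAAGATTTAACTTGTTGTTTTCTATGTAGGCAT
TTATCGGTATCATTTGCCACGATACGAATGATGGGAGTCGCTGCTAGCCGATCTGCGTATTCTTCGTTTC
ATCGTGGATATGGAACTAAACCGGCTCAATTAACGTTTATAGAATTGCGCGGTATGTCCGCCGTTACCAC
ACGTGAACCTGCCACGGCTCGCGCTTGCCCACCACAAGCGTATGCTACATGCCTAACTTATCTCTGGACA
TTCCTCGTCCGGCGTCACAATTGTGTTGGAACCTATAAATGCATATCTAGGGGACCAGACTTGAGATTCC
GTGGAGTGAGAGGGATGTTGGGCAGTACGCTATACGCAGAGGGATTTGTAATCGACGACTTGTATGCACG
GTGCACCCGACTAACTGTCCTACTTACACTCGCGTGTGAGAGGAAATGCTACGACAATGAAGACTCGGGG
AGTCATCGGCAGAGCACGTCAATTGGAAGTCAGGAAGATCCATTGGCGGTTGAGAACCGCCCCAAGAACG
CCTCGCGCGCCGATTTCATTATTTTATTAAGGAGGGGTTGCCACTTTCCCACAACTCAAAAACGTCTACG
AGACCCGGCTAAGGATGTCACGTCCCGCGTCGCAGTTCTCATTTAATCTAGGGTGCCTCCGGCGAGGGAT
TGGATGATACAAATCTGTACCCCTTGATTGGCGATAACGAAGACATTCACTACTCGCCTCGGTCCGGTTA
GCAGAGACGCTAGTAGCACGGATGTCAATGTGTAGGTGTTCGGCAATAATCATGTAAAGACGAGGAACCT
CGGAACGGCTGAGGTGCTTCCTTGTTGTAGCCTCGAT
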