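   SW   perc perc perc  query      position in query              matching  repeat          position in repeat
score   div. del. ins.  sequence   begin    end          (left)   repeat    class/family    begin  end    (left)   ID
 25000   0.5  0.0  0.0  contig_1     10000    12906    (500000)  +  PPI251  DNA/P             1     2907    (0)     1
 12000   1.2  0.1  0.0  contig_1     20000    20806    (480000)  +  PPI251  DNA/P             1      807  (2100)    2
  6000   1.0  0.0  0.1  contig_1     20807    21153    (479000)  +  PPI251  DNA/P          2561     2907    (0)     2
 11000   0.8  0.0  0.0  contig_2      5000     6400    (300000)  C  PPI251  DNA/P            (0)    2907   1507     3
 10000   0.9  0.1  0.0  contig_2      6451     7856    (298000)  C  PPI251  DNA/P         (1401)    1506    101     3
  9000   2.1  0.2  0.1  contig_3      1000     3324    (100000)  +  PPI251  DNA/P             1     2325   (582)    4
  4000   5.0  0.3  0.2  contig_3      9000     9400     (92000)  +  roo     LTR/Bel           1      400  (8700)    5
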