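##gff-version 3
PPI251	pinvade	TIR_left	1	31	.	+	.	ID=TIR_left_1
PPI251	pinvade	transposase_binding_site	48	68	.	+	.	ID=transposase_binding_site_2
PPI251	pinvade	ORF0	153	442	.	+	0	ID=ORF0_3
PPI251	pinvade	DNA_binding_domain	178	360	.	+	.	ID=DNA_binding_domain_4
PPI251	pinvade	IVS1	443	501	.	+	.	ID=IVS1_5
PPI251	pinvade	ORF1	502	1167	.	+	2	ID=ORF1_6
PPI251	pinvade	IVS2	1168	1221	.	+	.	ID=IVS2_7
PPI251	pinvade	ORF2	1222	1946	.	+	2	ID=ORF2_8
PPI251	pinvade	IVS3	1947	2137	.	+	.	ID=IVS3_9
PPI251	pinvade	ORF3	2138	2706	.	+	1	ID=ORF3_10
PPI251	pinvade	transposase_binding_site	2855	2871	.	+	.	ID=transposase_binding_site_11
PPI251	pinvade	TIR_right	2877	2907	.	+	.	ID=TIR_right_12
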