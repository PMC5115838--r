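# Budding-yeast cell-cycle Boolean network (Li et al., PNAS 101:4781, 2004)
# 11 nodes, 34 signed edges; a[i,j] = effect of column node j on row node i
# -1 inhibition (incl. self-degradation loops), +1 activation
# transcription cross-validated against the model's known fixed points
Cln3	MBF	SBF	Cln1.2	Cdh1	Swi5	Cdc20.Cdc14	Clb5.6	Sic1	Clb1.2	Mcm1.SFF
-1	0	0	0	0	0	0	0	0	0	0
1	0	0	0	0	0	0	0	0	-1	0
1	0	0	0	0	0	0	0	0	-1	0
0	0	1	-1	0	0	0	0	0	0	0
0	0	0	-1	0	0	1	-1	0	-1	0
0	0	0	0	0	-1	1	0	0	-1	1
0	0	0	0	0	0	-1	0	0	1	1
0	1	0	0	0	0	-1	0	-1	0	0
0	0	0	-1	0	1	1	-1	0	-1	0
0	0	0	0	-1	0	-1	1	-1	0	1
0	0	0	0	0	0	0	1	0	1	-1
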