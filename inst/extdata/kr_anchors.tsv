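# anchor coordinates in the synthetic reference alignment
# 1-based inclusive columns; KR_C starts at the subdomain_boundary row
anchor	motif	region	start_col	end_col
motif1	1	helix_alphaB	155	155
nadph_1	NA	NADPH_site	160	160
nadph_2	NA	NADPH_site	162	162
nadph_3	NA	NADPH_site	165	165
nadph_4	NA	NADPH_site	185	185
motif2	2	LDD_region	200	202
motif3	3	helix_alphaDE	210	210
motif4	4	catalytic_K	216	216
motif5	5	position5	222	222
motif6	6	loop_alphaE_betaE	240	240
motif7	7	W_position	252	252
motif8	8	H_A2_position	258	258
motif9	9	catalytic_Y	268	268
motif10	10	P_B2_position	274	274
motif11	11	GM_prelid	300	301
motif12	12	lid_RLXR	310	313
motif13	13	lid_terminal_H	320	320
subdomain_boundary	NA	subdomain_boundary	151	151
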