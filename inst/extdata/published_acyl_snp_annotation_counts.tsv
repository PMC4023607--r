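class	Jack	FAM94-41	M23	N0304-303-3	R02-6268F	R05-4256	R05-591	R08-1450	R95-1705	total
total_in_genes	414	668	615	618	633	427	467	722	578	1186
exon	379	585	550	548	553	392	413	625	501	1012
utr	112	188	162	164	177	127	142	192	168	304
cds	267	397	388	384	376	265	271	433	333	708
nonsynonymous	111	157	156	149	155	100	99	172	146	280
synonymous	156	240	232	235	221	165	172	261	187	428
start_loss	1	0	0	0	0	0	0	0	0	1
stop_gain	1	1	1	1	0	1	1	1	1	1
stop_loss	0	0	0	0	0	0	0	0	0	0
splice_site	1	3	2	2	3	1	0	2	2	5
intron	56	114	88	96	98	58	81	126	103	174
dbsnp_overlap	355	552	524	514	545	363	393	614	489	998
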