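class	Jack	FAM94-41	M23	N0304-303-3	R02-6268F	R05-4256	R05-591	R08-1450	R95-1705	total
total_in_genes	15752	27123	24906	24909	26504	19308	21040	28962	24518	48792
dbsnp_overlap	12748	22182	20494	20380	21741	15598	17082	23828	20048	39998
exon	14271	23757	22450	22311	23202	17023	18333	25381	21544	43283
utr	4156	7226	6659	6657	6939	5082	5533	7644	6479	12748
cds	10115	16531	15791	15654	16263	11941	12800	17737	15065	30535
nonsynonymous	4759	7814	7441	7338	7769	5704	6113	8383	7271	14372
synonymous	5365	8731	8366	8329	8512	6250	6704	9372	7808	16196
start_loss	6	11	9	8	8	7	7	12	6	17
stop_gain	29	70	68	67	80	44	44	72	55	125
stop_loss	24	28	29	31	30	21	23	29	28	49
splice_site	220	369	342	323	354	245	254	357	313	606
intron	2120	4483	3469	3609	4377	3036	3575	4752	3957	7488
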