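name	value
total_snps	48792
line_specific_snps	5563
annotated_gene_models	54175
expressed_gene_models	32885
annotated_transcript_nt	69700000
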