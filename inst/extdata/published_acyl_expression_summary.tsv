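category	annotated	expressed	diff_expressed
Synthesis of fatty acids in plastids	78	70	11
Synthesis of membrane lipids in plastids	54	31	13
Synthesis of membrane lipids in endomembrane system	101	89	19
Metabolism of acyl lipids in mitochondria	33	30	5
Synthesis and storage of oil	36	31	4
Degradation of storage lipids and straight fatty acids	142	104	29
Lipid signaling	295	191	52
Fatty acid elongation and wax and cutin metabolism	84	38	11
Miscellaneous	267	185	44
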