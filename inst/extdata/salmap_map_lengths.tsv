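family	parent	segregating_snps	map_length_cM
Br5	mother	1688	2807
Br5	father	1952	2170
Br6	mother	1804	2358
Br6	father	1895	1426
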