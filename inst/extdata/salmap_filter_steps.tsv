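step	snps_eliminated	individuals_eliminated
missing_genotypes_snps	14778	0
missing_genotypes_individuals	0	15
excess_heterozygosity_psvs	4895	0
mendelian_errors_snps	485	0
mendelian_errors_individuals	0	4
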