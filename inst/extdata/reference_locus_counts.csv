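quantity,count
snps_total,1601
provenance_outliers,27
hatchery_outliers,15
neutral_loci,1559
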