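# Synthetic per-allele SNP -> DMA% weights (percentage points per
# high-efficiency allele copy) for the three arsenic-metabolism instrument
# SNPs. PROVENANCE: these are NOT published estimates. The numeric values in
# the source publications' weight table were not available when this file was
# assembled, so the betas/SEs here are synthetic plausible values calibrated
# to cohort-scale facts (maximum weighted score 2*(3.1+1.2+4.4) = 17.4,
# matching the reported median genetically predicted DMA%; rs11191527 the
# weakest instrument; low-efficiency alleles rare at rs9527 and rs61735836).
# Replace beta_dma/se with published per-allele estimates before any use on
# real data. version: 0.1.0-synthetic
snp_id	effect_allele	other_allele	beta_dma	se	effect_allele_freq
rs9527	G	A	3.1	0.55	0.90
rs11191527	C	T	1.2	0.45	0.88
rs61735836	G	A	4.4	0.80	0.95
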