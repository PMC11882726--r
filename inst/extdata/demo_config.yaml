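# Packaged demo: a scaled-down synthetic run of the full pipeline.
# The generator defaults (nine cohorts, published sample sizes, accepted
# bifactor loading structure) are used with a reduced SNP count so the demo
# finishes in about a minute; the per-SNP GWAS stage is capped at 40 SNPs.
mode: synthetic
generator: ~        # defaults; m_snps overridden below via R when desired
ldsc:
  n_blocks: 100
  h2_z_threshold: 1.645
  collinearity_r: 0.9
models: zoo
gwas:
  model: bifactor_wm_sub_id
  zdiff: 1.0
  qsnp_alpha: 5.0e-8
  max_snps: 40
postgwas:
  p_sig: 5.0e-8
  r2_indep: 0.6
  r2_lead: 0.1
  merge_window: 250000
  r2_novel: 0.6
seed: 1
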