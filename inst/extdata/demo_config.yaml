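# End-to-end demonstration: simulate a lamb population with genetic,
# microbial, cohort and lot structure, then run profiling, relationship
# matrices, phenotype preparation, REML fits, forward-prediction BLUP and
# the bivariate proxy-trait analysis.
seed: 77
simulate:
  n_animals: 600
  n_snps: 800
  n_tags: 800
  n_flocks: 3
  n_years: 2
  sigma2_g: 0.25
  sigma2_m: 0.45
  sigma2_e: 0.30
  rho_gm: 0.7
  depth_log_mean: 10.309     # log(3e4): scaled-down sequencing depth
  depth_log_sd: 0.2
qc:
  min_reads: 10000           # matches the scaled-down depths
scheme: FP
overall_mean: 7.5
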