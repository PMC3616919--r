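# Demo configuration for run_pipeline(): a small F1-hybrid simulation with
# five zygotically activated genes among 30, SNPs every ~200 bp, 36-nt
# single-end reads at 0.5% per-base substitution error.
seed: 1
stages: [c3_6, c7, c8]
reference:
  n_genes: 30
  min_length: 500
  max_length: 3000
  x_fraction: 0.1
snp:
  mean_spacing: 200
reads:
  n_per_stage: 20000
  read_length: 36
  error_rate: 0.005
expression:
  n_zygotic: 5
  maternal_copies: 100
  zygotic_rate: 1
  onset_cycles: [1, 8]
classifier:
  error_ceiling: 0.01
  min_paternal_fraction: 0.10
  alpha: 0.05
  min_informative_reads: 100
  low_information_threshold: 5
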