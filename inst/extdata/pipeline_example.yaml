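# Example run_pipeline() configuration: simulate a three-line design and run
# every analysis stage. Replace the `simulate` block with `vcf:`/`line_map:`
# paths to analyse real data.
seed: 1
out_dir: pipeline_out
reference_line: FZTDU
simulate:
  chrom_lengths: {chr1: 20000000}
  n_sites: 8000
  n_generations: 188
  lines:
    line: [FZTDU, DUK, DU6]
    n_pairs: [200, 60, 80]
    selected: [false, true, true]
    prop_selected: [1.0, 0.5, 0.65]
    bottleneck_gen: [160, 160, 160]
    bottleneck_pairs: [55, 19, 7]
filter:
  dp_min: 4
  dp_sd_mult: 3
  gq_min: 20
  min_support: 15
  overrides: {DU6: 12}
windows:
  size: 50000
  step: 25000
  min_snps: 10
rdd:
  top_pct: 95
  bottom_pct: 10
ld:
  min_dist: 100000
  max_dist: 5000000
  bin_width: 100000
roh:
  az_het_rate: 0.001
  t_hw_az: 0.01
  t_az_hw: 0.05
  rec_rate_cM_per_Mb: 0.51
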