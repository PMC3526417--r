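# Demo pipeline run on a small simulated study (two genotypes, pooled
# control + 5 cold timepoints, 3 replicates, planted truth classes).
simulate:
  seed: 42
  n_genes: 600
  noise_sd_log2: 0.25
  effect_log2: 3.0
  planted_counts:
    common_induced: 40
    common_repressed: 12
    recurrent_specific_induced: 12
    recurrent_specific_repressed: 8
    il_specific_induced: 12
    il_specific_repressed: 8
    constitutive_up_il: 10
    constitutive_down_il: 6
    down_then_up: 8
    up_then_down_il: 8
  n_dreb1c_followers: 10
  n_segments: 17
  n_qtls: 31
detect:
  threshold: 100
deg:
  n_permutations: 1000
  fc_threshold: 5.0
  p_threshold: 0.05
  seed: 42
cluster:
  k: 6
coloc:
  flank: 0
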