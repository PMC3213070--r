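# Default configuration of the reference-gene screening pipeline.
# Every value shown here is also the package default: a bare
# `run_screen_config(seed = ...)` is equivalent to running this file.
# Set `input: path/to/ct.tsv` to analyze a measured Ct table instead of
# simulating one.

design:
  time_points_h: [0, 1, 4, 9, 18, 27, 50]
  replicates: [3, 4, 4, 3, 3, 3, 3]

genes:
  n_genes: 96
  stable_noise_sd: 0.25        # cycles; the 3 planted reference candidates
  null_noise_range: [0.7, 1.5] # cycles; biological noise of null genes
  spike_amplitude: 7.70        # log2; 2^7.70 ~ 208-fold burst at 4 h
  drift_amplitude: 1.49        # log2; 2^1.49 ~ 2.8-fold drift peak at 18 h

simulate:
  array_effect_sd: 0           # shared per-array Ct shift (cycles)
  planted_missing_genes: 8     # null genes given unexplained missing cells
  planted_missing_cells: 2

preprocess:
  max_unexplained: 2           # "two or more" technical missing -> removed
  qc_genes: [batch_1]          # vet against the per-sample mean Ct
  qc_r_min: 0.5

schemes:
  - mode: none
  - mode: single
    references: [drift_1]      # the unstable pseudo-reference
  - mode: single
    references: [stable_1]     # a validated stable reference

thresholds:
  fc_threshold: 1.5
  alpha: 0.05
  p_floor: 0.05                # screen keeps genes with adjusted p >= floor
  missing_tolerance: 2         # geNorm exclusion for imputed/assigned cells

focal_gene: stable_3           # trajectory compared across all schemes
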