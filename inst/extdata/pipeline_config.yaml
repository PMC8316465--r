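# markwise pipeline configuration template
#
# Either a `simulate:` block (keys = arguments of simulation_config()) or a
# `fixture_dir:` pointing at a directory written by write_fixture().
# Unknown keys are rejected at validation time.

seed: 1
output_dir: markwise_run

simulate:
  n_genes: 400             # genes on the toy chromosome
  genome_length: 4.0e6     # bp; ~4 kb per gene plus a 15% gene desert needed
  n_typical_enhancers: 20  # isolated enhancer peaks for the ranking curve
  # n_control: 4           # ChIP/RNA replicates per condition
  # n_case: 5
  # nb_mean: 500           # NB mean of expression counts
  # nb_dispersion: 0.05    # NB dispersion (variance = mu + a mu^2)
  # planted_lfc: 3         # |log2FC| of planted DE genes
  # congruent_fraction: 0.5

thresholds:
  fdr_max: 0.01            # DE significance (BH FDR)
  lfc_min: 1.5             # |log2 fold change| cutoff (log2 scale)
  occupancy_fdr_max: 0.05  # per-mark occupancy significance
  min_relative_score: 0.95 # motif relative-score threshold
  stitch_distance: 12500   # ROSE stitching gap (bp)
  tss_exclusion: 2500      # promoter half-width excluded before stitching (bp)
  z_min: 2.0               # 4C residual z threshold
  min_run: 3               # consecutive 4C fragments per call
  n_perm: 200              # GSEA permutations
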