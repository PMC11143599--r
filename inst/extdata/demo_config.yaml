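# Annotated demo configuration for `run_pipeline()`.
# Every key is optional; omitted keys take the package defaults shown in
# `validate_config()`. The demo runs entirely on simulated data.

seed: 1          # global seed; all stage seeds are derived from it
log: info        # "info" or "quiet"

simulate:
  enabled: true        # generate the toy study instead of reading inputs
  n_chroms: 2          # toy genome: 2 x 2 Mb
  chrom_length: 2000000
  n_genes: 60
  n_enhancers: 120     # planted eRNA sources (10% strand-imbalanced)
  n_decoys: 80         # accessibility peaks without transcription
  n_replicates: 3      # nascent-coverage samples per condition
  depth: 1
  n_cells_per_cluster: 200
  fragments_per_cell: 2000

enhancers:
  flank: 500       # candidate = peak midpoint +/- flank (1 kb regions)
  max_ratio: 10    # ten-fold strand-balance rule
  min_cpm: 1       # eRNA evidence cutoff (or histone-peak overlap)
  cluster_gap: 500 # clustered-candidate resolution distance

quantify:
  per_position_cap: 3   # per-base signal cap for gene quantification

diff:
  count_cutoff: 5   # enhancer expression cutoff (raw counts)
  min_samples: 2
  fdr: 0.1          # QL F-test threshold for enhancers
  lrt_fdr: 0.001    # any-change LRT threshold for genes
  kmeans_k: 6

fragqc:
  tss_flank: 2000

motifs:
  B: 50             # background sets per motif
  lfc_threshold: 1.5
  fdr: 1.0e-4

aggregate:
  flank: 1000
  bin_size: 25
  min_fc: 0.1
  fdr: 0.1
  top_n: 200
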