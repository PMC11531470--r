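Plain-text fixtures.

deltact_pairs_all_cohort.tsv
deltact_pairs_healthy_controls.tsv
  Published pairwise delta-Ct summary tables (mean and standard deviation
  of per-sample Ct differences for every ordered pair of six candidate
  miRNA references) from a B-cell precursor ALL xenograft benchmarking
  study: one table for the leukemia cohort (cell lines plus PDX samples),
  one for healthy-control PBMCs. Columns: gene_a, gene_b, mean_delta,
  sd_delta. Feed to deltact_scores() to recompute each gene's mean-STD
  stability score from the printed pairwise SDs.
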