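# Small in-code fixtures shared across test files.

# a tiny hand-built study: 2 strains x (subset of) time points x reps
tiny_study <- function(values, strains, timepoints, replicates,
                       genes = NULL) {
  mat <- as.matrix(values)
  if (!is.null(genes)) rownames(mat) <- genes
  samples <- tibble::tibble(
    sample_id = paste(strains, timepoints, replicates, sep = "|"),
    strain = strains, timepoint = timepoints, replicate = replicates
  )
  colnames(mat) <- samples$sample_id
  expression_study(mat, samples)
}

# default-design synthetic study, small gene count, ready for the pipeline
small_pipeline_study <- function(n_genes = 120, seed = 1, ...) {
  generate_expression_study(n_genes = n_genes, seed = seed, ...) |>
    normalize_common_mean() |>
    filter_low()
}

# per-replicate population summaries drawn directly at the statistic level
# (used by the shift-test power simulation)
replicate_stats <- function(means, cv, n = 4) {
  tibble::tibble(
    replicate = seq_len(n),
    mean_bias = rnorm(n, means, cv * means),
    sd_bias = abs(rnorm(n, means * 0.3, cv * means * 0.3)),
    mean_fsc = 1, sd_fsc = 1
  )
}
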