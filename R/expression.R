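#' Construct an expression study (log-scale matrix plus sample metadata)
#'
#' The working container for the expression pipeline: a genes x samples
#' matrix of log-scale values, a sample-metadata table, and a per-gene
#' `retained` flag set by [filter_low()]. All operations are affine on the
#' log scale, so the container is agnostic to the logarithm base of the
#' deposited values.
#'
#' @param matrix Numeric genes x samples matrix with gene ids as row names.
#' @param samples Data frame with columns `sample_id`, `strain`,
#'   `timepoint` (one of [timepoint_levels()]), `replicate`; rows must match
#'   the matrix columns (by `sample_id` when column names are present).
#' @return An object of class `expression_study` with fields `matrix`,
#'   `samples`, `retained` (named logical), `normalized`, `averaged`.
#' @export
expression_study <- function(matrix, samples) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix (genes x samples).")
  }
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- sprintf("g%05d", seq_len(nrow(matrix)))
  }
  samples <- as_tibble(samples)
  need <- c("sample_id", "strain", "timepoint", "replicate")
  if (!all(need %in% names(samples))) {
    abort("`samples` must have columns sample_id, strain, timepoint, replicate.")
  }
  if (nrow(samples) != ncol(matrix)) {
    abort("`samples` must have one row per matrix column.")
  }
  bad <- setdiff(unique(samples$timepoint), timepoint_levels())
  if (length(bad)) {
    abort(sprintf("unknown timepoint label(s): %s", paste(bad, collapse = ", ")))
  }
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- samples$sample_id
  } else if (!identical(colnames(matrix), samples$sample_id)) {
    matrix <- matrix[, samples$sample_id, drop = FALSE]
  }
  structure(
    list(matrix = matrix, samples = samples,
         retained = setNames(rep(TRUE, nrow(matrix)), rownames(matrix)),
         normalized = FALSE, averaged = FALSE),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %d genes (%d retained) x %d samples; %s%s\n",
    nrow(x$matrix), sum(x$retained), ncol(x$matrix),
    if (x$normalized) "normalized" else "not normalized",
    if (x$averaged) ", replicate-averaged" else ""
  ))
  invisible(x)
}

#' Matrix of retained genes only
#' @param study An [expression_study()].
#' @return Numeric matrix restricted to retained genes.
#' @export
retained_matrix <- function(study) {
  study$matrix[study$retained, , drop = FALSE]
}

#' Normalize every sample to a common mean on the log scale
#'
#' Each sample column is shifted additively (equivalently, scaled on the raw
#' intensity scale) so that its mean over retained genes equals
#' `target_mean`; by default the grand mean of the input columns, so the
#' overall level is preserved. Idempotent.
#'
#' @param study An [expression_study()]; all values must be finite.
#' @param target_mean Common column mean after normalization (log units).
#' @return The normalized study (`normalized = TRUE`).
#' @export
#' @examples
#' m <- matrix(c(0, 2, 2, 4), 2, dimnames = list(c("a", "b"), NULL))
#' s <- expression_study(m, tibble::tibble(
#'   sample_id = c("s1", "s2"), strain = "x",
#'   timepoint = "+His", replicate = 1:2))
#' colMeans(normalize_common_mean(s)$matrix)  # both 2
normalize_common_mean <- function(study, target_mean = NULL) {
  if (!all(is.finite(study$matrix))) {
    abort("expression matrix contains non-finite values; normalization refused.")
  }
  mns <- colMeans(study$matrix[study$retained, , drop = FALSE])
  target <- target_mean %||% mean(mns)
  study$matrix <- sweep(study$matrix, 2, mns - target, "-")
  study$normalized <- TRUE
  study$target_mean <- target
  study
}

#' Filter genes with low normalized values
#'
#' Small log-scale values are dominated by background noise, so genes that
#' fall below `threshold` are excluded from all downstream analyses (the
#' matrix keeps every gene; only the `retained` flags change). The quantifier
#' decides when a gene is dropped: `"any"` (default) drops a gene if any
#' sample value is below the threshold -- downstream analyses need a
#' complete genes x conditions matrix -- `"all"` requires every value below,
#' `"mean"` tests the gene's mean.
#'
#' @param study A normalized [expression_study()].
#' @param threshold Log-units cutoff (default -1.5).
#' @param rule Quantifier, one of `"any"`, `"all"`, `"mean"`.
#' @return The study with updated `retained` flags.
#' @export
filter_low <- function(study, threshold = -1.5, rule = c("any", "all", "mean")) {
  rule <- match.arg(rule)
  if (!study$normalized) {
    abort("`filter_low()` expects a normalized study; run normalize_common_mean() first.")
  }
  m <- study$matrix
  low <- m < threshold
  drop <- switch(rule,
    any = rowSums(low) > 0,
    all = rowSums(low) == ncol(m),
    mean = rowMeans(m) < threshold
  )
  study$retained <- study$retained & !drop
  if (!any(study$retained)) {
    abort("filtering removed every gene; lower the threshold.")
  }
  study
}

#' Average replicates within each strain and time point
#'
#' Collapses replicate columns by the arithmetic mean on the log scale,
#' leaving one column per strain x time point.
#'
#' @param study An [expression_study()].
#' @param expected Optional data frame with columns `strain`, `timepoint`
#'   naming the groups the design requires; an absent group is an error
#'   (named in the message).
#' @return A replicate-averaged study (`averaged = TRUE`, `replicate = NA`).
#' @export
average_replicates <- function(study, expected = NULL) {
  key <- paste(study$samples$strain, study$samples$timepoint, sep = "|")
  groups <- unique(key)
  if (!is.null(expected)) {
    want <- paste(expected$strain, expected$timepoint, sep = "|")
    miss <- setdiff(want, groups)
    if (length(miss)) {
      abort(sprintf("missing strain x time point group(s): %s",
                    paste(miss, collapse = ", ")))
    }
  }
  mat <- vapply(groups, function(g) {
    rowMeans(study$matrix[, key == g, drop = FALSE])
  }, numeric(nrow(study$matrix)))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1L)  # single-gene study
  rownames(mat) <- rownames(study$matrix)
  colnames(mat) <- groups
  first <- match(groups, key)
  samples <- tibble(
    sample_id = groups,
    strain = study$samples$strain[first],
    timepoint = study$samples$timepoint[first],
    replicate = NA_integer_
  )
  out <- expression_study(mat, samples)
  out$retained <- study$retained
  out$normalized <- study$normalized
  out$target_mean <- study$target_mean
  out$averaged <- TRUE
  attr(out, "truth") <- attr(study, "truth")
  out
}

#' @export
tidy.expression_study <- function(x, retained_only = TRUE, ...) {
  m <- if (retained_only) retained_matrix(x) else x$matrix
  as_tibble(m, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "value") |>
    left_join(x$samples, by = "sample_id")
}
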