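#' Simulate annotation gene sets, optionally enriched in a target list
#'
#' Builds a [gene_set_collection()] of random sets over a gene universe,
#' cycling the three annotation kinds used downstream (transcription-factor
#' regulons, functional categories, GO-like terms). Planted sets draw a
#' stated fraction of their members from a supplied target gene list (for
#' example a trajectory-loading tail), so enrichment calls can be validated
#' against ground truth.
#'
#' @param n_genes Universe size; gene ids are `g00001 ...` matching
#'   [generate_expression_study()].
#' @param set_sizes Integer vector of random-set sizes (each <= `n_genes`).
#' @param planted Optional data frame with columns `name`, `size`,
#'   `fraction` (of members drawn from `target`, in `[0, 1]`) and optionally
#'   `kind`.
#' @param target Character vector of target genes (required when `planted`
#'   is given).
#' @param kinds Kinds assigned to the random sets, recycled.
#' @param seed Integer seed.
#' @return A `gene_set_collection`; planted set names are recorded in the
#'   `"planted"` attribute.
#' @export
#' @examples
#' gs <- generate_gene_sets(500, set_sizes = rep(30, 5), seed = 1)
#' lengths(gs$sets)
generate_gene_sets <- function(n_genes, set_sizes, planted = NULL,
                               target = NULL,
                               kinds = c("regulon", "category", "go"),
                               seed = 1) {
  n_genes <- stop_if_not_count(n_genes, "n_genes", min = 1L)
  if (any(set_sizes > n_genes)) abort("`set_sizes` must all be <= `n_genes`.")
  withr::local_seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))

  sets <- list()
  kind <- character()
  if (length(set_sizes)) {
    for (i in seq_along(set_sizes)) {
      nm <- sprintf("random_set_%02d", i)
      sets[[nm]] <- sample(genes, set_sizes[i])
      kind[nm] <- kinds[(i - 1L) %% length(kinds) + 1L]
    }
  }
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    if (!all(c("name", "size", "fraction") %in% names(planted))) {
      abort("`planted` needs columns name, size, fraction.")
    }
    if (any(planted$fraction < 0 | planted$fraction > 1)) {
      abort("planted fractions must lie in [0, 1].")
    }
    if (is.null(target) || !length(target)) {
      abort("`target` genes are required when planting enriched sets.")
    }
    if (!all(target %in% genes)) abort("`target` genes must be in the universe.")
    for (i in seq_len(nrow(planted))) {
      p <- planted[i, ]
      n_in <- min(round(p$fraction * p$size), length(target))
      inside <- sample(target, n_in)
      outside <- sample(setdiff(genes, target), p$size - n_in)
      sets[[p$name]] <- c(inside, outside)
      kind[p$name] <- if ("kind" %in% names(planted)) p$kind else "category"
    }
  }
  out <- gene_set_collection(sets, kind)
  attr(out, "planted") <- if (is.null(planted)) character() else planted$name
  out
}
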