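#' A collection of annotation gene sets
#'
#' Named gene sets with a kind label each: `"regulon"` (genes controlled by
#' one transcription factor), `"category"` (functional classification), or
#' `"go"` (GO-like biological-process terms). Size filters differ by kind
#' (see [filter_sets()]).
#'
#' @param sets Named list of character vectors (gene ids).
#' @param kind Character vector of kinds, one per set (recycled if length
#'   1); values in `regulon`, `category`, `go`.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, kind = "category") {
  if (!is.list(sets) || (length(sets) && is.null(names(sets)))) {
    abort("`sets` must be a named list of gene-id vectors.")
  }
  if (length(kind) == 1L) kind <- rep(kind, length(sets))
  if (length(kind) != length(sets)) {
    abort("`kind` must have one entry per set.")
  }
  bad <- setdiff(unique(kind), c("regulon", "category", "go"))
  if (length(bad) && length(sets)) {
    abort(sprintf("unknown set kind(s): %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(sets = sets, kind = setNames(as.character(kind), names(sets)),
         filtered = FALSE),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets (%s)%s\n",
              length(x$sets),
              paste(names(table(x$kind)), table(x$kind), sep = ": ",
                    collapse = ", "),
              if (x$filtered) ", size-filtered" else ""))
  invisible(x)
}

#' Restrict gene sets to a universe and apply kind-specific size filters
#'
#' Set members are first intersected with the retained-gene universe, then
#' size thresholds are applied: regulons and functional categories must have
#' more than 15 members (strictly, so a 15-gene regulon is excluded);
#' GO-like terms must have between 15 and 1000 members inclusive (terms with
#' fewer than 15 or more than 1000 genes are excluded).
#'
#' @param collection A [gene_set_collection()].
#' @param universe Non-empty character vector of retained gene ids.
#' @param min_regulon Minimum exclusive size for regulon/category sets.
#' @param go_range Inclusive `c(min, max)` size range for GO-like sets.
#' @return The filtered collection (`filtered = TRUE`).
#' @export
filter_sets <- function(collection, universe, min_regulon = 15,
                        go_range = c(15, 1000)) {
  if (!length(universe)) abort("`universe` must be non-empty.")
  sets <- lapply(collection$sets, intersect, universe)
  keep <- vapply(names(sets), function(nm) {
    sz <- length(sets[[nm]])
    if (collection$kind[[nm]] == "go") {
      sz >= go_range[1] && sz <= go_range[2]
    } else {
      sz > min_regulon
    }
  }, logical(1))
  out <- gene_set_collection(sets[keep], collection$kind[keep])
  out$filtered <- TRUE
  attr(out, "planted") <- intersect(attr(collection, "planted"), names(out$sets))
  out
}

#' Binomial-test enrichment of gene sets in a selection
#'
#' For each set, with `k` selected genes in the set, `n` selected genes, `m`
#' set members and `N` universe genes, the raw p-value is the upper binomial
#' tail `P(X >= k)` with `X ~ Binomial(n, m/N)` -- the chance of drawing at
#' least as many hits if selection were independent sampling at the set's
#' background frequency. Bonferroni correction multiplies by the number of
#' sets tested within the same annotation kind (`family = "kind"`, default)
#' or across all sets (`family = "all"`); significance is declared at
#' `p_adj < alpha` (default 0.001). A hypergeometric tail (sampling without
#' replacement) is available for comparison.
#'
#' @param selection Character vector of selected genes, a subset of
#'   `universe`.
#' @param sets A filtered [gene_set_collection()].
#' @param universe Retained-gene universe.
#' @param alpha Significance level on the corrected p-value.
#' @param model `"binomial"` (default) or `"hypergeometric"`.
#' @param family Bonferroni family: `"kind"` or `"all"`.
#' @return Tibble of class `enrichment_report`: `set`, `kind`, `k`, `n`,
#'   `m`, `N`, `p_raw`, `p_adj`, `significant`.
#' @export
#' @examples
#' gs <- gene_set_collection(list(A = c("g1", "g2", "g3")), "category")
#' binomial_enrichment(c("g1", "g2"), gs, paste0("g", 1:10))
binomial_enrichment <- function(selection, sets, universe, alpha = 0.001,
                                model = c("binomial", "hypergeometric"),
                                family = c("kind", "all")) {
  model <- match.arg(model)
  family <- match.arg(family)
  if (!length(universe)) abort("`universe` must be non-empty.")
  outside <- setdiff(selection, universe)
  if (length(outside)) {
    abort(sprintf("selection gene(s) outside the universe: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  N <- length(universe)
  n <- length(selection)
  nms <- names(sets$sets)
  members <- lapply(sets$sets, intersect, universe)
  m <- lengths(members)
  k <- vapply(members, function(s) sum(selection %in% s), integer(1))
  p_raw <- if (model == "binomial") {
    pbinom(k - 1, n, m / N, lower.tail = FALSE)
  } else {
    stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  }
  tab <- tibble(set = nms, kind = unname(sets$kind[nms]),
                k = unname(k), n = n, m = unname(m), N = N,
                p_raw = unname(p_raw))
  if (nrow(tab)) {
    n_tests <- if (family == "kind") {
      table(tab$kind)[tab$kind]
    } else {
      nrow(tab)
    }
    tab$p_adj <- pmin(1, tab$p_raw * as.numeric(n_tests))
    tab$significant <- tab$p_adj < alpha
  } else {
    tab <- tibble(set = character(), kind = character(), k = integer(),
                  n = integer(), m = integer(), N = integer(),
                  p_raw = numeric(), p_adj = numeric(),
                  significant = logical())
  }
  class(tab) <- c("enrichment_report", class(tab))
  attr(tab, "alpha") <- alpha
  attr(tab, "model") <- model
  tab
}

#' Enrichment of both trajectory-loading tails
#'
#' Runs [binomial_enrichment()] independently for the positive and negative
#' loading tails (which must be disjoint), each with its own Bonferroni
#' family.
#'
#' @param tails List with elements `positive` and `negative` (gene-id
#'   vectors), e.g. from [loading_tails()].
#' @inheritParams binomial_enrichment
#' @return Named list of two `enrichment_report`s (`positive`, `negative`).
#' @export
enrich_tails <- function(tails, sets, universe, alpha = 0.001,
                         model = c("binomial", "hypergeometric"),
                         family = c("kind", "all")) {
  if (!all(c("positive", "negative") %in% names(tails))) {
    abort("`tails` must have elements `positive` and `negative`.")
  }
  if (length(intersect(tails$positive, tails$negative))) {
    abort("tails overlap; they must be disjoint gene lists.")
  }
  lapply(tails[c("positive", "negative")], binomial_enrichment,
         sets = sets, universe = universe, alpha = alpha,
         model = match.arg(model), family = match.arg(family))
}

#' @export
tidy.enrichment_report <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.enrichment_report <- function(x, ...) {
  tibble(n_sets = nrow(x), n_significant = sum(x$significant),
         alpha = attr(x, "alpha"), model = attr(x, "model"))
}
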