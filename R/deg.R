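#' Replicate-level starvation-versus-rich contrasts for one strain
#'
#' Builds the genes x comparisons matrix of log fold changes that feeds the
#' rank-product test: each comparison column is one starved replicate minus
#' one rich-medium (`+His`) replicate, over retained genes. By default all
#' starved/rich replicate pairings within the strain are used (the replicates
#' are biological and unpaired); `pairing = "matched"` pairs replicate 1 with
#' replicate 1 and so on.
#'
#' @param study A normalized, filtered (not replicate-averaged)
#'   [expression_study()].
#' @param strain Strain label.
#' @param state Starvation time point to contrast (default `-His >10 h`).
#' @param pairing `"all_pairs"` or `"matched"`.
#' @return Numeric genes x comparisons matrix of log fold changes.
#' @export
strain_contrasts <- function(study, strain, state = "-His >10 h",
                             pairing = c("all_pairs", "matched")) {
  pairing <- match.arg(pairing)
  if (study$averaged) abort("`strain_contrasts()` needs replicate-level data.")
  smp <- study$samples
  plus <- which(smp$strain == strain & smp$timepoint == TP_PLUS)
  minus <- which(smp$strain == strain & smp$timepoint == state)
  if (!length(plus) || !length(minus)) {
    abort(sprintf("strain %s lacks samples for +His or '%s'.", strain, state))
  }
  m <- retained_matrix(study)
  if (pairing == "matched") {
    if (length(plus) != length(minus)) {
      abort("matched pairing needs equal replicate counts.")
    }
    cols <- lapply(seq_along(plus), function(i) m[, minus[i]] - m[, plus[i]])
  } else {
    cols <- list()
    for (j in minus) for (i in plus) {
      cols[[length(cols) + 1L]] <- m[, j] - m[, i]
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("cmp", seq_len(ncol(out)))
  out
}

rank_one_direction <- function(changes, direction) {
  # rank 1 = most changed in the stated direction; ties get average ranks
  sgn <- if (direction == "up") -1 else 1
  apply(changes, 2, function(x) rank(sgn * x, ties.method = "average"))
}

#' Rank product of fold-change ranks across comparisons
#'
#' Within each comparison, genes are ranked by log fold change (rank 1 = the
#' most changed in `direction`; ties receive average ranks). The rank
#' product of a gene is the geometric mean of its ranks across comparisons;
#' a small value flags consistently strong change. The statistic depends only
#' on within-comparison orderings, so it is invariant under any monotone
#' transform of the fold changes.
#'
#' @param changes Numeric genes x comparisons matrix of log fold changes
#'   (at least one column, no missing values).
#' @param direction `"up"` or `"down"`.
#' @return Tibble with columns `gene` and `rp` (in `[1, n_genes]`).
#' @export
#' @examples
#' m <- cbind(c(3, 1, 0), c(2, 3, 0))
#' rank_product(m, "up")  # gene 2 ranked 2 and 1 -> rp = sqrt(2)
rank_product <- function(changes, direction = c("up", "down")) {
  direction <- match.arg(direction)
  changes <- as.matrix(changes)
  if (ncol(changes) < 1L) abort("`changes` needs at least one comparison.")
  if (any(is.na(changes))) abort("`changes` contains missing values.")
  r <- rank_one_direction(changes, direction)
  rp <- exp(rowMeans(log(r)))
  genes <- rownames(changes) %||% as.character(seq_len(nrow(changes)))
  tibble(gene = genes, rp = unname(rp))
}

# null rank products for B within-column permutations, as an n x B matrix.
# Products (not geometric means) are used throughout: products of average
# ranks are exact in doubles, so ties between null and observed values
# count correctly.
null_products <- function(ranks, B) {
  n <- nrow(ranks)
  P <- matrix(1, n, B)
  for (k in seq_len(ncol(ranks))) {
    idx <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
    P <- P * matrix(ranks[, k][idx], n, B)
  }
  P
}

#' Rank-product test with permutation-estimated false-positive proportion
#'
#' Runs [rank_product()] in both directions and estimates, for every gene,
#' the proportion of false positives (pfp, the rank-product analogue of the
#' FDR) by permutation: in each permutation the values within each
#' comparison are independently shuffled across genes, the null rank
#' products are pooled, and
#' `pfp(g) = E(g) / rank(g)` where `E(g)` is the average number of null rank
#' products at or below gene `g`'s observed value and `rank(g)` its position
#' among observed values. Genes with `pfp < fdr` are called differentially
#' expressed; in the rare event that a gene would be called in both
#' directions only the smaller-pfp direction is kept, so calls are disjoint.
#'
#' `method = "exact"` replaces the permutations by exhaustive enumeration of
#' all `n_genes^n_comparisons` rank combinations (per-gene ranks are
#' marginally uniform under within-comparison permutation), giving the exact
#' expected-false-positive curve for tiny instances.
#'
#' @inheritParams rank_product
#' @param n_permutations Number of permutations (>= 1; >= 100 recommended
#'   for reported results).
#' @param seed Integer seed; identical seeds give identical pfp values.
#' @param fdr Call threshold on pfp.
#' @param method `"permutation"` (default) or `"exact"`.
#' @return A `rank_product_result`: list with `table` (tibble: `gene`,
#'   `direction`, `rp`, `e_value`, `pfp`, `call`), `n_permutations`, `seed`,
#'   `fdr`, `method`. [tidy()] returns the table, [glance()] the call
#'   counts.
#' @export
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(30), 10, 3)
#' m[1, ] <- m[1, ] + 5
#' res <- rank_product_pfp(m, n_permutations = 200, seed = 7)
#' dplyr::filter(tidy(res), call)
rank_product_pfp <- function(changes, n_permutations = 1000, seed = 1,
                             fdr = 0.05, method = c("permutation", "exact")) {
  method <- match.arg(method)
  changes <- as.matrix(changes)
  n_permutations <- stop_if_not_count(n_permutations, "n_permutations", min = 1L)
  if (any(is.na(changes))) abort("`changes` contains missing values.")
  n <- nrow(changes)
  K <- ncol(changes)
  genes <- rownames(changes) %||% as.character(seq_len(n))

  per_direction <- function(direction) {
    ranks <- rank_one_direction(changes, direction)
    obs_prod <- apply(ranks, 1, prod)
    obs <- obs_prod^(1 / K)
    if (method == "exact") {
      e_val <- exact_expected_fp(n, K, obs_prod)
    } else {
      sorted_null <- sort(null_products(ranks, n_permutations))
      e_val <- findInterval(obs_prod * (1 + 1e-12), sorted_null) / n_permutations
    }
    pos <- rank(obs_prod, ties.method = "average")
    tibble(gene = genes, direction = direction, rp = obs,
           e_value = e_val, pfp = e_val / pos, call = e_val / pos < fdr)
  }
  withr::local_seed(seed)
  tab <- bind_rows(per_direction("up"), per_direction("down"))
  both <- tab |>
    filter(.data$call) |>
    dplyr::count(.data$gene) |>
    filter(.data$n > 1)
  if (nrow(both)) {
    for (g in both$gene) {
      rows <- which(tab$gene == g & tab$call)
      keep <- rows[which.min(tab$pfp[rows])]
      tab$call[setdiff(rows, keep)] <- FALSE
    }
  }
  structure(
    list(table = tab, n_permutations = if (method == "exact") NA_integer_ else n_permutations,
         seed = seed, fdr = fdr, method = method),
    class = "rank_product_result"
  )
}

# exact E[# null rank products <= observed]: under independent
# within-comparison permutations each gene's rank vector is marginally
# uniform on {1..n}^K, so by linearity the expected count is
# n * P(prod(U) <= observed product); enumerated over all n^K tuples
# (tiny instances only). `obs_prod` are observed rank products.
exact_expected_fp <- function(n, K, obs_prod) {
  if (n^K > 2e6) abort("exact enumeration is limited to n_genes^K <= 2e6.")
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), K)))
  prods <- apply(grid, 1, prod)
  vapply(obs_prod, function(r) n * mean(prods <= r * (1 + 1e-12)), numeric(1))
}

#' @export
print.rank_product_result <- function(x, ...) {
  cat(sprintf(
    "<rank_product_result> %d genes, %s; %d up / %d down calls at pfp < %g\n",
    length(unique(x$table$gene)),
    if (x$method == "exact") "exact enumeration"
    else sprintf("%d permutations (seed %d)", x$n_permutations, x$seed),
    sum(x$table$call & x$table$direction == "up"),
    sum(x$table$call & x$table$direction == "down"), x$fdr
  ))
  invisible(x)
}

#' @export
tidy.rank_product_result <- function(x, ...) x$table

#' @export
glance.rank_product_result <- function(x, ...) {
  tibble(
    n_genes = length(unique(x$table$gene)),
    n_up = sum(x$table$call & x$table$direction == "up"),
    n_down = sum(x$table$call & x$table$direction == "down"),
    fdr = x$fdr, n_permutations = x$n_permutations, method = x$method
  )
}

#' Called genes of a rank-product result
#' @param x A `rank_product_result`.
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return Character vector of called gene ids.
#' @export
deg_calls <- function(x, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  tab <- x$table[x$table$call, ]
  if (direction != "both") tab <- tab[tab$direction == direction, ]
  unique(tab$gene)
}

#' Overlap of differential-expression calls across strains
#'
#' Summarises how each rewired strain's called genes overlap with the native
#' strain's, and which genes are shared by every supplied strain.
#'
#' @param calls_by_strain Named list of gene-id character vectors.
#' @param universe Retained-gene universe; a call outside it is an error.
#' @param native Name of the reference strain (default: first element).
#' @return List with `pairwise` (tibble: `strain`, `n_calls`,
#'   `overlap_with_native`) and `shared` (genes called in every strain).
#' @export
deg_overlap <- function(calls_by_strain, universe, native = NULL) {
  stopifnot(is.list(calls_by_strain), !is.null(names(calls_by_strain)))
  outside <- setdiff(unique(unlist(calls_by_strain)), universe)
  if (length(outside)) {
    abort(sprintf("gene(s) outside the universe: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  native <- native %||% names(calls_by_strain)[1]
  if (!native %in% names(calls_by_strain)) abort("unknown `native` strain.")
  pairwise <- purrr::map_dfr(names(calls_by_strain), function(s) {
    tibble(strain = s, n_calls = length(calls_by_strain[[s]]),
           overlap_with_native = length(intersect(calls_by_strain[[s]],
                                                  calls_by_strain[[native]])))
  })
  list(pairwise = pairwise, shared = Reduce(intersect, calls_by_strain))
}
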