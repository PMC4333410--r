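#' K-means clustering of gene change profiles
#'
#' Genes are the observations and their change values over the
#' strain-condition rows (22 under the study design) the coordinates, with
#' Euclidean distance on the shared log scale. The best of `n_init` random
#' starts (by within-cluster sum of squares) is kept; results are
#' deterministic given `seed`.
#'
#' @param change A `change_matrix` (conditions x genes).
#' @param k Number of clusters (1 <= k <= number of genes).
#' @param n_init Random starts.
#' @param seed Integer seed.
#' @param iter_max Maximum Lloyd/Hartigan iterations per start.
#' @return A `cluster_profiles`: list with `assignment` (tibble `gene`,
#'   `cluster`), `centroids` (k x conditions), `inertia`, `k`, `seed`,
#'   `conditions` metadata.
#' @export
#' @examples
#' study <- generate_expression_study(n_genes = 60, seed = 3) |>
#'   normalize_common_mean() |> average_replicates()
#' cm <- build_change_matrix(study)
#' kmeans_profiles(cm, k = 3, seed = 1)$inertia
kmeans_profiles <- function(change, k, n_init = 50, seed = 1, iter_max = 100) {
  x <- t(unclass(change))  # genes x conditions
  k <- stop_if_not_count(k, "k", min = 1L)
  if (k > nrow(x)) abort("`k` exceeds the number of genes.")
  withr::local_seed(seed)
  km <- kmeans(x, centers = k, nstart = n_init, iter.max = iter_max)
  structure(
    list(assignment = tibble(gene = rownames(x),
                             cluster = unname(km$cluster)),
         centroids = km$centers, inertia = km$tot.withinss,
         k = k, seed = seed,
         conditions = change_conditions(change)),
    class = "cluster_profiles"
  )
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat(sprintf("<cluster_profiles> %d genes in %d clusters (inertia %.4g, seed %d)\n",
              nrow(x$assignment), x$k, x$inertia, x$seed))
  invisible(x)
}

#' @export
tidy.cluster_profiles <- function(x, ...) x$assignment

#' @export
glance.cluster_profiles <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, n_genes = nrow(x$assignment),
         seed = x$seed)
}

#' Correlation of each cluster centroid with growth rate
#'
#' Pearson correlation between a cluster's centroid profile and the
#' per-condition growth rates, over conditions with defined growth (rows
#' with unreliable growth, such as 10 min bins, should be excluded when the
#' change matrix is built). A constant centroid has no defined correlation
#' and is reported as missing with a reason.
#'
#' @param result A [kmeans_profiles()] result.
#' @param growth Optional per-condition growth rates (defaults to the
#'   `growth_rate` column of the condition metadata).
#' @return Tibble: `cluster`, `n_genes`, `r`, `p_value`, `note`.
#' @export
cluster_growth_correlation <- function(result, growth = NULL) {
  growth <- growth %||% result$conditions$growth_rate
  if (length(growth) != ncol(result$centroids)) {
    abort("`growth` must have one value per condition row.")
  }
  ok <- !is.na(growth)
  if (sum(ok) < 3) abort("growth must be defined for at least 3 conditions.")
  sizes <- table(result$assignment$cluster)
  purrr::map_dfr(seq_len(result$k), function(cl) {
    cen <- result$centroids[cl, ok]
    if (sd(cen) == 0) {
      return(tibble(cluster = cl, n_genes = as.integer(sizes[as.character(cl)]),
                    r = NA_real_, p_value = NA_real_,
                    note = "constant centroid: correlation undefined"))
    }
    ht <- cor.test(cen, growth[ok], method = "pearson")
    tibble(cluster = cl, n_genes = as.integer(sizes[as.character(cl)]),
           r = unname(ht$estimate), p_value = ht$p.value, note = NA_character_)
  })
}

#' Cross-tabulate loading tails against growth-correlated clusters
#'
#' Checks the concordance that supports the success-path reading: genes in
#' the positive loading tail should sit in clusters whose centroids
#' correlate positively with growth, and negative-tail genes in negatively
#' correlated clusters. Reports the contingency table and the two
#' concordant fractions (missing for an empty tail).
#'
#' @param tails List with `positive` and `negative` gene vectors.
#' @param result A [kmeans_profiles()] result covering all tail genes.
#' @param growth_corr Optional precomputed [cluster_growth_correlation()]
#'   table.
#' @return List with `table` (tibble: `tail`, `cluster_sign`, `n`) and
#'   `fractions` (tibble: `tail`, `fraction_concordant`).
#' @export
tails_vs_clusters <- function(tails, result, growth_corr = NULL) {
  growth_corr <- growth_corr %||% cluster_growth_correlation(result)
  assign <- setNames(result$assignment$cluster, result$assignment$gene)
  missing <- setdiff(unlist(tails[c("positive", "negative")]), names(assign))
  if (length(missing)) {
    abort(sprintf("tail gene(s) not clustered: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  sign_of <- setNames(sign(growth_corr$r), growth_corr$cluster)
  rows <- purrr::map_dfr(c("positive", "negative"), function(tl) {
    genes <- tails[[tl]]
    if (!length(genes)) {
      return(tibble(tail = tl, cluster_sign = NA_character_, n = 0L))
    }
    s <- sign_of[as.character(assign[genes])]
    tibble(tail = tl,
           cluster_sign = dplyr::case_when(
             is.na(s) ~ "undefined", s > 0 ~ "positive",
             s < 0 ~ "negative", TRUE ~ "zero"),
           n = 1L) |>
      group_by(.data$tail, .data$cluster_sign) |>
      summarise(n = sum(.data$n), .groups = "drop")
  })
  fractions <- purrr::map_dfr(c("positive", "negative"), function(tl) {
    genes <- tails[[tl]]
    if (!length(genes)) {
      return(tibble(tail = tl, fraction_concordant = NA_real_))
    }
    s <- sign_of[as.character(assign[genes])]
    want <- if (tl == "positive") 1 else -1
    tibble(tail = tl, fraction_concordant = mean(s == want, na.rm = TRUE))
  })
  list(table = rows, fractions = fractions)
}
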