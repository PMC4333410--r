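#' Principal-component analysis of the transcriptional-change matrix
#'
#' Columns (genes) are mean-centered and the matrix is decomposed by SVD.
#' No unit-variance scaling is applied: change values share the
#' log-expression scale, and scaling would inflate low-variance genes
#' (set `scale = TRUE` to override). Scores are the projections of the
#' condition rows, loadings are orthonormal gene-space directions, and each
#' component's variance fraction is its squared singular value over the
#' total.
#'
#' @param change A `change_matrix` from [build_change_matrix()] (or any
#'   conditions x genes numeric matrix), at least 3 rows.
#' @param n_components Components to retain (<= min(rows, cols)).
#' @param scale Scale genes to unit variance before decomposition.
#' @return A `trajectory_model`: list with `scores` (conditions x
#'   components), `loadings` (genes x components, orthonormal),
#'   `variance_fraction`, `center` (gene means), `sdev`, `conditions`
#'   metadata tibble.
#' @export
#' @examples
#' study <- generate_expression_study(n_genes = 60, seed = 2) |>
#'   normalize_common_mean() |> average_replicates()
#' cm <- build_change_matrix(study,
#'   states = timepoint_levels()[2:4], include_baseline = FALSE)
#' model <- pca_trajectory(cm)
#' model$variance_fraction
pca_trajectory <- function(change, n_components = 3, scale = FALSE) {
  x <- unclass(change)
  if (nrow(x) < 3) abort("need at least 3 condition rows.")
  n_components <- stop_if_not_count(n_components, "n_components", min = 1L)
  if (n_components > min(dim(x))) {
    abort("`n_components` exceeds min(rows, cols).")
  }
  pc <- prcomp(x, center = TRUE, scale. = scale)
  k <- seq_len(n_components)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  conditions <- change_conditions(change) %||%
    tibble(condition = rownames(x) %||% as.character(seq_len(nrow(x))),
           strain = NA_character_, timepoint = NA_character_,
           is_baseline = FALSE, is_failure = FALSE, growth_rate = NA_real_)
  structure(
    list(scores = pc$x[, k, drop = FALSE],
         loadings = pc$rotation[, k, drop = FALSE],
         variance_fraction = vf[k],
         center = pc$center, sdev = pc$sdev,
         scaled = scale, conditions = conditions),
    class = "trajectory_model"
  )
}

#' @export
print.trajectory_model <- function(x, ...) {
  cat(sprintf(
    "<trajectory_model> %d conditions, %d components (%s%% of variance)\n",
    nrow(x$scores), ncol(x$scores),
    paste(round(100 * x$variance_fraction, 1), collapse = "/")
  ))
  invisible(x)
}

#' @export
tidy.trajectory_model <- function(x, ...) {
  bind_cols(x$conditions, as_tibble(x$scores))
}

#' @export
glance.trajectory_model <- function(x, ...) {
  tibble(n_conditions = nrow(x$scores), n_components = ncol(x$scores),
         variance_pc1 = x$variance_fraction[1],
         variance_pc2 = if (ncol(x$scores) > 1) x$variance_fraction[2] else NA_real_)
}

included_rows <- function(model, exclude_failures, exclude = NULL) {
  keep <- rep(TRUE, nrow(model$scores))
  if (exclude_failures) keep <- keep & !model$conditions$is_failure
  if (!is.null(exclude)) keep <- keep & !(model$conditions$condition %in% exclude)
  keep
}

#' Correlation between two principal-component score columns
#'
#' Pearson correlation between the scores of two components across
#' conditions, optionally excluding failure strains (the headline
#' correlation between the first two components holds among survivors,
#' "except for failures").
#'
#' @param model A [pca_trajectory()] model.
#' @param pair Two component indices.
#' @param exclude_failures Drop failure-strain rows.
#' @param exclude Condition ids to drop additionally.
#' @return One-row tibble: `pc_i`, `pc_j`, `r`, `p_value`, `n`.
#' @export
pc_correlation <- function(model, pair = c(1, 2), exclude_failures = FALSE,
                           exclude = NULL) {
  if (length(pair) != 2 || any(pair > ncol(model$scores))) {
    abort("`pair` must index two available components.")
  }
  keep <- included_rows(model, exclude_failures, exclude)
  if (sum(keep) < 3) abort("fewer than 3 included conditions.")
  a <- model$scores[keep, pair[1]]
  b <- model$scores[keep, pair[2]]
  if (sd(a) == 0 || sd(b) == 0) abort("degenerate (zero-variance) scores.")
  ht <- cor.test(a, b, method = "pearson")
  tibble(pc_i = pair[1], pc_j = pair[2],
         r = unname(ht$estimate), p_value = ht$p.value, n = sum(keep))
}

# score-space coordinates of the zero-change state (+His): the origin the
# distance axis is measured from
origin_point <- function(model, pair) {
  drop((0 - model$center) %*% model$loadings[, pair, drop = FALSE])
}

#' Fit the success-path line through the PC1/PC2 score cloud
#'
#' Total-least-squares (major-axis) fit: both coordinates are PC scores with
#' no dependent/independent asymmetry, so the line minimises orthogonal
#' residuals -- it is the first principal axis of the 2-D score cloud.
#' Failure-strain conditions are excluded from the fit by default (they drop
#' off the path; their projections remain available downstream). The line
#' direction is oriented away from the zero-change (`+His`) origin, so
#' projections increase as conditions move along the path.
#'
#' @param model A [pca_trajectory()] model.
#' @param exclude_failures Exclude failure rows from the fit.
#' @param pair Score columns to fit (default PC1/PC2).
#' @param method `"tls"` (total least squares, default) or `"ols"`
#'   (ordinary least squares of the second coordinate on the first, for
#'   sensitivity analysis).
#' @param tol Isotropy tolerance: the fit is rejected when the eigenvalue
#'   gap of the 2-D covariance is below `tol` times the leading eigenvalue.
#' @return A `path_line`: list with `slope`, `intercept`, `direction` (unit
#'   2-vector), `centroid`, `origin` (projection coordinate of the
#'   zero-change state), `method`, `pair`, `included`.
#' @export
fit_path <- function(model, exclude_failures = TRUE, pair = c(1, 2),
                     method = c("tls", "ols"), tol = 1e-8) {
  method <- match.arg(method)
  keep <- included_rows(model, exclude_failures)
  if (sum(keep) < 3) abort("need at least 3 included score points.")
  pts <- model$scores[keep, pair, drop = FALSE]
  ctr <- colMeans(pts)
  if (method == "tls") {
    cv <- stats::cov(pts)
    eg <- eigen(cv, symmetric = TRUE)
    if ((eg$values[1] - eg$values[2]) <= tol * max(eg$values[1], tol)) {
      abort("isotropic point cloud: total-least-squares direction undefined.")
    }
    u <- eg$vectors[, 1]
  } else {
    b <- stats::coef(stats::lm(pts[, 2] ~ pts[, 1]))[2]
    u <- c(1, b) / sqrt(1 + b^2)
  }
  # orient away from the +His origin so path coordinates grow with progress
  org <- origin_point(model, pair)
  if (sum((t(pts) - org) [1, ] * u[1] + (t(pts) - org)[2, ] * u[2]) < 0) u <- -u
  slope <- if (abs(u[1]) < 1e-12) Inf else u[2] / u[1]
  intercept <- if (is.finite(slope)) ctr[2] - slope * ctr[1] else NA_real_
  structure(
    list(slope = unname(slope), intercept = unname(intercept),
         direction = u, centroid = ctr,
         origin = sum((org - ctr) * u),
         method = method, pair = pair, included = keep),
    class = "path_line"
  )
}

#' @export
print.path_line <- function(x, ...) {
  cat(sprintf("<path_line> PC%d/PC%d %s fit: slope %.4g, intercept %.4g (%d points)\n",
              x$pair[1], x$pair[2], x$method, x$slope, x$intercept,
              sum(x$included)))
  invisible(x)
}

#' Normalized distance of each condition along the success path
#'
#' Each condition's score point is orthogonally projected onto the fitted
#' line; its signed arc-length coordinate is measured from the projection of
#' a defined initial point -- by default the zero-change (`+His`) state --
#' and the coordinates of the conditions included in the fit are affinely
#' rescaled to span `[0, 1]`. Failure-strain conditions are projected with
#' the same map, so their distances (and their orthogonal residuals, which
#' quantify "dropping off" the path) are reported but may fall outside
#' `[0, 1]`.
#'
#' @param model A [pca_trajectory()] model.
#' @param line A [fit_path()] line (fitted with defaults when omitted).
#' @param origin `"baseline"` (projection of the zero-change state) or
#'   `"min"` (smallest included projection).
#' @return Tibble: condition metadata plus `coordinate` (arc length from
#'   the origin), `distance` (normalized), `residual` (orthogonal distance
#'   to the line) and `included`.
#' @export
normalized_distance <- function(model, line = NULL,
                                origin = c("baseline", "min")) {
  origin <- match.arg(origin)
  line <- line %||% fit_path(model)
  pts <- model$scores[, line$pair, drop = FALSE]
  rel <- sweep(pts, 2, line$centroid)
  coord <- drop(rel %*% line$direction)
  resid <- sqrt(pmax(rowSums(rel^2) - coord^2, 0))
  origin_coord <- if (origin == "baseline") line$origin else min(coord[line$included])
  coord <- coord - origin_coord
  inc <- coord[line$included]
  if (diff(range(inc)) == 0) abort("all projections coincide: distances undefined.")
  dist <- (coord - min(inc)) / diff(range(inc))
  bind_cols(model$conditions,
            tibble(coordinate = coord, distance = dist,
                   residual = resid, included = line$included))
}

#' Correlation between normalized distance and growth rate
#'
#' Pearson correlation between each condition's position along the success
#' path and its growth rate. The 10 min bins are excluded by default: a
#' growth rate estimated over ten minutes is dominated by counting noise.
#'
#' @param distances Output of [normalized_distance()].
#' @param growth Optional growth-rate vector aligned with `distances`
#'   (defaults to the `growth_rate` column).
#' @param exclude_10min Drop `-His 10 min` rows.
#' @param include_failures Keep failure-strain rows (default `TRUE`).
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
growth_distance_correlation <- function(distances, growth = NULL,
                                        exclude_10min = TRUE,
                                        include_failures = TRUE) {
  d <- distances
  if (!is.null(growth)) {
    if (length(growth) != nrow(d)) abort("`growth` length must match rows.")
    d$growth_rate <- growth
  }
  keep <- !is.na(d$growth_rate) & !d$is_baseline
  if (exclude_10min) keep <- keep & d$timepoint != TP_10MIN
  if (!include_failures) keep <- keep & !d$is_failure
  if (sum(keep) < 3) abort("fewer than 3 conditions with defined growth.")
  ht <- cor.test(d$distance[keep], d$growth_rate[keep], method = "pearson")
  tibble(r = unname(ht$estimate), p_value = ht$p.value, n = sum(keep))
}

#' Gene loadings on the success path and their top tails
#'
#' The unit vector along the fitted line, expressed in the score plane, is
#' mapped back to gene space through the loading columns; the result (unit
#' norm) is each gene's loading on the path. The `floor(tail_fraction * n)`
#' most positive and most negative genes form the tails handed to
#' enrichment -- with the study's 3398 retained genes and the default 5%,
#' 169 genes per tail. Ties are broken by stable gene order.
#'
#' @param model A [pca_trajectory()] model.
#' @param line A [fit_path()] line (defaults to fitting one).
#' @param tail_fraction Fraction per tail, in `(0, 0.5]`.
#' @return Tibble of class `path_loadings`: `gene`, `loading`, `tail`
#'   (`"positive"`, `"negative"` or `NA`); tails also in the `"tails"`
#'   attribute (see [loading_tails()]).
#' @export
path_loadings <- function(model, line = NULL, tail_fraction = 0.05) {
  if (tail_fraction <= 0 || tail_fraction > 0.5) {
    abort("`tail_fraction` must be in (0, 0.5].")
  }
  line <- line %||% fit_path(model)
  w <- drop(model$loadings[, line$pair, drop = FALSE] %*% line$direction)
  genes <- rownames(model$loadings)
  n_tail <- floor(tail_fraction * length(w))
  if (n_tail < 1) abort("tail would be empty; increase `tail_fraction`.")
  ord_pos <- order(-w, seq_along(w))[seq_len(n_tail)]
  ord_neg <- order(w, seq_along(w))[seq_len(n_tail)]
  tail <- rep(NA_character_, length(w))
  tail[ord_pos] <- "positive"
  tail[ord_neg] <- "negative"
  out <- tibble(gene = genes, loading = w, tail = tail)
  attr(out, "tails") <- list(positive = genes[ord_pos], negative = genes[ord_neg])
  class(out) <- c("path_loadings", class(out))
  out
}

#' Positive and negative tail gene lists of path loadings
#' @param x A [path_loadings()] result.
#' @return List with `positive` and `negative` gene-id vectors.
#' @export
loading_tails <- function(x) attr(x, "tails")
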