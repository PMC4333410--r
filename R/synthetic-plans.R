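#' Describe the planned phenotype of one strain (fate plan)
#'
#' A fate plan encodes, per strain, the ground truth the synthetic-data
#' generator plants: how strongly the rewired-gene reporter ratio (GFP bias)
#' shifts under starvation, how its cell-to-cell variation changes, how cell
#' size (forward scatter) shifts, and the exponential growth rates in
#' histidine-rich (`growth_rate_plus`) and histidine-free
#' (`growth_rate_minus`) medium. Fate classes follow the three observed
#' outcomes of starvation: `good` survivors recover near-native growth,
#' `poor` survivors grow slowly, `failure` strains show no detectable growth
#' (and therefore contribute no late expression sample), and `native` marks
#' the unrewired control.
#'
#' @param strain Strain label (e.g. `"hisB"`).
#' @param fate One of `"good"`, `"poor"`, `"failure"`, `"native"`.
#' @param bias_shift Multiplicative change of the geometric-mean GFP bias
#'   under starvation (dimensionless).
#' @param bias_cv_initial,bias_cv_final Coefficient of variation of the GFP
#'   bias in rich medium and under starvation; both must be positive.
#' @param fsc_shift Multiplicative change of geometric-mean forward scatter
#'   (relative cell size) under starvation.
#' @param growth_rate_plus,growth_rate_minus Exponential growth rates
#'   (h^-1); `growth_rate_minus` must be `0` for failures.
#' @param has_late_timepoint Whether the strain yields a `-His >10 h`
#'   expression sample. Must be `FALSE` for failures.
#'
#' @return A one-row tibble; rows from several calls can be bound into a
#'   study design (see [default_fate_plans()]).
#' @export
#' @examples
#' fate_plan("hisB", "good", bias_shift = 4, growth_rate_minus = 0.55)
fate_plan <- function(strain,
                      fate = c("good", "poor", "failure", "native"),
                      bias_shift = 1,
                      bias_cv_initial = 0.3,
                      bias_cv_final = bias_cv_initial,
                      fsc_shift = 1,
                      growth_rate_plus = 0.7,
                      growth_rate_minus = if (fate == "failure") 0 else 0.5,
                      has_late_timepoint = fate != "failure") {
  fate <- match.arg(fate)
  stop_if_not_scalar_number(bias_shift, "bias_shift", positive = TRUE)
  stop_if_not_scalar_number(bias_cv_initial, "bias_cv_initial", positive = TRUE)
  stop_if_not_scalar_number(bias_cv_final, "bias_cv_final", positive = TRUE)
  stop_if_not_scalar_number(fsc_shift, "fsc_shift", positive = TRUE)
  stop_if_not_scalar_number(growth_rate_plus, "growth_rate_plus")
  stop_if_not_scalar_number(growth_rate_minus, "growth_rate_minus")
  if (growth_rate_minus < 0) {
    abort("`growth_rate_minus` must be >= 0.")
  }
  if (fate == "failure" && (growth_rate_minus != 0 || has_late_timepoint)) {
    abort("failure strains must have growth_rate_minus = 0 and no late time point.")
  }
  tibble(
    strain = as.character(strain), fate = fate,
    bias_shift = bias_shift,
    bias_cv_initial = bias_cv_initial, bias_cv_final = bias_cv_final,
    fsc_shift = fsc_shift,
    growth_rate_plus = growth_rate_plus, growth_rate_minus = growth_rate_minus,
    has_late_timepoint = has_late_timepoint
  )
}

#' Default eight-strain study design
#'
#' Mirrors the rewired histidine-operon panel: a native control plus seven
#' rewired strains falling into three fates under histidine starvation --
#' good survivors (`hisB`, `hisC`, `hisF`) with strong reporter induction and
#' near-native growth recovery, poor survivors (`hisA`, `hisI`) with little
#' mean induction but increased cell-to-cell variation and suppressed growth,
#' and failures (`hisD`, `hisG`) with no detectable growth and no late
#' expression sample. Six strains grow under starvation and two fail, so with
#' three replicates the expression design yields 90 samples.
#'
#' Numeric values are generator ground truth chosen to be realistic for
#' *E. coli* in minimal medium (rich-medium growth ~0.7 h^-1, reporter-ratio
#' CVs of 25--50%), not measurements.
#'
#' @return Tibble with one [fate_plan()] row per strain.
#' @export
#' @examples
#' default_fate_plans()
default_fate_plans <- function() {
  bind_rows(
    fate_plan("native", "native", bias_shift = 4.0, bias_cv_initial = 0.45,
              bias_cv_final = 0.30, fsc_shift = 1.15,
              growth_rate_plus = 0.75, growth_rate_minus = 0.60),
    fate_plan("hisB", "good", bias_shift = 4.0, bias_cv_initial = 0.45,
              bias_cv_final = 0.30, fsc_shift = 1.15,
              growth_rate_plus = 0.72, growth_rate_minus = 0.55),
    fate_plan("hisC", "good", bias_shift = 3.5, bias_cv_initial = 0.50,
              bias_cv_final = 0.35, fsc_shift = 1.20,
              growth_rate_plus = 0.70, growth_rate_minus = 0.50),
    fate_plan("hisF", "good", bias_shift = 2.0, bias_cv_initial = 0.40,
              bias_cv_final = 0.30, fsc_shift = 1.05,
              growth_rate_plus = 0.74, growth_rate_minus = 0.58),
    fate_plan("hisA", "poor", bias_shift = 1.2, bias_cv_initial = 0.25,
              bias_cv_final = 0.45, fsc_shift = 1.35,
              growth_rate_plus = 0.70, growth_rate_minus = 0.15),
    fate_plan("hisI", "poor", bias_shift = 1.1, bias_cv_initial = 0.25,
              bias_cv_final = 0.50, fsc_shift = 1.40,
              growth_rate_plus = 0.68, growth_rate_minus = 0.10),
    fate_plan("hisD", "failure", bias_shift = 1.0, bias_cv_initial = 0.30,
              bias_cv_final = 0.35, fsc_shift = 1.00,
              growth_rate_plus = 0.70, growth_rate_minus = 0,
              has_late_timepoint = FALSE),
    fate_plan("hisG", "failure", bias_shift = 1.0, bias_cv_initial = 0.30,
              bias_cv_final = 0.30, fsc_shift = 1.00,
              growth_rate_plus = 0.72, growth_rate_minus = 0,
              has_late_timepoint = FALSE)
  )
}

#' Plant a one-dimensional expression trajectory
#'
#' The generator's central assumption is that successful adaptation moves a
#' strain's transcriptional change along a single gene-space direction `g`
#' (unit vector over genes), by a per-condition scalar amount (the trajectory
#' progress), with growth rate an affine function of progress. Failure
#' strains additionally receive a displacement orthogonal to `g`, so that
#' "dropping off" the path is true by construction.
#'
#' @param direction Numeric vector over genes; normalized to unit length.
#' @param progress Tibble with columns `strain`, `timepoint`, `progress`
#'   (trajectory coordinate, 0 for `+His`) and `growth_rate` (h^-1, `NA`
#'   where growth is undefined).
#' @param growth_slope,growth_intercept Affine map from progress to growth
#'   rate (h^-1 per unit progress, h^-1).
#' @param noise_sd Per-gene, per-sample residual standard deviation on the
#'   log-expression scale; must be >= 0.
#' @param off_path_magnitude Size of the orthogonal displacement given to
#'   failure-strain starvation states (log-expression units).
#' @param off_direction Unit vector orthogonal to `direction` (computed if
#'   omitted; required when `off_path_magnitude > 0` and genes < 2).
#'
#' @return An object of class `trajectory_plan`.
#' @seealso [default_trajectory_plan()] for the standard study conditions.
#' @export
trajectory_plan <- function(direction, progress,
                            growth_slope = 0.15, growth_intercept = 0,
                            noise_sd = 0.03, off_path_magnitude = 1.5,
                            off_direction = NULL) {
  if (!is.numeric(direction) || length(direction) < 2L) {
    abort("`direction` must be a numeric vector over at least 2 genes.")
  }
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) abort("`direction` must be non-zero.")
  direction <- direction / nrm
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  need <- c("strain", "timepoint", "progress", "growth_rate")
  if (!all(need %in% names(progress))) {
    abort("`progress` must have columns strain, timepoint, progress, growth_rate.")
  }
  base <- progress$progress[progress$timepoint == TP_PLUS]
  if (length(base) && any(base != 0)) {
    abort("progress of the +His baseline must be 0.")
  }
  if (is.null(off_direction)) {
    # deterministic orthogonal complement of g along the first two axes
    v <- numeric(length(direction))
    v[1:2] <- c(-direction[2], direction[1])
    if (sum(v^2) == 0) v[1:2] <- c(1, 0)
    v <- v - sum(v * direction) * direction
    off_direction <- v / sqrt(sum(v^2))
  } else {
    off_direction <- off_direction - sum(off_direction * direction) * direction
    off_direction <- off_direction / sqrt(sum(off_direction^2))
  }
  structure(
    list(direction = direction, progress = as_tibble(progress),
         growth_slope = growth_slope, growth_intercept = growth_intercept,
         noise_sd = noise_sd, off_path_magnitude = off_path_magnitude,
         off_direction = off_direction),
    class = "trajectory_plan"
  )
}

#' Default trajectory plan for a fate-plan design
#'
#' Builds a seeded random unit direction supported on a fraction of the
#' genes (adaptive reorganization touches a subset of the transcriptome, not
#' every gene equally) and a progress schedule per strain: the late-state
#' progress is proportional to the planned starvation growth rate (so growth
#' is exactly affine in progress, slope `max(growth_rate_minus)/amplitude`),
#' the 2 h state sits at 60% of the late progress, and the 10 min state at
#' 5% (expression changes lag starvation by roughly ten minutes). Failure
#' strains have zero on-path progress and are displaced off the path.
#'
#' @param fates Fate-plan tibble (see [default_fate_plans()]).
#' @param n_genes Number of genes.
#' @param seed Integer seed for the random direction.
#' @param amplitude Late-state progress of the fastest-growing strain
#'   (log-expression units of total displacement along the path).
#' @param support_fraction Fraction of genes carrying the direction.
#' @param growth_noise_sd Standard deviation of growth-rate noise around the
#'   affine map (h^-1).
#' @inheritParams trajectory_plan
#' @return A `trajectory_plan`.
#' @export
#' @examples
#' plan <- default_trajectory_plan(default_fate_plans(), n_genes = 100, seed = 1)
#' plan$progress
default_trajectory_plan <- function(fates, n_genes = 3398, seed = 1,
                                    amplitude = 4, support_fraction = 0.1,
                                    noise_sd = 0.03, off_path_magnitude = 1.5,
                                    growth_noise_sd = 0.02) {
  stop_if_not_count(n_genes, "n_genes", min = 10L)
  withr::local_seed(seed)
  support <- sample.int(n_genes, max(2L, ceiling(support_fraction * n_genes)))
  g <- numeric(n_genes)
  g[support] <- rnorm(length(support))
  g <- g / sqrt(sum(g^2))
  # orthogonal off-path direction with its own (disjoint where possible) support
  v <- numeric(n_genes)
  off_support <- setdiff(seq_len(n_genes), support)
  if (length(off_support) < 2L) off_support <- seq_len(n_genes)
  off_support <- sample(off_support, max(2L, ceiling(support_fraction * n_genes) / 2))
  v[off_support] <- rnorm(length(off_support))
  v <- v - sum(v * g) * g
  v <- v / sqrt(sum(v^2))

  mu_max <- max(fates$growth_rate_minus)
  if (mu_max <= 0) abort("at least one strain must grow under starvation.")
  slope <- mu_max / amplitude

  sched <- purrr::map_dfr(seq_len(nrow(fates)), function(i) {
    f <- fates[i, ]
    s_late <- amplitude * f$growth_rate_minus / mu_max
    tp <- c(TP_PLUS, TP_10MIN, TP_2H, if (f$has_late_timepoint) TP_LATE)
    s <- c(0, 0.05 * s_late, 0.6 * s_late, if (f$has_late_timepoint) s_late)
    mu <- slope * s + rnorm(length(s), 0, growth_noise_sd)
    mu[tp == TP_PLUS] <- f$growth_rate_plus
    tibble(strain = f$strain, timepoint = tp, progress = s, growth_rate = mu)
  })

  trajectory_plan(g, sched, growth_slope = slope, growth_intercept = 0,
                  noise_sd = noise_sd, off_path_magnitude = off_path_magnitude,
                  off_direction = v)
}

#' @export
print.trajectory_plan <- function(x, ...) {
  cat(sprintf(
    "<trajectory_plan> %d genes, %d conditions, noise_sd = %g, off-path = %g\n",
    length(x$direction), nrow(x$progress), x$noise_sd, x$off_path_magnitude
  ))
  invisible(x)
}
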