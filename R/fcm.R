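#' Label flow-cytometry events (range, bead, debris, cell)
#'
#' Events are labelled, never removed, in three passes: (1) an event sitting
#' at or beyond a channel's range limit on any channel is `out_of_range`
#' (saturation piles up exactly at the limits, so the boundaries are
#' inclusive); (2) remaining events inside the bead box are `bead`; (3)
#' remaining events inside the debris box are `debris`; everything else is
#' `cell`. Gates are axis-aligned boxes given as named lists of `c(lo, hi)`
#' intervals per channel; overlapping bead and debris boxes are rejected as
#' ambiguous.
#'
#' @param events Tibble with channel columns `FSC`, `SSC`, `GFP`, `RFP`.
#' @param bead_gate,debris_gate Gate boxes (`NULL` for no gate), e.g.
#'   `list(FSC = c(1e5, 2.2e5), SSC = c(8e4, 1.8e5))`; see [default_gates()].
#' @param instrument_range Named list of `c(min, max)` per channel; defaults
#'   to the table's `"instrument_range"` attribute, else the 18-bit scale.
#' @return The events with a `label` column
#'   (`cell` / `bead` / `debris` / `out_of_range`).
#' @export
#' @examples
#' ev <- generate_fcm_sample(fate_plan("hisB", "good"), "+His",
#'                           n_cells = 500, seed = 1)
#' table(gate_events(ev, default_gates()$bead, default_gates()$debris)$label)
gate_events <- function(events, bead_gate = NULL, debris_gate = NULL,
                        instrument_range = NULL) {
  for (ch in fcm_channels()) {
    if (!ch %in% names(events)) abort(sprintf("`events` lacks channel %s.", ch))
  }
  instrument_range <- instrument_range %||%
    attr(events, "instrument_range") %||% default_instrument_range()
  if (gates_overlap(bead_gate, debris_gate, instrument_range)) {
    abort("bead and debris gates overlap; labelling would be ambiguous.")
  }
  n <- nrow(events)
  label <- rep("cell", n)
  oor <- rep(FALSE, n)
  for (ch in fcm_channels()) {
    rng <- instrument_range[[ch]]
    oor <- oor | events[[ch]] <= rng[1] | events[[ch]] >= rng[2]
  }
  in_box <- function(gate) {
    if (is.null(gate)) return(rep(FALSE, n))
    inside <- rep(TRUE, n)
    for (ch in names(gate)) {
      inside <- inside & events[[ch]] >= gate[[ch]][1] & events[[ch]] <= gate[[ch]][2]
    }
    inside
  }
  label[in_box(debris_gate)] <- "debris"
  label[in_box(bead_gate)] <- "bead"
  label[oor] <- "out_of_range"
  events$label <- label
  attr(events, "instrument_range") <- instrument_range
  events
}

# boxes overlap when their intervals intersect on every channel either
# mentions (a channel absent from a box spans the full instrument range)
gates_overlap <- function(a, b, instrument_range) {
  if (is.null(a) || is.null(b)) return(FALSE)
  for (ch in union(names(a), names(b))) {
    ia <- a[[ch]] %||% instrument_range[[ch]]
    ib <- b[[ch]] %||% instrument_range[[ch]]
    if (max(ia[1], ib[1]) > min(ia[2], ib[2])) return(FALSE)
  }
  TRUE
}

#' Cell concentration from spiked-in beads
#'
#' Beads of known concentration are mixed into the sample, so the cell
#' concentration is the cell-to-bead event ratio times the bead
#' concentration.
#'
#' @param events Gated events (a `label` column from [gate_events()]).
#' @param bead_conc Bead concentration (beads/ml).
#' @return Cell concentration (cells/ml).
#' @export
#' @examples
#' ev <- tibble::tibble(label = rep(c("cell", "bead"), c(5000, 1000)))
#' concentration(ev, 1e5)  # 5e5
concentration <- function(events, bead_conc) {
  if (!"label" %in% names(events)) abort("`events` must be gated first.")
  stop_if_not_scalar_number(bead_conc, "bead_conc", positive = TRUE)
  n_bead <- sum(events$label == "bead")
  if (n_bead == 0) abort("no bead events: concentration is undefined.")
  sum(events$label == "cell") / n_bead * bead_conc
}

#' Per-cell GFP bias (green over red fluorescence)
#'
#' The rewired gene is co-expressed with GFP while RFP is constitutive, so
#' the per-event ratio GFP/RFP reports rewired-gene expression independent of
#' overall reporter capacity. Computed over cell events only.
#'
#' @param events Event table; if a `label` column is present only
#'   `label == "cell"` rows are used, otherwise all rows are taken as cells.
#' @return Numeric vector of per-cell bias values, in event order.
#' @export
#' @examples
#' gfp_bias(tibble::tibble(GFP = c(200, 100), RFP = c(100, 100)))
gfp_bias <- function(events) {
  if ("label" %in% names(events)) {
    events <- events[events$label == "cell", , drop = FALSE]
  }
  bad <- which(events$RFP <= 0)
  if (length(bad)) {
    abort(sprintf("RFP FI <= 0 for cell event(s) %s; bias undefined.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  events$GFP / events$RFP
}

#' Population statistics of GFP bias and cell size over replicates
#'
#' Computes, per replicate, the mean and standard deviation of the GFP bias
#' and of forward scatter (relative cell size), then averages these
#' statistics over replicates and reports their standard errors across
#' replicates. SDs are arithmetic on the raw scale by default; `log = TRUE`
#' computes them on log-transformed values instead.
#'
#' @param data Tibble with columns `bias`, `fsc` and `replicate` (one row
#'   per cell event); each replicate needs at least two events.
#' @param log Compute statistics on `log10` values.
#' @return One-row tibble of class `population_stats` with `mean_bias`,
#'   `sd_bias`, `mean_fsc`, `sd_fsc`, their standard errors `se_*`,
#'   `n_events`, `n_replicates`; the per-replicate table is kept in the
#'   `"replicates"` attribute (used by [shift_test()]).
#' @export
population_stats <- function(data, log = FALSE) {
  need <- c("bias", "fsc", "replicate")
  if (!all(need %in% names(data))) {
    abort("`data` must have columns bias, fsc, replicate.")
  }
  counts <- table(data$replicate)
  if (length(counts) == 0 || any(counts < 2)) {
    abort("every replicate needs at least 2 events (and none may be empty).")
  }
  if (log) {
    data <- mutate(data, bias = log10(.data$bias), fsc = log10(.data$fsc))
  }
  per_rep <- data |>
    group_by(.data$replicate) |>
    summarise(
      mean_bias = mean(.data$bias), sd_bias = sd(.data$bias),
      mean_fsc = mean(.data$fsc), sd_fsc = sd(.data$fsc),
      n_events = n(), .groups = "drop"
    )
  R <- nrow(per_rep)
  se <- function(v) if (R > 1) sd(v) / sqrt(R) else NA_real_
  out <- tibble(
    mean_bias = mean(per_rep$mean_bias), sd_bias = mean(per_rep$sd_bias),
    mean_fsc = mean(per_rep$mean_fsc), sd_fsc = mean(per_rep$sd_fsc),
    se_mean_bias = se(per_rep$mean_bias), se_sd_bias = se(per_rep$sd_bias),
    se_mean_fsc = se(per_rep$mean_fsc), se_sd_fsc = se(per_rep$sd_fsc),
    n_events = sum(per_rep$n_events), n_replicates = R
  )
  attr(out, "replicates") <- per_rep
  class(out) <- c("population_stats", class(out))
  out
}

#' Exponential growth rate from two concentrations
#'
#' `mu = ln(Ct / C0) / t`: the rate at which offspring accumulate during
#' exponential growth, from initial and final cell concentrations and the
#' elapsed culture time.
#'
#' @param C0,Ct Initial and final cell concentrations (cells/ml), > 0.
#' @param t Culture time (h), > 0. All arguments recycle.
#' @return Growth rate(s) in h^-1.
#' @export
#' @examples
#' growth_rate(1e3, 1e7, 10)  # log(1e4) / 10
growth_rate <- function(C0, Ct, t) {
  if (any(!is.finite(C0)) || any(C0 <= 0)) abort("`C0` must be positive.")
  if (any(!is.finite(Ct)) || any(Ct <= 0)) abort("`Ct` must be positive.")
  if (any(!is.finite(t)) || any(t <= 0)) abort("`t` must be positive.")
  log(Ct / C0) / t
}

#' Test for a starvation-induced increase in a population statistic
#'
#' One-sided Welch two-sample t-test on per-replicate summary statistics,
#' with alternative "greater under starvation" (-His > +His). The underlying
#' study flags increases at P < 0.05 and stronger levels with asterisks;
#' which test sits behind such flags is a convention, and this one-sided
#' Welch test on replicate summaries is the convention adopted here.
#'
#' @param stats_plus,stats_minus [population_stats()] results (or their
#'   per-replicate tables) for the rich-medium and starved conditions; at
#'   least two replicates each.
#' @param statistic Which statistic to compare: `"mean_bias"`, `"sd_bias"`,
#'   `"mean_fsc"` or `"sd_fsc"`.
#' @return One-row tibble: `statistic`, `estimate_plus`, `estimate_minus`,
#'   `t`, `df`, `p_value` (one-sided).
#' @export
shift_test <- function(stats_plus, stats_minus,
                       statistic = c("mean_bias", "sd_bias", "mean_fsc", "sd_fsc")) {
  statistic <- match.arg(statistic)
  grab <- function(x) {
    rep_tab <- attr(x, "replicates") %||% as_tibble(x)
    if (!statistic %in% names(rep_tab)) {
      abort(sprintf("per-replicate values of %s unavailable.", statistic))
    }
    rep_tab[[statistic]]
  }
  a <- grab(stats_plus)
  b <- grab(stats_minus)
  if (length(a) < 2 || length(b) < 2) {
    abort("at least 2 replicates per condition are required.")
  }
  ht <- t.test(b, a, alternative = "greater", var.equal = FALSE)
  tibble(
    statistic = statistic,
    estimate_plus = mean(a), estimate_minus = mean(b),
    t = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value
  )
}

#' Correlation between growth rate and expression (or size) variation
#'
#' Pearson correlation between per-strain growth rates and population
#' standard deviations, by default on the logarithmic scale on both axes (as
#' the underlying comparison plots them).
#'
#' @param growth Growth rates (h^-1), length >= 3.
#' @param sds Population standard deviations, same length.
#' @param log_scale Correlate `log10` of both vectors (values must then be
#'   positive).
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
growth_variation_correlation <- function(growth, sds, log_scale = TRUE) {
  if (length(growth) != length(sds)) abort("`growth` and `sds` lengths differ.")
  if (length(growth) < 3) abort("need at least 3 strains.")
  if (log_scale) {
    if (any(growth <= 0) || any(sds <= 0)) {
      abort("log-scale correlation needs positive values.")
    }
    growth <- log10(growth)
    sds <- log10(sds)
  }
  if (sd(growth) == 0 || sd(sds) == 0) {
    abort("zero variance: correlation undefined.")
  }
  ht <- cor.test(growth, sds, method = "pearson")
  tibble(r = unname(ht$estimate), p_value = ht$p.value, n = length(growth))
}
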