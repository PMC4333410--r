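#' Build the strain-condition transcriptional-change matrix
#'
#' For each strain, the log expression in rich medium (`+His`) is subtracted
#' from each requested starvation state, giving one change profile per
#' strain-condition over the retained genes. With the eight-strain design
#' two presets reproduce the study's 22-row matrices:
#'
#' * clustering preset -- states `-His 2 h` and `-His >10 h` plus an explicit
#'   zero baseline row per strain (the 10 min state is excluded because its
#'   growth estimate is unreliable): 8 + 8 + 6 = 22 rows;
#' * PCA preset -- states `-His 10 min`, `-His 2 h`, `-His >10 h` with no
#'   baseline: 8 + 8 + 6 = 22 rows.
#'
#' Strains lacking the late state are treated as failures (configurable via
#' `failures`); a requested state missing for any other strain is an error.
#'
#' @param study A replicate-averaged, normalized [expression_study()].
#' @param states Starvation time points to difference against `+His`.
#' @param include_baseline Add a zero change row per strain for `+His`.
#' @param growth Optional data frame `strain`, `timepoint`, `growth_rate`
#'   attached to matching rows (defaults to generator truth when present).
#' @param failures Strains whose missing late state is expected; default:
#'   strains without a `-His >10 h` sample.
#' @return A `change_matrix`: numeric conditions x genes matrix whose
#'   `"conditions"` attribute is a tibble (`condition`, `strain`,
#'   `timepoint`, `is_baseline`, `is_failure`, `growth_rate`).
#' @export
#' @examples
#' study <- generate_expression_study(n_genes = 50, seed = 1) |>
#'   normalize_common_mean() |>
#'   average_replicates()
#' nrow(build_change_matrix(study))  # 22
build_change_matrix <- function(study,
                                states = c("-His 2 h", "-His >10 h"),
                                include_baseline = TRUE,
                                growth = NULL, failures = NULL) {
  if (!study$averaged) {
    abort("`build_change_matrix()` expects a replicate-averaged study.")
  }
  bad <- setdiff(states, setdiff(timepoint_levels(), TP_PLUS))
  if (length(bad)) {
    abort(sprintf("unknown state(s): %s", paste(bad, collapse = ", ")))
  }
  smp <- study$samples
  strains <- unique(smp$strain)
  if (is.null(failures)) {
    failures <- strains[!vapply(strains, function(s) {
      any(smp$strain == s & smp$timepoint == TP_LATE)
    }, logical(1))]
  }
  if (is.null(growth)) {
    truth <- attr(study, "truth")
    if (!is.null(truth)) growth <- truth$progress
  }
  m <- retained_matrix(study)
  col_of <- function(s, tp) {
    j <- which(smp$strain == s & smp$timepoint == tp)
    if (length(j) != 1L) return(NULL)
    m[, j]
  }
  rows <- list()
  meta <- list()
  add_row <- function(values, s, tp, baseline) {
    id <- paste(s, tp, sep = "|")
    rows[[id]] <<- values
    meta[[id]] <<- tibble(condition = id, strain = s, timepoint = tp,
                          is_baseline = baseline, is_failure = s %in% failures)
  }
  for (s in strains) {
    base <- col_of(s, TP_PLUS)
    if (is.null(base)) abort(sprintf("strain %s lacks a +His sample.", s))
    if (include_baseline) add_row(base * 0, s, TP_PLUS, TRUE)
    for (tp in states) {
      v <- col_of(s, tp)
      if (is.null(v)) {
        if (tp == TP_LATE && s %in% failures) next
        abort(sprintf("state '%s' is absent for growing strain %s.", tp, s))
      }
      add_row(v - base, s, tp, FALSE)
    }
  }
  mat <- do.call(rbind, rows)
  conditions <- bind_rows(meta)
  if (!is.null(growth)) {
    conditions <- left_join(
      conditions,
      dplyr::distinct(as_tibble(growth)[, c("strain", "timepoint", "growth_rate")]),
      by = c("strain", "timepoint")
    )
    # baseline rows describe the rich-medium regime; the growth-change
    # correlations downstream compare starvation states, so their growth
    # is left undefined here
    conditions$growth_rate[conditions$is_baseline] <- NA_real_
  } else {
    conditions$growth_rate <- NA_real_
  }
  structure(mat, conditions = conditions, class = c("change_matrix", "matrix"))
}

#' Condition metadata of a change matrix
#' @param change A `change_matrix` from [build_change_matrix()].
#' @return Tibble of per-row condition metadata.
#' @export
change_conditions <- function(change) attr(change, "conditions")

#' @export
print.change_matrix <- function(x, ...) {
  cond <- change_conditions(x)
  cat(sprintf(
    "<change_matrix> %d conditions x %d genes (%d baseline, %d failure rows)\n",
    nrow(x), ncol(x), sum(cond$is_baseline), sum(cond$is_failure)
  ))
  invisible(x)
}

#' @export
tidy.change_matrix <- function(x, ...) {
  as_tibble(unclass(x), rownames = "condition") |>
    tidyr::pivot_longer(-"condition", names_to = "gene", values_to = "change") |>
    left_join(change_conditions(x), by = "condition")
}
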