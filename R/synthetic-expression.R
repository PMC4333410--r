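#' Simulate a log-scale expression study with planted ground truth
#'
#' Generates the genes x samples matrix of a starvation time-course: per
#' strain, samples at `+His`, `-His 10 min`, `-His 2 h` and (for strains with
#' `has_late_timepoint`) `-His >10 h`, each with `n_reps` replicates. Log
#' expression is
#' `baseline + progress * direction + off-path term + DE offsets + noise`,
#' where `direction` and the per-condition `progress` come from the
#' trajectory plan: surviving strains move along one gene-space direction by
#' an amount tied to their growth rate, while failure strains stay at the
#' origin of the path and are displaced orthogonally. With the default
#' eight-strain design (six growing strains with four time points, two
#' failures with three) and three replicates the study has exactly 90
#' samples.
#'
#' @param fates Fate-plan tibble ([default_fate_plans()]).
#' @param traj A [trajectory_plan()]; defaults to
#'   [default_trajectory_plan()] for `fates` at `n_genes` (seeded from
#'   `seed`).
#' @param n_genes Number of genes (>= 10).
#' @param n_reps Replicates per strain x time point (>= 2).
#' @param de_spec Optional planted differential expression: a data frame
#'   with columns `gene` (index in `1..n_genes` or gene id), `strain`, and
#'   `lfc` (log-units added to that strain's `-His 2 h` and `-His >10 h`
#'   samples).
#' @param baseline Optional numeric vector of per-gene baseline log
#'   expression; drawn as N(2, 0.8) if omitted.
#' @param seed Integer seed; identical seeds give identical studies.
#'
#' @return An [expression_study()] whose `"truth"` attribute records the
#'   planted direction, per-condition progress and growth rates, DE table and
#'   baseline.
#' @export
#' @examples
#' study <- generate_expression_study(n_genes = 200, seed = 1)
#' dim(study$matrix)
generate_expression_study <- function(fates = default_fate_plans(),
                                      traj = NULL,
                                      n_genes = 3398, n_reps = 3,
                                      de_spec = NULL, baseline = NULL,
                                      seed = 1) {
  n_genes <- stop_if_not_count(n_genes, "n_genes", min = 10L)
  n_reps <- stop_if_not_count(n_reps, "n_reps", min = 2L)
  withr::local_seed(seed)
  if (is.null(traj)) {
    traj <- default_trajectory_plan(fates, n_genes = n_genes,
                                    seed = sample.int(2^31 - 1, 1))
  }
  if (length(traj$direction) != n_genes) {
    abort("`traj$direction` length must equal `n_genes`.")
  }
  genes <- sprintf("g%05d", seq_len(n_genes))
  if (is.null(baseline)) baseline <- rnorm(n_genes, mean = 2, sd = 0.8)
  if (length(baseline) != n_genes) abort("`baseline` length must equal `n_genes`.")

  if (!is.null(de_spec)) {
    de_spec <- as_tibble(de_spec)
    if (!all(c("gene", "strain", "lfc") %in% names(de_spec))) {
      abort("`de_spec` needs columns gene, strain, lfc.")
    }
    if (is.numeric(de_spec$gene)) {
      if (any(de_spec$gene < 1 | de_spec$gene > n_genes)) {
        abort("`de_spec` references gene indices outside 1..n_genes.")
      }
      de_spec$gene <- genes[de_spec$gene]
    } else if (!all(de_spec$gene %in% genes)) {
      abort("`de_spec` references unknown gene ids.")
    }
  }

  sched <- traj$progress
  cols <- list()
  meta <- list()
  for (i in seq_len(nrow(fates))) {
    f <- fates[i, ]
    tps <- c(TP_PLUS, TP_10MIN, TP_2H, if (f$has_late_timepoint) TP_LATE)
    for (tp in tps) {
      row <- sched[sched$strain == f$strain & sched$timepoint == tp, ]
      if (nrow(row) != 1L) {
        abort(sprintf("trajectory plan lacks progress for %s / %s.", f$strain, tp))
      }
      mean_vec <- baseline + row$progress * traj$direction
      if (f$fate == "failure" && tp == TP_2H && traj$off_path_magnitude > 0) {
        mean_vec <- mean_vec + traj$off_path_magnitude * traj$off_direction
      }
      if (!is.null(de_spec) && tp %in% c(TP_2H, TP_LATE)) {
        hit <- de_spec[de_spec$strain == f$strain, ]
        if (nrow(hit)) {
          mean_vec[match(hit$gene, genes)] <-
            mean_vec[match(hit$gene, genes)] + hit$lfc
        }
      }
      for (r in seq_len(n_reps)) {
        id <- sprintf("%s|%s|r%d", f$strain, tp, r)
        cols[[id]] <- mean_vec + rnorm(n_genes, 0, traj$noise_sd)
        meta[[id]] <- tibble(sample_id = id, strain = f$strain,
                             timepoint = tp, replicate = r)
      }
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- genes
  study <- expression_study(mat, bind_rows(meta))
  attr(study, "truth") <- list(
    direction = setNames(traj$direction, genes),
    off_direction = setNames(traj$off_direction, genes),
    progress = left_join(sched, fates[, c("strain", "fate")], by = "strain"),
    de = de_spec, baseline = setNames(baseline, genes),
    noise_sd = traj$noise_sd
  )
  study
}

#' Ground truth planted by the generator
#'
#' @param study An [expression_study()] made by [generate_expression_study()].
#' @return List with elements `direction`, `off_direction`, `progress`
#'   (per-condition trajectory coordinate and growth rate, with fate),
#'   `de`, `baseline`, `noise_sd`; `NULL` for real studies.
#' @export
study_truth <- function(study) attr(study, "truth")
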