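test_that("gating labels every event exactly once and respects range limits", {
  rng <- lapply(
    stats::setNames(nm = c("FSC", "SSC", "GFP", "RFP")),
    function(ch) c(1, 262144))
  ev <- tibble::tibble(
    FSC = c(262144, 5e4, 1.5e5, 2000), SSC = c(2e4, 2e4, 1.2e5, 800),
    GFP = c(100, 100, 3e4, 20), RFP = c(100, 100, 5e3, 20)
  )
  g <- default_gates()
  out <- gate_events(ev, g$bead, g$debris, instrument_range = rng)
  expect_identical(out$label, c("out_of_range", "cell", "bead", "debris"))
  # partition: labels are exhaustive and exclusive
  expect_identical(sum(table(out$label)), nrow(ev))
  # empty gates, nothing saturated -> all cells
  ev2 <- tibble::tibble(FSC = c(100, 200), SSC = c(50, 60),
                        GFP = c(10, 20), RFP = c(10, 20))
  expect_true(all(gate_events(ev2, instrument_range = rng)$label == "cell"))
  # overlapping boxes are ambiguous
  expect_error(
    gate_events(ev, list(FSC = c(0, 100)), list(FSC = c(50, 200)),
                instrument_range = rng),
    "overlap")
})

test_that("generator gates recover ground-truth labels almost perfectly", {
  plan <- default_fate_plans()[3, ]
  ev <- generate_fcm_sample(plan, "-His", n_cells = 8000, n_beads = 1000,
                            n_debris = 500, seed = 17)
  g <- default_gates()
  out <- gate_events(ev, g$bead, g$debris)
  expect_gte(mean(out$label == out$true_label), 0.99)
})

test_that("bead-based concentration follows the count ratio", {
  ev <- tibble::tibble(label = rep(c("cell", "bead"), c(5000, 1000)))
  expect_equal(concentration(ev, 1e5), 5e5)
  expect_equal(concentration(tibble::tibble(label = "bead"), 1e5), 0)
  expect_error(concentration(tibble::tibble(label = "cell"), 1e5), "bead")

  # planned concentration c recovered within 3 binomial standard errors
  plan <- default_fate_plans()[1, ]
  bead_conc <- 1e5
  n_cells <- 5000; n_beads <- 1000
  planned <- n_cells / n_beads * bead_conc
  ev <- generate_fcm_sample(plan, "+His", n_cells = n_cells,
                            n_beads = n_beads, n_debris = 200, seed = 3)
  g <- default_gates()
  est <- concentration(gate_events(ev, g$bead, g$debris), bead_conc)
  se <- planned * sqrt(1 / n_cells + 1 / n_beads)
  expect_lt(abs(est - planned), 3 * se)
})

test_that("GFP bias is the per-event green/red ratio, scale invariant", {
  expect_equal(gfp_bias(tibble::tibble(GFP = 200, RFP = 100)), 2)
  ev <- tibble::tibble(GFP = c(10, 55, 3), RFP = c(10, 55, 3))
  expect_equal(gfp_bias(ev), rep(1, 3))
  # joint rescaling of both channels cancels
  ev2 <- tibble::tibble(GFP = runif(20, 10, 100), RFP = runif(20, 10, 100))
  ev3 <- dplyr::mutate(ev2, GFP = GFP * 7.3, RFP = RFP * 7.3)
  expect_equal(gfp_bias(ev3), gfp_bias(ev2), tolerance = 1e-12)
  expect_error(gfp_bias(tibble::tibble(GFP = c(1, 2), RFP = c(1, 0))), "RFP")

  # geometric mean of simulated bias matches the generating ratio
  plan <- fate_plan("x", "good", bias_shift = 3, bias_cv_initial = 0.4,
                    bias_cv_final = 0.4)
  ev <- generate_fcm_sample(plan, "-His", n_cells = 10000, n_beads = 0,
                            n_debris = 0, seed = 4, saturation_fraction = 0)
  gm <- exp(mean(log(gfp_bias(ev))))
  expect_equal(gm, 3, tolerance = 0.05)
})

test_that("population statistics average over replicates with honest SEs", {
  const <- tibble::tibble(bias = rep(2, 40), fsc = rep(100, 40),
                          replicate = rep(1:4, each = 10))
  st <- population_stats(const)
  expect_equal(st$sd_bias, 0)
  # one replicate duplicated four times -> zero standard errors
  base <- tibble::tibble(bias = rnorm(50, 5), fsc = rnorm(50, 100))
  dup <- dplyr::bind_rows(lapply(1:4, function(r) dplyr::mutate(base, replicate = r)))
  st2 <- population_stats(dup)
  expect_equal(st2$se_mean_bias, 0)
  expect_equal(st2$se_sd_fsc, 0)
  expect_error(population_stats(const[1, ]), "at least 2")

  # planted CV recovered within 10% at 10000 events x 4 replicates
  plan <- fate_plan("x", "good", bias_shift = 1, bias_cv_initial = 0.35)
  evs <- purrr::map_dfr(1:4, function(r) {
    ev <- generate_fcm_sample(plan, "+His", n_cells = 10000, n_beads = 0,
                              n_debris = 0, seed = 100 + r,
                              saturation_fraction = 0)
    tibble::tibble(bias = gfp_bias(ev), fsc = ev$FSC, replicate = r)
  })
  st3 <- population_stats(evs)
  expect_equal(st3$sd_bias / st3$mean_bias, 0.35, tolerance = 0.1)
})

test_that("growth rate follows ln(Ct/C0)/t with its algebraic identities", {
  expect_equal(growth_rate(5e5, 5e5, 3), 0)
  expect_equal(growth_rate(1e3, exp(1) * 1e3, 1), 1)
  expect_equal(growth_rate(1e3, 1e7, 10), log(1e4) / 10)
  # antisymmetric under swapping C0 and Ct
  expect_equal(growth_rate(2e4, 8e6, 5), -growth_rate(8e6, 2e4, 5))
  # additive over consecutive intervals, weighted by time
  mu1 <- growth_rate(1e3, 1e5, 4); mu2 <- growth_rate(1e5, 1e7, 6)
  expect_equal(growth_rate(1e3, 1e7, 10), (4 * mu1 + 6 * mu2) / 10)
  expect_error(growth_rate(0, 1e5, 2), "positive")
  expect_error(growth_rate(1e3, 1e5, 0), "positive")
})

test_that("the starvation shift test is one-sided with correct direction", {
  a <- replicate_stats(2, 0.2, 4)
  expect_equal(shift_test(a, a, "mean_bias")$p_value, 0.5)
  withr::with_seed(5, {
    lo <- replicate_stats(1, 0.2, 4); hi <- replicate_stats(4, 0.2, 4)
  })
  expect_lt(shift_test(lo, hi, "mean_bias")$p_value, 0.05)
  expect_gt(shift_test(hi, lo, "mean_bias")$p_value, 0.5)
  expect_error(shift_test(a[1:1, ], a, "mean_bias"), "2 replicates")

  # power: planted 4x shift, CV 20%, n = 4 -> detected in >= 80% of runs
  withr::with_seed(77, {
    hits <- vapply(1:1000, function(i) {
      shift_test(replicate_stats(1, 0.2, 4), replicate_stats(4, 0.2, 4),
                 "mean_bias")$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(hits), 0.8)
})

test_that("growth-variation correlation behaves on the log scale", {
  g <- c(0.1, 0.2, 0.4, 0.8)
  expect_equal(growth_variation_correlation(g, g * 3)$r, 1)
  expect_equal(growth_variation_correlation(g, rev(g))$r, -1)
  expect_error(growth_variation_correlation(g, rep(1, 4)), "zero variance")
  expect_error(growth_variation_correlation(g, c(-1, 1, 1, 1)), "positive")
})
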