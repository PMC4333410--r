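make_two_col_study <- function() {
  tiny_study(cbind(c(0, 2), c(2, 4)),
             strains = c("a", "a"), timepoints = c("+His", "-His 2 h"),
             replicates = c(1, 1), genes = c("g1", "g2"))
}

test_that("common-mean normalization equalizes columns and is idempotent", {
  s <- normalize_common_mean(make_two_col_study())
  expect_equal(unname(colMeans(s$matrix)), c(2, 2))
  # already-common means: identity
  expect_equal(normalize_common_mean(s)$matrix, s$matrix)
  # random matrix: all column means equal within 1e-12
  withr::with_seed(3, {
    m <- matrix(rnorm(600, sd = 2), 100, 6)
  })
  s2 <- tiny_study(m, strains = rep("a", 6),
                   timepoints = rep(c("+His", "-His 2 h"), each = 3),
                   replicates = rep(1:3, 2))
  ns <- normalize_common_mean(s2)
  expect_lt(diff(range(colMeans(ns$matrix))), 1e-12)
  # explicit target mean
  nt <- normalize_common_mean(s2, target_mean = 0)
  expect_equal(unname(colMeans(nt$matrix)), rep(0, 6), tolerance = 1e-12)
  s2$matrix[1, 1] <- NA
  expect_error(normalize_common_mean(s2), "non-finite")
})

test_that("low-value filtering drops genes by the chosen quantifier", {
  m <- rbind(g1 = c(0, 1, 1), g2 = c(-2, 1, 1), g3 = c(-2, -2, -2))
  s <- tiny_study(m, strains = rep("a", 3),
                  timepoints = c("+His", "-His 2 h", "-His >10 h"),
                  replicates = c(1, 1, 1))
  s$normalized <- TRUE
  expect_identical(unname(filter_low(s)$retained), c(TRUE, FALSE, FALSE))
  expect_identical(unname(filter_low(s, rule = "all")$retained),
                   c(TRUE, TRUE, FALSE))
  expect_identical(unname(filter_low(s, rule = "mean")$retained),
                   c(TRUE, TRUE, FALSE))
  # nothing below threshold: nothing dropped
  s_ok <- s; s_ok$matrix <- abs(m)
  expect_true(all(filter_low(s_ok)$retained))
  s_all <- s; s_all$matrix <- m - 10
  expect_error(filter_low(s_all), "every gene")
  expect_error(filter_low(make_two_col_study()), "normalized")
})

test_that("planted below-threshold genes are exactly the ones dropped", {
  withr::with_seed(8, {
    n <- 100
    base <- matrix(rnorm(n * 6, mean = 2, sd = 0.3), n, 6)
    low_genes <- sample(n, 10)
    base[cbind(low_genes, sample(6, 10, replace = TRUE))] <- -3
  })
  s <- tiny_study(base, strains = rep("a", 6),
                  timepoints = rep(c("+His", "-His 2 h"), 3),
                  replicates = rep(1:3, each = 2))
  # normalization shifts are tiny relative to the -3 outliers
  f <- filter_low(normalize_common_mean(s, target_mean = 2))
  expect_identical(sort(unname(which(!f$retained))), sort(low_genes))
})

test_that("replicate averaging collapses to one column per condition", {
  m <- rbind(c(1, 2, 3, 5, 5, 5))
  s <- tiny_study(m, strains = rep("a", 6),
                  timepoints = rep(c("+His", "-His 2 h"), each = 3),
                  replicates = rep(1:3, 2), genes = "g1")
  avg <- average_replicates(s)
  expect_equal(unname(avg$matrix[1, ]), c(2, 5))
  # identical replicates unchanged
  expect_equal(unname(avg$matrix[1, 2]), 5)
  # the 90-sample design averages to 30 columns
  study <- generate_expression_study(n_genes = 20, seed = 5)
  expect_identical(ncol(average_replicates(study)$matrix), 30L)
  expect_error(
    average_replicates(s, expected = data.frame(
      strain = "a", timepoint = "-His >10 h")),
    "-His >10 h")
})

test_that("the change matrix has 22 rows under both study presets", {
  avg <- average_replicates(small_pipeline_study(n_genes = 60, seed = 6))
  km <- build_change_matrix(avg)  # {2 h, late} + baselines
  expect_identical(nrow(km), 22L)
  expect_identical(sum(change_conditions(km)$is_baseline), 8L)
  pca_cm <- build_change_matrix(avg, states = timepoint_levels()[2:4],
                                include_baseline = FALSE)
  expect_identical(nrow(pca_cm), 22L)
  # baselines are exactly zero
  expect_true(all(km[change_conditions(km)$is_baseline, ] == 0))
  # a growing strain missing a requested state is an error
  drop_cols <- !(avg$samples$strain == "hisB" &
                   avg$samples$timepoint == "-His >10 h")
  crippled <- expression_study(avg$matrix[, drop_cols],
                               avg$samples[drop_cols, ])
  crippled$normalized <- TRUE; crippled$averaged <- TRUE
  expect_error(
    build_change_matrix(crippled, failures = c("hisD", "hisG")),
    "hisB")
})

test_that("change values cancel gene-specific baselines", {
  avg <- average_replicates(small_pipeline_study(n_genes = 30, seed = 10))
  cm1 <- build_change_matrix(avg)
  shifted <- avg
  shifted$matrix <- avg$matrix + rnorm(nrow(avg$matrix))  # per-gene constant
  cm2 <- build_change_matrix(shifted)
  expect_equal(unclass(cm1), unclass(cm2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("filtering then re-normalizing reaches the normalization fixed point", {
  withr::with_seed(12, {
    m <- matrix(rnorm(300, 1, 1.5), 50, 6)
  })
  s <- tiny_study(m, strains = rep("a", 6),
                  timepoints = rep(c("+His", "-His 2 h"), 3),
                  replicates = rep(1:3, each = 2))
  a <- s |> normalize_common_mean(target_mean = 1) |> filter_low() |>
    normalize_common_mean(target_mean = 1)
  b <- a |> normalize_common_mean(target_mean = 1)
  expect_equal(a$matrix, b$matrix, tolerance = 1e-12)
  expect_lt(diff(range(colMeans(retained_matrix(a)))), 1e-9)
})

test_that("expression studies survive a TSV round trip", {
  study <- generate_expression_study(n_genes = 15, seed = 3)
  mp <- withr::local_tempfile(fileext = ".tsv")
  sp <- withr::local_tempfile(fileext = ".tsv")
  write_expression_study(study, mp, sp)
  back <- read_expression_study(mp, sp)
  expect_equal(back$matrix, study$matrix, tolerance = 1e-6)
  expect_identical(back$samples$strain, study$samples$strain)
})
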