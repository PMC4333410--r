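ranked_matrix <- function(n = 12, p = 40, seed = 5) {
  withr::with_seed(seed, matrix(rnorm(n * p), n, p,
                                dimnames = list(NULL, sprintf("g%03d", 1:p))))
}

test_that("PCA of the change matrix matches an eigendecomposition oracle", {
  x <- ranked_matrix(8, 10)
  model <- pca_trajectory(x, n_components = 5)
  or <- oracle_pca(x)
  expect_equal(model$variance_fraction,
               or$variance_fraction[1:5], tolerance = 1e-8)
  for (k in 1:5) {
    expect_equal(abs(sum(model$loadings[, k] * or$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  # variance fractions sum to <= 1 and are non-increasing
  expect_lte(sum(model$variance_fraction), 1 + 1e-12)
  expect_true(all(diff(model$variance_fraction) <= 1e-12))
  expect_error(pca_trajectory(x, n_components = 50), "exceeds")
  expect_error(pca_trajectory(x[1:2, ]), "at least 3")
})

test_that("a rank-one matrix concentrates all variance on PC1 and reconstructs", {
  s <- c(0, 0.5, 1, 2, 3)
  g <- rnorm(30); g <- g / sqrt(sum(g^2))
  x <- outer(s, g)
  model <- pca_trajectory(x, n_components = 3)
  expect_equal(model$variance_fraction[1], 1, tolerance = 1e-9)
  # full-rank reconstruction: scores %*% t(loadings) + centering
  x2 <- ranked_matrix(6, 9)
  m2 <- pca_trajectory(x2, n_components = 6)
  rec <- m2$scores %*% t(m2$loadings)
  rec <- sweep(rec, 2, m2$center, "+")
  expect_equal(rec, x2, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("PC correlations respect inclusion rules", {
  x <- ranked_matrix(10, 20)
  model <- pca_trajectory(x, n_components = 3)
  # collinear planted scores
  model2 <- model
  model2$scores[, 2] <- -2 * model2$scores[, 1]
  expect_equal(abs(pc_correlation(model2)$r), 1)
  model$conditions$is_failure <- c(rep(FALSE, 8), TRUE, TRUE)
  r_all <- pc_correlation(model)$n
  r_surv <- pc_correlation(model, exclude_failures = TRUE)$n
  expect_identical(c(r_all, r_surv), c(10L, 8L))
  expect_error(
    pc_correlation(model, exclude = model$conditions$condition[1:8]),
    "fewer than 3")
})

test_that("the TLS path fit recovers exact lines and refuses isotropy", {
  # points exactly on y = -x
  x <- seq(-2, 2, length.out = 8)
  scores <- cbind(x, -x)
  model <- list(scores = scores, loadings = diag(2),
                center = c(0, 0),
                conditions = tibble::tibble(
                  condition = as.character(1:8), strain = "s",
                  timepoint = "-His 2 h", is_baseline = FALSE,
                  is_failure = FALSE, growth_rate = NA_real_))
  class(model) <- "trajectory_model"
  line <- fit_path(model, pair = c(1, 2))
  expect_equal(line$slope, -1, tolerance = 1e-12)
  expect_equal(line$intercept, 0, tolerance = 1e-12)
  # swapping the axes inverts the line algebraically
  model_sw <- model
  model_sw$scores <- scores[, 2:1]
  line_sw <- fit_path(model_sw, pair = c(1, 2))
  expect_equal(line_sw$slope, 1 / line$slope, tolerance = 1e-12)
  # isotropic cloud: direction undefined
  iso <- model
  iso$scores <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  iso$conditions <- iso$conditions[1:4, ]
  expect_error(fit_path(iso, pair = c(1, 2)), "isotropic")
})

test_that("TLS slope is recovered from noisy planted lines across seeds", {
  slopes <- vapply(1:100, function(i) {
    withr::with_seed(1000 + i, {
      t <- runif(15, -3, 3)
      pts <- cbind(t, -0.8 * t + 0.5) +
        matrix(rnorm(30, sd = 0.05), 15, 2)
    })
    model <- list(scores = pts, loadings = diag(2), center = c(0, 0),
                  conditions = tibble::tibble(
                    condition = as.character(1:15), strain = "s",
                    timepoint = "-His 2 h", is_baseline = FALSE,
                    is_failure = FALSE, growth_rate = NA_real_))
    class(model) <- "trajectory_model"
    fit_path(model, pair = c(1, 2))$slope
  }, numeric(1))
  expect_equal(mean(slopes), -0.8, tolerance = 0.02)
  expect_lt(sd(slopes), 0.05)
})

test_that("normalized distances span [0, 1] and preserve planted order", {
  study <- small_pipeline_study(n_genes = 400, seed = 31)
  avg <- average_replicates(study)
  cm <- build_change_matrix(avg, states = timepoint_levels()[2:4],
                            include_baseline = FALSE)
  model <- pca_trajectory(cm)
  line <- fit_path(model)
  nd <- normalized_distance(model, line)
  inc <- nd$included
  expect_equal(min(nd$distance[inc]), 0)
  expect_equal(max(nd$distance[inc]), 1)
  truth <- study_truth(study)$progress
  s <- truth$progress[match(paste(nd$strain, nd$timepoint),
                            paste(truth$strain, truth$timepoint))]
  expect_gte(cor(nd$distance[inc], s[inc], method = "spearman"), 0.95)
  # a point already on the line projects to itself (zero residual)
  on_line <- which.min(nd$residual)
  expect_lt(nd$residual[on_line], 0.5)
})

test_that("distances and tails are invariant to PC sign flips and rescaling", {
  study <- small_pipeline_study(n_genes = 300, seed = 17)
  cm <- build_change_matrix(average_replicates(study),
                            states = timepoint_levels()[2:4],
                            include_baseline = FALSE)
  model <- pca_trajectory(cm)
  nd <- normalized_distance(model)
  tails <- loading_tails(path_loadings(model))
  for (flip in list(c(-1, 1), c(1, -1), c(-1, -1))) {
    fm <- model
    fm$scores[, 1:2] <- sweep(fm$scores[, 1:2], 2, flip, "*")
    fm$loadings[, 1:2] <- sweep(fm$loadings[, 1:2], 2, flip, "*")
    nd_f <- normalized_distance(fm)
    expect_equal(nd_f$distance, nd$distance, tolerance = 1e-9)
    tails_f <- loading_tails(path_loadings(fm))
    expect_identical(tails_f$positive, tails$positive)
    expect_identical(tails_f$negative, tails$negative)
  }
  # joint affine rescaling of the score plane leaves distances unchanged
  sm <- model
  sm$scores <- model$scores * 3.7
  sm$loadings <- model$loadings           # same directions
  sm$center <- model$center * 3.7
  nd_s <- normalized_distance(sm)
  expect_equal(nd_s$distance, nd$distance, tolerance = 1e-9)
})

test_that("growth correlates with distance when planted, not when shuffled", {
  study <- small_pipeline_study(n_genes = 400, seed = 23)
  cm <- build_change_matrix(average_replicates(study),
                            states = timepoint_levels()[2:4],
                            include_baseline = FALSE)
  model <- pca_trajectory(cm)
  nd <- normalized_distance(model)
  gd <- growth_distance_correlation(nd)
  expect_gt(gd$r, 0.8)
  # strictly affine growth gives r = 1
  nd2 <- nd
  nd2$growth_rate <- 0.1 + 0.5 * nd2$distance
  expect_equal(growth_distance_correlation(nd2)$r, 1, tolerance = 1e-12)
  # permutation null is centred at zero
  keep <- !is.na(nd$growth_rate) & nd$timepoint != "-His 10 min"
  withr::with_seed(4, {
    null_r <- vapply(1:300, function(i) {
      cor(nd$distance[keep], sample(nd$growth_rate[keep]))
    }, numeric(1))
  })
  expect_lt(abs(mean(null_r)), 0.05)
})

test_that("path loadings take the stated tail sizes with stable ties", {
  study <- small_pipeline_study(n_genes = 100, seed = 41)
  cm <- build_change_matrix(average_replicates(study),
                            states = timepoint_levels()[2:4],
                            include_baseline = FALSE)
  model <- pca_trajectory(cm)
  pl <- path_loadings(model, tail_fraction = 0.05)
  tails <- loading_tails(pl)
  expect_identical(lengths(tails), c(positive = 5L, negative = 5L))
  expect_error(path_loadings(model, tail_fraction = 0.7), "tail_fraction")
  expect_error(path_loadings(model, tail_fraction = 0), "tail_fraction")

  # noise-free construction: positive tail = genes with largest g components
  fates <- default_fate_plans()
  traj <- default_trajectory_plan(fates, n_genes = 100, seed = 2,
                                  support_fraction = 0.3,
                                  noise_sd = 0, growth_noise_sd = 0)
  clean <- generate_expression_study(fates, traj, n_genes = 100, seed = 3) |>
    normalize_common_mean()
  ccm <- build_change_matrix(average_replicates(clean),
                             states = timepoint_levels()[2:4],
                             include_baseline = FALSE)
  cmod <- pca_trajectory(ccm)
  cpl <- path_loadings(cmod)
  g <- study_truth(clean)$direction[cpl$gene]
  top_true <- names(sort(g, decreasing = TRUE))[1:5]
  expect_setequal(loading_tails(cpl)$positive, top_true)
})
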