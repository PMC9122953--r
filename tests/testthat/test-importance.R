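# PCA signal extraction, Boruta relevance testing, and variable ranking.

test_that("median imputation fills gaps and keeps the mask", {
  env <- data.frame(a = c(1, 2, NA, 4), b = c(1, 1, 1, 1.5))
  out <- impute_missing(env)
  expect_equal(out$a, c(1, 2, 2, 4))
  expect_equal(sum(attr(out, "miss_mask")), 1)

  clean <- impute_missing(env[1:2, ])
  expect_equal(as.matrix(clean), as.matrix(env[1:2, ]))

  allna <- data.frame(a = c(NA_real_, NA_real_), b = c(1, 2))
  expect_error(impute_missing(allna), "entirely missing")

  ## external medians take precedence (training-partition imputation)
  out2 <- impute_missing(env, medians = c(a = 99, b = 0))
  expect_equal(out2$a[3], 99)
})

test_that("PCA is centered, scaled, orthonormal, with a fixed sign convention", {
  set.seed(1)
  x <- data.frame(a = rnorm(50))
  x$b <- 2 * x$a + 5                         # perfectly correlated pair
  p <- fit_pca(x)
  expect_equal(p$variance_explained[1], 1, tolerance = 1e-12)

  set.seed(2)
  big <- as.data.frame(matrix(rnorm(3000), 300, 10))
  pb <- fit_pca(big)
  expect_true(all(abs(crossprod(pb$loadings) - diag(10)) < 1e-8))
  expect_true(all(diff(pb$variance_explained) < 1e-12))
  expect_equal(sum(pb$variance_explained), 1, tolerance = 1e-8)
  ## isotropic data spreads variance roughly evenly
  expect_true(all(abs(pb$variance_explained - 0.1) < 0.05))
  ## sign convention: dominant loading positive
  expect_true(all(apply(pb$loadings, 2, function(v) v[which.max(abs(v))]) > 0))

  degen <- data.frame(a = rnorm(20), b = rep(1, 20))
  expect_error(fit_pca(degen), "zero-variance.*b")
})

test_that("component retention uses the worst-case partition", {
  fake <- function(ve) structure(list(variance_explained = ve),
                                 class = "pc_model")
  expect_equal(retain_pcs(fake(c(0.6, 0.35, 0.04, 0.01))), 3)
  expect_equal(retain_pcs(fake(c(0.6, 0.35, 0.04, 0.01)), threshold = 1), 4)
  ## partitions needing k = 3 and k = 5: the max wins
  expect_equal(retain_pcs(list(fake(c(0.6, 0.35, 0.04, 0.01)),
                               fake(c(0.4, 0.3, 0.2, 0.05, 0.05)))), 5)
})

test_that("variable R-squared is the squared loading matrix", {
  id <- structure(list(loadings = diag(3)), class = "pc_model")
  expect_equal(variable_r2(id), diag(3))

  rot <- structure(list(loadings = matrix(sqrt(0.5) * c(1, 1, 1, -1), 2)),
                   class = "pc_model")
  expect_true(all(abs(variable_r2(rot) - 0.5) < 1e-12))

  set.seed(3)
  p <- fit_pca(as.data.frame(matrix(rnorm(1200), 60, 20)))
  expect_true(all(abs(rowSums(variable_r2(p)) - 1) < 1e-8))
})

test_that("rank contributions weight squared loadings by PC importance", {
  r2 <- matrix(c(0.8, 0.3, 0.1, 0.6), 2,
               dimnames = list(c("v1", "v2"), c("PC1", "PC2")))
  rk <- rank_variables(r2, c(PC1 = 0.7, PC2 = 0.3))
  expect_equal(unname(rk$contribution), c(0.59, 0.39), tolerance = 1e-12)
  expect_equal(names(rk$contribution), c("v1", "v2"))
  expect_equal(rk$kept, c("v1", "v2"))

  ## single confirmed PC: ranking collapses to the squared loading order
  rk1 <- rank_variables(r2, c(PC2 = 1))
  expect_equal(names(rk1$contribution), c("v2", "v1"))
  expect_equal(rk1$kept, c("v2", "v1"))  # v1 sits exactly at the 0.1 threshold
  rk_strict <- rank_variables(r2, c(PC2 = 1), keep_threshold = 0.2)
  expect_equal(rk_strict$kept, "v2")

  expect_error(rank_variables(r2, numeric()), "confirmed")
  expect_error(rank_variables(r2, c(bad = 1)), "named")
})

test_that("pearson screen reports correlations over pairwise-complete pairs", {
  x <- seq_len(30)
  res <- pearson_screen(x, data.frame(same = x, anti = -x))
  expect_equal(res$r, c(1, -1), tolerance = 1e-12)
  expect_true(all(res$p < 1e-20))

  res2 <- pearson_screen(x, data.frame(flat = rep(1, 30),
                                       gappy = c(NA, x[-1])))
  expect_true(res2$degenerate[1])
  expect_equal(res2$n[2], 29)
})

test_that("boruta separates signal from noise and is deterministic", {
  set.seed(10)
  x <- matrix(rnorm(3000), 300, 10,
              dimnames = list(NULL, paste0("x", 1:10)))
  y <- 3 * x[, 1] + rnorm(300, 0, 0.5)
  b <- boruta(x, y, num_trees = 100, max_iter = 40, seed = 4)
  expect_equal(unname(b$decision["x1"]), "confirmed")
  expect_gte(sum(b$decision[-1] == "rejected"), 7)

  b2 <- boruta(x, y, num_trees = 100, max_iter = 40, seed = 4)
  expect_identical(b$decision, b2$decision)
  expect_identical(b$history, b2$history)

  ## duplicated informative feature: both confirmed (all-relevant behavior)
  xx <- cbind(x[, 1:5], dup = x[, 1])
  bd <- boruta(xx, y, num_trees = 100, max_iter = 40, seed = 5)
  expect_equal(unname(bd$decision[c("x1", "dup")]),
               c("confirmed", "confirmed"))

  expect_error(boruta(x, rep(1, 300)), "constant")
  expect_error(boruta(x, y, alpha = 2), "alpha")
})

test_that("nested cross-validation recovers a noiseless signal and is reproducible", {
  sim <- simulate_env(env_sim_spec(150, noise_sd = 0, missing_rate = 0.02,
                                   seed = 21))
  rep1 <- nested_cv_train(sim$env, sim$response, cv_folds = 5, seed = 21,
                          num_trees = 200, boruta_trees = 100,
                          boruta_max_iter = 25)
  expect_gte(rep1$holdout_r2, 0.75)
  expect_true(all(sim$truth$signal_names %in% rep1$kept_variables))

  rep2 <- nested_cv_train(sim$env, sim$response, cv_folds = 5, seed = 21,
                          num_trees = 200, boruta_trees = 100,
                          boruta_max_iter = 25)
  expect_identical(rep1$rank_contribution, rep2$rank_contribution)
  expect_identical(rep1$holdout_r2, rep2$holdout_r2)

  expect_error(nested_cv_train(sim$env[1:30, ], sim$response[1:30]),
               "at least")
})
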