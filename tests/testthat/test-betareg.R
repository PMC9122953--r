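# Tercile binning, beta regression likelihood fitting, and marginal means.

test_that("tercile binning matches the fixed nitrite breakpoints", {
  ## published nitrite cuts (umol/kg): Lo <= 0.040 < Md <= 0.073 < Hi
  nit <- c(0.001, 0.05, 0.2)
  bins <- tercile_bin(nit, breaks = c(0.040, 0.073))
  expect_equal(as.character(bins), c("Lo", "Md", "Hi"))
  expect_equal(attr(bins, "rule"), "fixed")

  nine <- tercile_bin(c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  expect_equal(as.integer(table(nine)), c(3L, 3L, 3L))

  expect_error(tercile_bin(rep(2, 10)), "identical")
  expect_warning(tercile_bin(c(1, 1, 1, 1, 5, 9)), "tied")
})

test_that("unit-interval squeeze pulls boundaries inside (0, 1)", {
  expect_equal(squeeze_unit_interval(0, n = 100), 0.005)
  expect_equal(squeeze_unit_interval(1, n = 100), 0.995)
  expect_equal(squeeze_unit_interval(0.5, n = 17), 0.5)
  y <- squeeze_unit_interval(c(0, 0.2, 1))
  expect_true(all(y > 0 & y < 1))
  expect_error(squeeze_unit_interval(0.5, n = 1), "at least 2")
})

test_that("intercept-only fit recovers mean and precision", {
  d <- data.frame(y = simulate_beta_response(data.frame(one = rep(1, 2000)),
                                             c(qlogis(0.3), 0), precision = 20,
                                             formula = ~ one, seed = 9))
  fit <- fit_beta_regression(y ~ 1, d)
  expect_gt(plogis(coef(fit)[1]), 0.28)
  expect_lt(plogis(coef(fit)[1]), 0.32)
  expect_gt(fit$precision_phi, 17)
  expect_lt(fit$precision_phi, 23)
})

test_that("the fitted likelihood dominates the generating parameters", {
  d <- expand.grid(a = factor(c("x", "y", "z")))
  d <- d[rep(1:3, each = 80), , drop = FALSE]
  cf <- c(-1, 0.6, -0.4)
  d$y <- simulate_beta_response(d, cf, precision = 30, formula = ~ a, seed = 2)
  fit <- fit_beta_regression(y ~ a, d)
  X <- model.matrix(~ a, d)
  ll_true <- sum(dbeta(d$y, plogis(X %*% cf) * 30,
                       (1 - plogis(X %*% cf)) * 30, log = TRUE))
  expect_gte(fit$loglik, ll_true - 1e-6)
})

test_that("degenerate designs and boundary responses are rejected", {
  d <- data.frame(y = c(0.2, 0.4, 0.6), a = factor(c("u", "u", "u")),
                  dup = c(1, 1, 1))
  expect_error(fit_beta_regression(y ~ a, d), "rank-deficient|contrasts")
  d2 <- data.frame(y = c(0, 0.5, 0.9), x = 1:3)
  expect_error(fit_beta_regression(y ~ x, d2), "strictly inside")
})

test_that("the fit agrees with an independent beta-likelihood implementation", {
  skip_if_not_installed("glmmTMB")
  d <- expand.grid(nit = factor(c("Lo", "Md", "Hi"), c("Lo", "Md", "Hi")),
                   dcm = factor(c("S", "M", "D"), c("S", "M", "D")))
  d <- d[rep(1:9, each = 40), ]
  cf <- c(-2, 0.5, 1, 0.3, 0.6, 0.2, 0.4, -0.1, 0.3)
  d$y <- simulate_beta_response(d, cf, precision = 50,
                                formula = ~ nit * dcm, seed = 13)
  fit <- fit_beta_regression(y ~ nit * dcm, d)
  ref <- glmmTMB::glmmTMB(y ~ nit * dcm, data = d,
                          family = glmmTMB::beta_family())
  expect_equal(unname(coef(fit)), unname(glmmTMB::fixef(ref)$cond),
               tolerance = 1e-4)
  expect_equal(fit$precision_phi, glmmTMB::sigma(ref), tolerance = 1e-3)
  expect_equal(unname(vcov(fit)), unname(as.matrix(vcov(ref)$cond)),
               tolerance = 1e-4)
})

test_that("model methods behave like a standard fitted model", {
  d <- data.frame(g = factor(rep(c("a", "b"), each = 100)))
  d$y <- simulate_beta_response(d, c(-1, 0.8), precision = 30, seed = 3)
  fit <- fit_beta_regression(y ~ g, d)
  expect_length(coef(fit), 2)
  expect_equal(dim(vcov(fit)), c(2, 2))
  expect_s3_class(summary(fit), "summary.betareg_fit")
  expect_equal(attr(logLik(fit), "df"), 3)
  pr <- predict(fit, data.frame(g = factor(c("a", "b"))))
  expect_true(all(pr > 0 & pr < 1))
  expect_equal(predict(fit)[1], fitted(fit)[1])
  expect_length(residuals(fit, "pearson"), 200)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(200, 2))
})

test_that("marginal means average on the link scale with delta-method intervals", {
  d <- expand.grid(nit = factor(c("Lo", "Md", "Hi"), c("Lo", "Md", "Hi")),
                   dcm = factor(c("S", "M", "D"), c("S", "M", "D")))
  d <- d[rep(1:9, each = 50), ]

  ## no-noise limit: marginal means equal cell sample means to 3 decimals
  cf <- c(-1.5, 0.4, 0.9, 0.2, 0.5, 0.1, 0.3, -0.2, 0.25)
  d$y <- simulate_beta_response(d, cf, precision = 1e6,
                                formula = ~ nit * dcm, seed = 4)
  fit <- fit_beta_regression(y ~ nit * dcm, d)
  mm <- marginal_means(fit, "nit", by = "dcm")
  cell_means <- tapply(d$y, interaction(d$nit, d$dcm, sep = " | ",
                                        lex.order = TRUE), mean)
  expect_equal(mm$means$mean, as.numeric(cell_means[mm$means$cell]),
               tolerance = 5e-4)
  expect_true(all(mm$means$ci_low < mm$means$mean &
                  mm$means$mean < mm$means$ci_high))

  ## all-zero coefficients: every marginal mean is one half
  d0 <- d
  d0$y <- simulate_beta_response(d0, rep(0, 9), precision = 1e5,
                                 formula = ~ nit * dcm, seed = 5)
  fit0 <- fit_beta_regression(y ~ nit * dcm, d0)
  mm0 <- marginal_means(fit0, "nit")
  expect_true(all(abs(mm0$means$mean - 0.5) < 0.01))

  ## balanced design, no interaction: marginal mean is the main effect
  d1 <- d
  d1$y <- simulate_beta_response(d1, c(-1, 0.5, 1), precision = 1e5,
                                 formula = ~ nit, seed = 6)
  fit1 <- fit_beta_regression(y ~ nit + dcm, d1)
  mm1 <- marginal_means(fit1, "nit")
  eta <- coef(fit1)["(Intercept)"] +
    c(0, coef(fit1)["nitMd"], coef(fit1)["nitHi"]) +
    mean(c(0, coef(fit1)["dcmM"], coef(fit1)["dcmD"]))
  expect_equal(mm1$means$mean, unname(plogis(eta)), tolerance = 1e-10)
})

test_that("marginal means match an independent reference implementation", {
  skip_if_not_installed("glmmTMB")
  skip_if_not_installed("emmeans")
  d <- expand.grid(nit = factor(c("Lo", "Md", "Hi"), c("Lo", "Md", "Hi")),
                   dcm = factor(c("S", "M", "D"), c("S", "M", "D")))
  d <- d[rep(1:9, each = 30), ]
  d$y <- simulate_beta_response(d, c(-2, .5, 1, .3, .6, .2, .4, -.1, .3),
                                precision = 50, formula = ~ nit * dcm,
                                seed = 7)
  fit <- fit_beta_regression(y ~ nit * dcm, d)
  mm <- marginal_means(fit, "nit")
  ref <- glmmTMB::glmmTMB(y ~ nit * dcm, data = d,
                          family = glmmTMB::beta_family())
  em <- summary(emmeans::emmeans(ref, ~ nit), type = "response")
  expect_equal(mm$means$mean, em$response, tolerance = 1e-4)
  expect_equal(mm$means$ci_low, em$asymp.LCL, tolerance = 1e-4)
  expect_equal(mm$means$ci_high, em$asymp.UCL, tolerance = 1e-4)
})

test_that("parametric bootstrap intervals track the delta-method intervals", {
  d <- data.frame(g = factor(rep(c("a", "b"), each = 150)))
  d$y <- simulate_beta_response(d, c(-1, 0.6), precision = 40, seed = 11)
  fit <- fit_beta_regression(y ~ g, d)
  delta <- marginal_means(fit, "g")$means
  boot <- marginal_means(fit, "g", ci = "boot", boot_B = 200,
                         boot_seed = 2)$means
  expect_equal(boot$mean, delta$mean)
  expect_equal(boot$ci_low, delta$ci_low, tolerance = 0.15)
  expect_equal(boot$ci_high, delta$ci_high, tolerance = 0.15)
  expect_true(all(boot$ci_low < boot$mean & boot$mean < boot$ci_high))
})

test_that("link monotonicity: raising a coefficient raises its cell mean", {
  d <- expand.grid(nit = factor(c("Lo", "Md", "Hi"), c("Lo", "Md", "Hi")))
  d <- d[rep(1:3, each = 60), , drop = FALSE]
  d$y <- simulate_beta_response(d, c(-1, 0.4, 0.8), precision = 40,
                                formula = ~ nit, seed = 8)
  fit <- fit_beta_regression(y ~ nit, d)
  bumped <- fit
  bumped$coefficients["nitHi"] <- bumped$coefficients["nitHi"] + 0.5
  m0 <- marginal_means(fit, "nit")$means
  m1 <- marginal_means(bumped, "nit")$means
  expect_gt(m1$mean[m1$cell == "Hi"], m0$mean[m0$cell == "Hi"])
  expect_equal(m1$mean[m1$cell == "Lo"], m0$mean[m0$cell == "Lo"])
})

test_that("fits are invariant to row order", {
  d <- data.frame(g = factor(rep(c("a", "b", "c"), each = 50)))
  d$y <- simulate_beta_response(d, c(-1, 0.5, 1), precision = 30, seed = 10)
  f1 <- fit_beta_regression(y ~ g, d)
  f2 <- fit_beta_regression(y ~ g, d[rev(seq_len(nrow(d))), ])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$precision_phi, f2$precision_phi, tolerance = 1e-5)
})
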