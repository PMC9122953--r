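# Beta regression of trait fractions on binned covariates, with estimated
# marginal means. The mean is linked to the linear predictor by the logit
# and a single precision parameter phi governs dispersion: y ~
# Beta(mu * phi, (1 - mu) * phi).

#' Tercile binning of a continuous covariate
#'
#' Splits a continuous variable into three roughly equally sized groups at
#' its empirical 1/3 and 2/3 quantiles (type 7), or at fixed breakpoints.
#' Intervals are left-open, right-closed, except the lowest which includes
#' the minimum.
#'
#' @param x numeric vector (non-finite values are carried through as `NA`).
#' @param breaks optional length-2 ascending breakpoints for fixed binning
#'   (e.g. the nitrite cuts `c(0.040, 0.073)` in micromolar units).
#' @param labels category labels, low to high.
#' @return factor of bin assignments with attributes `breaks` and `rule`.
#' @export
#' @examples
#' tercile_bin(c(0.01, 0.05, 0.2), breaks = c(0.040, 0.073))
tercile_bin <- function(x, breaks = NULL, labels = c("Lo", "Md", "Hi")) {
  xf <- x[is.finite(x)]
  if (length(xf) < 3 && is.null(breaks)) abort("need at least 3 finite values")
  rule <- if (is.null(breaks)) "tercile" else "fixed"
  if (is.null(breaks)) {
    if (length(unique(xf)) == 1) abort("all values identical; no spread to bin")
    breaks <- stats::quantile(xf, c(1 / 3, 2 / 3), type = 7, names = FALSE)
    ## heavy ties at a breakpoint make equal groups impossible
    for (b in breaks) {
      if (mean(xf == b) >= 1 / 3) {
        warning("more than a third of values tied at breakpoint ",
                signif(b, 4), "; groups will be unequal")
        break
      }
    }
  }
  if (length(breaks) != 2 || diff(breaks) < 0) {
    abort("`breaks` must be two ascending values")
  }
  cuts <- c(min(xf, na.rm = TRUE) - .Machine$double.eps * 10, breaks, Inf)
  out <- cut(x, cuts, labels = labels, right = TRUE)
  attr(out, "breaks") <- breaks
  attr(out, "rule") <- rule
  out
}

#' Squeeze fractions off the unit-interval boundary
#'
#' The beta likelihood is undefined at exactly 0 or 1; the standard
#' transformation `(y * (n - 1) + 0.5) / n` pulls observations slightly
#' toward 1/2.
#'
#' @param y fractions in \[0, 1\].
#' @param n sample size governing the squeeze (default `length(y)`).
#' @return fractions strictly inside (0, 1).
#' @export
squeeze_unit_interval <- function(y, n = length(y)) {
  if (n < 2) abort("`n` must be at least 2")
  assert_fraction(y, "y")
  (y * (n - 1) + 0.5) / n
}

beta_negloglik <- function(par, X, y) {
  beta <- par[-length(par)]
  phi <- exp(par[length(par)])
  mu <- stats::plogis(drop(X %*% beta))
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

beta_negloglik_grad <- function(par, X, y) {
  beta <- par[-length(par)]
  phi <- exp(par[length(par)])
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ystar <- stats::qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  dmu_deta <- mu * (1 - mu)
  gbeta <- -phi * drop(crossprod(X, (ystar - mustar) * dmu_deta))
  dphi <- sum(mu * (ystar - mustar) + log(1 - y) -
                digamma((1 - mu) * phi) + digamma(phi))
  c(gbeta, -dphi * phi)
}

#' Beta regression with logit mean link
#'
#' Fits a fixed-precision beta regression by maximum likelihood: the mean
#' follows `inverse-logit(X beta)` and the precision `phi` is constant.
#' Optimization is quasi-Newton (BFGS with analytic gradients) from a
#' logit-linear least-squares start; the coefficient covariance comes from
#' the inverse observed information (numerical Hessian at the optimum).
#'
#' @param formula model formula for the mean (e.g.
#'   `f_sidero ~ nitrite_bin * dcm_bin`).
#' @param data data frame holding the response (strictly inside (0, 1);
#'   see [squeeze_unit_interval()]) and covariates.
#' @param max_restarts extra optimization attempts from perturbed starts
#'   if the first does not converge.
#' @return an object of class `betareg_fit` with methods `print`,
#'   `summary`, `coef`, `vcov`, `logLik`, `predict`, `fitted`,
#'   `residuals`, `simulate`, and `plot`.
#' @export
#' @examples
#' d <- data.frame(g = factor(rep(c("a", "b"), each = 50)))
#' d$y <- simulate_beta_response(d, c(-1, 0.8), precision = 30, seed = 3)
#' fit <- fit_beta_regression(y ~ g, d)
#' summary(fit)
fit_beta_regression <- function(formula, data, max_restarts = 3) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  if (any(y <= 0 | y >= 1)) {
    abort("response must lie strictly inside (0, 1); see squeeze_unit_interval()")
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    abort("design is rank-deficient; aliased term(s): %s",
          paste(aliased, collapse = ", "))
  }

  ## start: logit-scale least squares + moment estimate of phi
  beta0 <- stats::lm.fit(X, stats::qlogis(y))$coefficients
  mu0 <- stats::plogis(drop(X %*% beta0))
  resid_var <- stats::var(y - mu0)
  phi0 <- max(1, mean(mu0 * (1 - mu0)) / max(resid_var, 1e-10) - 1)
  par0 <- c(beta0, log_phi = log(phi0))

  fit <- NULL
  for (attempt in 0:max_restarts) {
    start <- if (attempt == 0) par0 else
      par0 + stats::rnorm(length(par0), 0, 0.25 * attempt)
    res <- try(stats::optim(start, beta_negloglik, beta_negloglik_grad,
                            X = X, y = y, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-12)),
               silent = TRUE)
    if (!inherits(res, "try-error") && res$convergence == 0) { fit <- res; break }
  }
  if (is.null(fit)) {
    abort("beta regression did not converge after %d restarts (n = %d, %d terms)",
          max_restarts, length(y), ncol(X))
  }
  hess <- stats::optimHess(fit$par, beta_negloglik, beta_negloglik_grad,
                           X = X, y = y)
  vcov_full <- tryCatch(solve(hess), error = function(e) {
    warning("observed information is singular; using pseudo-inverse")
    ev <- eigen(hess, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos] %*% (t(ev$vectors[, pos]) / ev$values[pos])
  })
  k <- ncol(X)
  coefs <- fit$par[seq_len(k)]
  names(coefs) <- colnames(X)
  structure(list(
    coefficients = coefs,
    precision_phi = unname(exp(fit$par[k + 1])),
    vcov = structure(vcov_full[seq_len(k), seq_len(k), drop = FALSE],
                     dimnames = list(colnames(X), colnames(X))),
    vcov_full = vcov_full,
    loglik = -fit$value,
    n = length(y),
    converged = TRUE,
    formula = formula,
    terms = stats::terms(mf),
    xlevels = stats::.getXlevels(stats::terms(mf), mf),
    contrasts = attr(X, "contrasts"),
    model = mf,
    fitted = stats::plogis(drop(X %*% coefs)),
    y = y
  ), class = "betareg_fit")
}

#' @export
print.betareg_fit <- function(x, ...) {
  cat("Beta regression (logit link, constant precision)\n")
  cat("Coefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("phi = %.3f, log-likelihood = %.2f, n = %d\n",
              x$precision_phi, x$loglik, x$n))
  invisible(x)
}

#' @export
coef.betareg_fit <- function(object, ...) object$coefficients

#' @export
vcov.betareg_fit <- function(object, ...) object$vcov

#' @export
logLik.betareg_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' @export
fitted.betareg_fit <- function(object, ...) object$fitted

#' @export
summary.betareg_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, phi = object$precision_phi,
              loglik = object$loglik, n = object$n)
  class(out) <- "summary.betareg_fit"
  out
}

#' @export
print.summary.betareg_fit <- function(x, ...) {
  cat("Beta regression (logit link)\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nPrecision phi: %.3f   log-likelihood: %.2f   n: %d\n",
              x$phi, x$loglik, x$n))
  invisible(x)
}

betareg_design <- function(object, newdata) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  stats::model.matrix(tt, mf, contrasts.arg = object$contrasts)
}

#' @export
predict.betareg_fit <- function(object, newdata = NULL,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) {
    stats::qlogis(object$fitted)
  } else {
    drop(betareg_design(object, newdata) %*% object$coefficients)
  }
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
residuals.betareg_fit <- function(object,
                                  type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") {
    v <- object$fitted * (1 - object$fitted) / (1 + object$precision_phi)
    r <- r / sqrt(v)
  }
  r
}

#' @export
simulate.betareg_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  phi <- object$precision_phi
  as.data.frame(replicate(nsim, stats::rbeta(object$n, object$fitted * phi,
                                             (1 - object$fitted) * phi)))
}

#' @export
plot.betareg_fit <- function(x, ...) {
  graphics::plot(x$fitted, residuals(x, "pearson"),
                 xlab = "fitted mean", ylab = "Pearson residual", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Estimated marginal means from a beta regression
#'
#' For each level of `factor_name`, averages the linear predictor on the
#' link scale over the reference grid formed by all observed levels of the
#' other factors, and inverse-transforms the average. Confidence intervals
#' use the delta method on the link scale; pairwise contrasts between
#' levels are z-tests on link-scale differences, optionally Tukey-adjusted.
#'
#' @param fit a [fit_beta_regression()] fit.
#' @param factor_name covariate whose marginal means are wanted; default
#'   reports each factor in the model in turn.
#' @param by optional factor name: marginal means of `factor_name` within
#'   each level of `by` (the interaction profile).
#' @param level confidence level.
#' @param adjust `"none"` (default) or `"tukey"` p-value adjustment for
#'   pairwise contrasts.
#' @param ci `"delta"` (default) for delta-method intervals on the link
#'   scale, or `"boot"` for a parametric bootstrap (refit on `boot_B`
#'   datasets simulated from the fitted model, percentile interval).
#' @param boot_B,boot_seed parametric bootstrap replicates and seed.
#' @return object of class `marginal_means`: data frames `means` and
#'   `contrasts`.
#' @export
marginal_means <- function(fit, factor_name = NULL, by = NULL,
                           level = 0.95, adjust = c("none", "tukey"),
                           ci = c("delta", "boot"), boot_B = 200,
                           boot_seed = 1) {
  adjust <- match.arg(adjust)
  ci <- match.arg(ci)
  stopifnot(inherits(fit, "betareg_fit"))
  facs <- fit$xlevels
  if (!length(facs)) abort("model has no factors to marginalise over")
  if (is.null(factor_name)) {
    out <- lapply(names(facs), function(f)
      marginal_means(fit, f, by = by, level = level, adjust = adjust,
                     ci = ci, boot_B = boot_B, boot_seed = boot_seed))
    names(out) <- names(facs)
    return(out)
  }
  if (!factor_name %in% names(facs)) {
    abort("'%s' is not a factor in the model (have: %s)", factor_name,
          paste(names(facs), collapse = ", "))
  }
  if (!is.null(by) && !by %in% names(facs)) {
    abort("`by` factor '%s' is not in the model", by)
  }

  grid <- expand.grid(facs, stringsAsFactors = TRUE)
  cell_groups <- if (is.null(by)) grid[[factor_name]] else
    interaction(grid[[factor_name]], grid[[by]], sep = " | ", lex.order = TRUE)
  X <- betareg_design(fit, grid)

  lv <- levels(cell_groups)
  ## averaged design row per marginal cell (equal weights over the grid)
  A <- t(vapply(lv, function(l) colMeans(X[cell_groups == l, , drop = FALSE]),
                numeric(ncol(X))))
  eta <- drop(A %*% fit$coefficients)
  se <- sqrt(rowSums((A %*% fit$vcov) * A))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  if (ci == "delta") {
    lo <- stats::plogis(eta - zc * se)
    hi <- stats::plogis(eta + zc * se)
  } else {
    ## parametric bootstrap: refit on data simulated from the fitted model
    mf <- fit$model
    resp <- names(mf)[1]
    set.seed(boot_seed)
    boots <- vapply(seq_len(boot_B), function(b) {
      mf[[resp]] <- stats::rbeta(fit$n, fit$fitted * fit$precision_phi,
                                 (1 - fit$fitted) * fit$precision_phi)
      bf <- fit_beta_regression(fit$formula, mf)
      drop(A %*% bf$coefficients)
    }, numeric(length(lv)))
    qs <- apply(matrix(boots, nrow = length(lv)), 1, stats::quantile,
                probs = c((1 - level) / 2, 1 - (1 - level) / 2))
    lo <- stats::plogis(qs[1, ]); hi <- stats::plogis(qs[2, ])
  }
  means <- data.frame(
    cell = lv, mean = stats::plogis(eta),
    ci_low = lo, ci_high = hi,
    link_eta = eta, link_se = se,
    stringsAsFactors = FALSE, row.names = NULL
  )

  pairs_idx <- utils::combn(length(lv), 2)
  D <- A[pairs_idx[1, ], , drop = FALSE] - A[pairs_idx[2, ], , drop = FALSE]
  d_eta <- drop(D %*% fit$coefficients)
  d_se <- sqrt(rowSums((D %*% fit$vcov) * D))
  z <- d_eta / d_se
  p <- switch(adjust,
    none = 2 * stats::pnorm(-abs(z)),
    tukey = stats::ptukey(sqrt(2) * abs(z), nmeans = length(lv),
                          df = Inf, lower.tail = FALSE))
  contrasts <- data.frame(
    contrast = paste(lv[pairs_idx[1, ]], "-", lv[pairs_idx[2, ]]),
    estimate_link = d_eta, se_link = d_se, z = z, p = p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(factor = factor_name, by = by, means = means,
                 contrasts = contrasts, level = level, adjust = adjust),
            class = "marginal_means")
}

#' @export
print.marginal_means <- function(x, ...) {
  cat(sprintf("Estimated marginal means for %s%s (%.0f%% CI, link = logit)\n",
              x$factor, if (!is.null(x$by)) paste0(" by ", x$by) else "",
              100 * x$level))
  print(cbind(x$means[1], round(x$means[2:4], 4)), row.names = FALSE)
  cat("Pairwise contrasts (link scale",
      if (x$adjust != "none") paste0(", ", x$adjust, "-adjusted") else "",
      "):\n", sep = "")
  ctab <- x$contrasts
  ctab[2:5] <- round(ctab[2:5], 4)
  print(ctab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.marginal_means <- function(x, ...) {
  m <- x$means
  idx <- seq_len(nrow(m))
  graphics::plot(idx, m$mean, ylim = range(m$ci_low, m$ci_high),
                 xaxt = "n", xlab = x$factor, ylab = "marginal mean", pch = 19,
                 ...)
  graphics::axis(1, at = idx, labels = m$cell)
  graphics::arrows(idx, m$ci_low, idx, m$ci_high, angle = 90, code = 3,
                   length = 0.05)
  invisible(x)
}
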