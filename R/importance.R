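# Environmental driver ranking: principal-component signal extraction,
# random-forest regression in nested cross-validation, Boruta shadow-feature
# relevance testing, and back-projection of PC importance onto the original
# variables via squared loadings.

#' Median-impute missing entries
#'
#' Replaces missing values by the per-variable median of the observed
#' values (or by externally supplied medians, e.g. from a training
#' partition, to avoid leakage). The missingness mask and the medians used
#' are attached as attributes for reporting.
#'
#' @param env data frame or matrix of numeric predictors with `NA` for
#'   missing entries.
#' @param medians optional named vector of medians to impute with.
#' @return data frame with attributes `miss_mask` and `medians`.
#' @export
impute_missing <- function(env, medians = NULL) {
  x <- as.matrix(env)
  mask <- is.na(x)
  if (is.null(medians)) {
    if (any(colSums(!mask) == 0)) {
      abort("variable(s) entirely missing: %s",
            paste(colnames(x)[colSums(!mask) == 0], collapse = ", "))
    }
    medians <- apply(x, 2, stats::median, na.rm = TRUE)
  }
  for (j in seq_len(ncol(x))) x[mask[, j], j] <- medians[[colnames(x)[j]]]
  out <- as.data.frame(x)
  attr(out, "miss_mask") <- mask
  attr(out, "medians") <- medians
  out
}

#' Principal component model on scaled, centered predictors
#'
#' Eigendecomposition of the correlation structure of the (training) data,
#' with a deterministic sign convention: the largest-magnitude loading of
#' each component is positive. Variance fractions are relative to the total
#' variance of the scaled data.
#'
#' @param env complete (imputed) numeric data frame or matrix.
#' @return object of class `pc_model` with orthonormal `loadings`
#'   (variable x PC), `variance_explained`, `center`, `scale`.
#' @export
fit_pca <- function(env) {
  x <- as.matrix(env)
  if (nrow(x) < 2 || ncol(x) < 2) abort("PCA needs at least 2 samples and 2 variables")
  if (anyNA(x)) abort("impute missing values before PCA")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort("zero-variance variable(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  loadings <- sweep(pr$rotation, 2, flip, `*`)
  structure(list(loadings = loadings,
                 variance_explained = pr$sdev^2 / ncol(x),
                 center = pr$center, scale = pr$scale),
            class = "pc_model")
}

#' Project data onto a fitted principal component model
#'
#' @param pc_model a [fit_pca()] model.
#' @param newdata complete numeric data with the model's variables.
#' @param k number of leading components to return (default all).
#' @return sample x PC score matrix.
#' @export
predict_pca <- function(pc_model, newdata, k = NULL) {
  x <- as.matrix(newdata)[, rownames(pc_model$loadings), drop = FALSE]
  x <- scale(x, pc_model$center, pc_model$scale)
  k <- k %||% ncol(pc_model$loadings)
  x %*% pc_model$loadings[, seq_len(k), drop = FALSE]
}

#' Number of components cumulatively explaining a variance threshold
#'
#' Across one or more fitted PC models (one per training partition), finds
#' for each the smallest k whose components cumulatively explain
#' `threshold` of the variance, and returns the maximum: every component
#' reaching the threshold in at least one partition is retained.
#'
#' @param pc_models a `pc_model` or list of them.
#' @param threshold cumulative variance fraction (default 0.99).
#' @return integer k; retained components are 1..k.
#' @export
retain_pcs <- function(pc_models, threshold = 0.99) {
  if (inherits(pc_models, "pc_model")) pc_models <- list(pc_models)
  if (!length(pc_models)) abort("no PC models supplied")
  ks <- vapply(pc_models, function(m) {
    cs <- cumsum(m$variance_explained)
    k <- which(cs >= threshold - 1e-12)[1]
    if (is.na(k)) length(cs) else k
  }, numeric(1))
  as.integer(max(ks))
}

#' Variance explained by each variable for each component
#'
#' The square of the orthonormal loading matrix: entry (v, p) is the
#' fraction of variable v's (scaled) variance captured by component p.
#' Rows sum to 1 over a complete component set.
#'
#' @param pc_model a [fit_pca()] model.
#' @return variable x PC matrix of squared loadings.
#' @export
variable_r2 <- function(pc_model) {
  pc_model$loadings^2
}

#' Boruta all-relevant feature selection
#'
#' At each iteration every active feature is duplicated as a row-permuted
#' "shadow", a random-forest regression is fitted to the joint set, and a
#' feature scores a hit when its permutation importance exceeds the best
#' shadow importance. Hits are compared to a Binomial(iterations, 1/2) law:
#' features with significantly more hits than chance are confirmed,
#' significantly fewer are rejected (and dropped from later iterations),
#' and features still undecided at `max_iter` remain tentative. Tail
#' p-values are Bonferroni-adjusted over the initial feature count when
#' `mc_adjust` is `TRUE`.
#'
#' @param features numeric matrix or data frame of predictors.
#' @param response numeric response vector.
#' @param num_trees trees per forest.
#' @param max_iter maximum number of shadow iterations.
#' @param alpha significance level of the binomial decision test.
#' @param mc_adjust Bonferroni-adjust the binomial p-values over features.
#' @param seed integer seed (shadow permutations and forests).
#' @param min_node minimum node size for the default forest learner.
#' @param learner optional custom learner: `function(x, y, seed)` returning
#'   a named importance vector over the columns of `x`; defaults to a
#'   ranger permutation-importance forest.
#' @return object of class `boruta_result`: `decision` (named character:
#'   confirmed / rejected / tentative), `hits`, `iters`, `history` (per
#'   iteration importance of each real feature), `shadow_max`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("x", 1:6)))
#' y <- 3 * x[, 1] + rnorm(100, 0, 0.5)
#' boruta(x, y, num_trees = 100, max_iter = 30, seed = 1)$decision
boruta <- function(features, response, num_trees = 200, max_iter = 100,
                   alpha = 0.01, mc_adjust = TRUE, seed = 1,
                   min_node = 5, learner = NULL) {
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.numeric(response)
  if (stats::sd(y) == 0) abort("response is constant")
  if (nrow(x) != length(y)) abort("features and response are misaligned")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1)")
  p <- ncol(x)
  feat <- colnames(x)
  learner <- learner %||% function(xx, yy, s) {
    fit <- ranger::ranger(x = xx, y = yy, num.trees = num_trees,
                          importance = "permutation", seed = s,
                          min.node.size = min_node, num.threads = 1)
    fit$variable.importance
  }
  adj <- if (mc_adjust) p else 1

  decision <- stats::setNames(rep("tentative", p), feat)
  hits <- stats::setNames(rep(0L, p), feat)
  iters <- stats::setNames(rep(0L, p), feat)
  history <- matrix(NA_real_, max_iter, p, dimnames = list(NULL, feat))
  shadow_max <- rep(NA_real_, max_iter)

  set.seed(derive_seed(seed, 0))
  it <- 0L
  while (it < max_iter && any(decision == "tentative")) {
    it <- it + 1L
    active <- feat[decision != "rejected"]
    xa <- x[, active, drop = FALSE]
    sh <- apply(xa, 2, sample)
    colnames(sh) <- paste0(".shadow.", active)
    imp <- learner(cbind(xa, sh), y, derive_seed(seed, it))
    smax <- max(imp[colnames(sh)])
    shadow_max[it] <- smax
    real_imp <- imp[active]
    history[it, active] <- real_imp
    hit <- real_imp > smax
    hits[active] <- hits[active] + hit
    iters[active] <- iters[active] + 1L
    ## binomial decision test on still-tentative features
    tent <- feat[decision == "tentative"]
    p_conf <- stats::pbinom(hits[tent] - 1L, iters[tent], 0.5,
                            lower.tail = FALSE)
    p_rej <- stats::pbinom(hits[tent], iters[tent], 0.5)
    decision[tent][p_conf * adj < alpha] <- "confirmed"
    decision[tent][p_rej * adj < alpha] <- "rejected"
  }
  structure(list(decision = decision, hits = hits, iters = iters,
                 history = history[seq_len(it), , drop = FALSE],
                 shadow_max = shadow_max[seq_len(it)],
                 alpha = alpha, n_iter = it),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(factor(x$decision, c("confirmed", "tentative", "rejected")))
  cat(sprintf("Boruta: %d iterations; %d confirmed, %d tentative, %d rejected\n",
              x$n_iter, tab[1], tab[2], tab[3]))
  invisible(x)
}

#' Retain and rank variables by weighted squared loadings
#'
#' A variable is kept when its squared loading (R-squared) with at least
#' one confirmed component reaches `keep_threshold`. Its rank contribution
#' is the sum over confirmed components of the squared loading weighted by
#' the component's relative importance. Variables are ordered by
#' descending contribution, ties broken alphabetically.
#'
#' @param r2 variable x PC squared-loading matrix from [variable_r2()].
#' @param pc_importance named nonnegative vector over confirmed components,
#'   summing to 1 (names are PC column names of `r2`).
#' @param keep_threshold minimum squared loading with a confirmed PC.
#' @return list with `kept` (character vector, ranked) and `contribution`
#'   (named numeric over all variables, sorted descending).
#' @export
rank_variables <- function(r2, pc_importance, keep_threshold = 0.1) {
  if (!length(pc_importance)) abort("no confirmed components to rank with")
  if (is.null(names(pc_importance)) ||
      !all(names(pc_importance) %in% colnames(r2))) {
    abort("`pc_importance` must be named by PC columns of `r2`")
  }
  if (any(pc_importance < 0)) abort("PC importances must be nonnegative")
  sub <- r2[, names(pc_importance), drop = FALSE]
  contribution <- drop(sub %*% pc_importance)
  keep <- apply(sub, 1, max) >= keep_threshold
  ord <- order(-contribution, rownames(r2))
  contribution <- stats::setNames(contribution[ord], rownames(r2)[ord])
  list(kept = names(contribution)[keep[ord]], contribution = contribution)
}

#' Pearson correlation screen
#'
#' Sample correlation and two-sided t-test p-value between the response and
#' each variable, over pairwise-complete observations.
#'
#' @param response numeric response.
#' @param env data frame or matrix of variables (may contain `NA`).
#' @return data frame with `variable`, `r`, `p`, `n`; zero-variance
#'   variables get `NA` and `degenerate = TRUE`.
#' @export
pearson_screen <- function(response, env) {
  x <- as.matrix(env)
  out <- lapply(seq_len(ncol(x)), function(j) {
    ok <- stats::complete.cases(response, x[, j])
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok, j]) == 0 || stats::sd(response[ok]) == 0) {
      return(data.frame(variable = colnames(x)[j], r = NA_real_,
                        p = NA_real_, n = n, degenerate = TRUE))
    }
    ct <- stats::cor.test(response[ok], x[ok, j], method = "pearson")
    data.frame(variable = colnames(x)[j], r = unname(ct$estimate),
               p = ct$p.value, n = n, degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## ranger regression fit + holdout predictions, single-threaded and seeded
rf_fit <- function(x, y, num_trees, mtry, min_node, seed,
                   importance = "none") {
  ranger::ranger(x = as.data.frame(x), y = y, num.trees = num_trees,
                 mtry = min(mtry, ncol(x)), min.node.size = min_node,
                 importance = importance, seed = seed, num.threads = 1)
}

#' Rank environmental drivers by nested cross-validated forest importance
#'
#' Full driver-ranking procedure: reserve a holdout fraction for final
#' performance estimation; within the remainder run k-fold cross-validation
#' where each training partition is independently imputed, scaled, centered
#' and decomposed into principal components; retain every component
#' cumulatively explaining `var_threshold` of the variance in at least one
#' partition; test component relevance per partition with [boruta()] and
#' confirm components passing in at least `confirm_prop` of partitions;
#' tune forest hyperparameters across the folds by RMSE; refit on all
#' non-holdout data with the confirmed components; and back-project
#' component importance onto the original variables with [rank_variables()].
#'
#' @param env data frame of environmental predictors (`NA` allowed).
#' @param response numeric response (e.g. per-sample f_sidero), fully
#'   observed.
#' @param cv_folds number of cross-validation folds.
#' @param holdout_frac fraction reserved for final performance estimation.
#' @param seed integer seed controlling every random stage.
#' @param num_trees trees for tuning and the final forest.
#' @param boruta_trees,boruta_max_iter,boruta_min_node,alpha Boruta
#'   settings per partition; the relevance screen uses a larger minimum
#'   node size than the final model since only the importance ranking,
#'   not predictive accuracy, matters there.
#' @param boruta_mc_adjust Bonferroni-adjust the per-partition Boruta
#'   tests. Off by default here: each partition tests at level `alpha`
#'   and the cross-partition majority vote (`confirm_prop`) supplies the
#'   multiplicity control, so sporadic per-partition false confirmations
#'   do not survive aggregation.
#' @param var_threshold cumulative variance for component retention.
#' @param keep_threshold squared-loading threshold for variable retention.
#' @param confirm_prop fraction of partitions that must confirm a component.
#' @param min_node_grid candidate minimum node sizes for tuning.
#' @return object of class `importance_report`.
#' @export
nested_cv_train <- function(env, response, cv_folds = 10,
                            holdout_frac = 0.2, seed = 1,
                            num_trees = 500, boruta_trees = 200,
                            boruta_max_iter = 50, boruta_min_node = 10,
                            boruta_mc_adjust = FALSE, alpha = 0.01,
                            var_threshold = 0.99, keep_threshold = 0.1,
                            confirm_prop = 0.5,
                            min_node_grid = c(3, 5, 10)) {
  env <- as.data.frame(env)
  n <- nrow(env)
  if (length(response) != n) abort("env and response are misaligned")
  if (n < 5 * cv_folds) abort("need at least %d samples for %d folds",
                              5 * cv_folds, cv_folds)
  n_hold <- round(n * holdout_frac)
  if (n_hold < 10) abort("holdout of %d samples is too small (< 10)", n_hold)

  set.seed(derive_seed(seed, 0))
  hold <- sort(sample.int(n, n_hold))
  train <- setdiff(seq_len(n), hold)
  fold_id <- sample(rep_len(seq_len(cv_folds), length(train)))

  ## per-partition preprocessing: impute -> scale/center -> PCA
  parts <- lapply(seq_len(cv_folds), function(f) {
    idx <- train[fold_id != f]
    imp <- impute_missing(env[idx, , drop = FALSE])
    list(idx = idx, val_idx = train[fold_id == f],
         medians = attr(imp, "medians"), imputed = imp,
         pca = fit_pca(imp))
  })
  k <- retain_pcs(lapply(parts, `[[`, "pca"), var_threshold)
  k <- min(k, min(vapply(parts, function(p) ncol(p$pca$loadings), numeric(1))))

  ## Boruta relevance of the retained components, per partition
  borutas <- lapply(seq_len(cv_folds), function(f) {
    sc <- predict_pca(parts[[f]]$pca, parts[[f]]$imputed, k)
    boruta(sc, response[parts[[f]]$idx], num_trees = boruta_trees,
           max_iter = boruta_max_iter, alpha = alpha,
           min_node = boruta_min_node, mc_adjust = boruta_mc_adjust,
           seed = derive_seed(seed, 100 + f))
  })
  pc_names <- colnames(parts[[1]]$pca$loadings)[seq_len(k)]
  confirm_counts <- rowSums(vapply(
    borutas, function(b) b$decision == "confirmed", logical(k)))
  names(confirm_counts) <- pc_names
  confirmed <- pc_names[confirm_counts >= confirm_prop * cv_folds]

  ## final preprocessing on all non-holdout data
  imp_train <- impute_missing(env[train, , drop = FALSE])
  medians <- attr(imp_train, "medians")
  pca <- fit_pca(imp_train)
  r2 <- variable_r2(pca)
  y_train <- response[train]
  y_hold <- response[hold]
  env_hold <- impute_missing(env[hold, , drop = FALSE], medians = medians)

  if (!length(confirmed)) {
    ## nothing beats noise: intercept-only fallback
    mu <- mean(y_train)
    ss_res <- sum((y_hold - mu)^2)
    report <- list(retained_k = k, confirmed_pcs = character(),
                   confirm_counts = confirm_counts,
                   pc_importance = numeric(),
                   variable_r2 = r2, kept_variables = character(),
                   rank_contribution = numeric(),
                   holdout_r2 = 1 - ss_res / sum((y_hold - mean(y_hold))^2),
                   holdout_rmse = sqrt(mean((y_hold - mu)^2)),
                   confirmed_variance = 0,
                   best_params = NULL, pca = pca, boruta = borutas,
                   pearson = pearson_screen(response, env),
                   n = n, n_holdout = n_hold, seed = seed)
    return(structure(report, class = "importance_report"))
  }

  ## hyperparameter tuning across the folds by validation RMSE
  m <- length(confirmed)
  mtry_grid <- unique(pmax(1, c(ceiling(sqrt(m)), floor(m / 3), floor(m / 2))))
  grid <- expand.grid(mtry = mtry_grid, min_node = min_node_grid)
  fold_feats <- lapply(seq_len(cv_folds), function(f) {
    pt <- parts[[f]]
    val <- impute_missing(env[pt$val_idx, , drop = FALSE],
                          medians = pt$medians)
    list(sc = predict_pca(pt$pca, pt$imputed, k)[, confirmed, drop = FALSE],
         scv = predict_pca(pt$pca, val, k)[, confirmed, drop = FALSE],
         y = response[pt$idx], yv = response[pt$val_idx])
  })
  cv_rmse <- vapply(seq_len(nrow(grid)), function(gi) {
    errs <- vapply(seq_len(cv_folds), function(f) {
      ff <- fold_feats[[f]]
      fit <- rf_fit(ff$sc, ff$y, num_trees, grid$mtry[gi],
                    grid$min_node[gi], derive_seed(seed, 200 + f))
      pred <- stats::predict(fit, data = as.data.frame(ff$scv),
                             num.threads = 1)$predictions
      mean((ff$yv - pred)^2)
    }, numeric(1))
    sqrt(mean(errs))
  }, numeric(1))
  best <- grid[which.min(cv_rmse), ]

  ## final forest on all non-holdout data, confirmed components only
  sc_train <- predict_pca(pca, imp_train, k)[, confirmed, drop = FALSE]
  final <- rf_fit(sc_train, y_train, num_trees, best$mtry, best$min_node,
                  derive_seed(seed, 999), importance = "permutation")
  imp <- pmax(final$variable.importance[confirmed], 0)
  pc_importance <- if (sum(imp) > 0) imp / sum(imp) else
    stats::setNames(rep(1 / m, m), confirmed)

  sc_hold <- predict_pca(pca, env_hold, k)[, confirmed, drop = FALSE]
  pred <- stats::predict(final, data = as.data.frame(sc_hold),
                         num.threads = 1)$predictions
  ranking <- rank_variables(r2, pc_importance, keep_threshold)

  report <- list(
    retained_k = k,
    confirmed_pcs = confirmed,
    confirm_counts = confirm_counts,
    pc_importance = pc_importance,
    variable_r2 = r2,
    kept_variables = ranking$kept,
    rank_contribution = ranking$contribution,
    holdout_r2 = 1 - sum((y_hold - pred)^2) / sum((y_hold - mean(y_hold))^2),
    holdout_rmse = sqrt(mean((y_hold - pred)^2)),
    confirmed_variance = sum(pca$variance_explained[match(confirmed, colnames(pca$loadings))]),
    best_params = as.list(best),
    pca = pca,
    boruta = borutas,
    model = final,
    pearson = pearson_screen(response, env),
    n = n, n_holdout = n_hold, seed = seed
  )
  structure(report, class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Environmental driver importance report\n")
  cat(sprintf("  %d samples (%d holdout); %d PCs retained, %d confirmed\n",
              x$n, x$n_holdout, x$retained_k, length(x$confirmed_pcs)))
  cat(sprintf("  holdout R^2 = %.3f, RMSE = %.4g\n",
              x$holdout_r2, x$holdout_rmse))
  if (length(x$kept_variables)) {
    cat(sprintf("  %d variables retained (max R^2 >= 0.1); top ranked:\n",
                length(x$kept_variables)))
    top <- utils::head(x$rank_contribution, 5)
    for (v in names(top)) cat(sprintf("    %-12s %.4f\n", v, top[[v]]))
  } else {
    cat("  no variables retained\n")
  }
  invisible(x)
}

#' @export
summary.importance_report <- function(object, ...) {
  out <- list(
    retained_k = object$retained_k,
    confirmed_pcs = object$confirmed_pcs,
    pc_importance = object$pc_importance,
    kept = object$kept_variables,
    top10 = utils::head(object$rank_contribution, 10),
    holdout_r2 = object$holdout_r2,
    holdout_rmse = object$holdout_rmse,
    confirmed_variance = object$confirmed_variance
  )
  class(out) <- "summary.importance_report"
  out
}

#' @export
print.summary.importance_report <- function(x, ...) {
  cat(sprintf("Retained PCs: %d; confirmed: %s\n", x$retained_k,
              paste(x$confirmed_pcs, collapse = ", ")))
  cat(sprintf("Confirmed PCs explain %.1f%% of the variance\n",
              100 * x$confirmed_variance))
  cat(sprintf("Holdout R^2 %.3f, RMSE %.4g\n", x$holdout_r2, x$holdout_rmse))
  cat("Top variables by rank contribution:\n")
  print(round(x$top10, 4))
  invisible(x)
}

#' @export
plot.importance_report <- function(x, n_top = 15, ...) {
  contrib <- utils::head(x$rank_contribution, n_top)
  op <- graphics::par(mar = c(4, 7, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(contrib), horiz = TRUE, las = 1,
                    xlab = "rank contribution",
                    main = "Environmental driver ranking", ...)
  invisible(x)
}
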