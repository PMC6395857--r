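# Model-comparison protocols: credible-interval overlap of posterior
# log-likelihoods, slope-identification scoring under the 95%-CI rules, and
# leave-one-cluster-out spatial cross-validation scored by MSE.

#' Compare two fits by log-likelihood credible-interval overlap
#'
#' Two models are judged to fit equally well when the equal-tailed 95%
#' credible intervals of their posterior log-likelihood draws overlap; when
#' the intervals are disjoint, the model with the higher median wins.
#'
#' @param llk_a,llk_b numeric vectors of posterior log-likelihood draws.
#' @param prob interval mass (default 0.95).
#' @return List of class \code{"fit_comparison"}: \code{ci_a}, \code{ci_b},
#'   \code{median_a}, \code{median_b} and \code{verdict} in
#'   \code{c("equal", "A_better", "B_better")}.
#' @examples
#' compare_fit(rnorm(500, -10), rnorm(500, -10.2))$verdict  # "equal"
#' @export
compare_fit <- function(llk_a, llk_b, prob = 0.95) {
  a <- (1 - prob) / 2
  ci_a <- stats::quantile(llk_a, c(a, 1 - a), names = FALSE)
  ci_b <- stats::quantile(llk_b, c(a, 1 - a), names = FALSE)
  overlap <- ci_a[1] <= ci_b[2] && ci_b[1] <= ci_a[2]
  med_a <- stats::median(llk_a); med_b <- stats::median(llk_b)
  verdict <- if (overlap) "equal" else if (med_a > med_b) "A_better"
             else "B_better"
  structure(list(ci_a = ci_a, ci_b = ci_b, median_a = med_a,
                 median_b = med_b, verdict = verdict),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat(sprintf("A: median %.1f, CI [%.1f, %.1f]\n", x$median_a,
              x$ci_a[1], x$ci_a[2]))
  cat(sprintf("B: median %.1f, CI [%.1f, %.1f]\n", x$median_b,
              x$ci_b[1], x$ci_b[2]))
  cat("Verdict:", x$verdict, "\n")
  invisible(x)
}

#' Score slope identification against the generating truth
#'
#' A truly non-zero coefficient is correctly identified when its 95%
#' credible interval excludes zero and matches the true sign; a truly zero
#' coefficient is correctly identified when its interval covers zero.
#' Coefficients excluded by a selection procedure should be supplied as
#' all-zero draw columns, which this rule treats as estimated at zero.
#'
#' @param draws S x p matrix of coefficient draws (columns align with
#'   \code{beta_true}).
#' @param beta_true true coefficient vector, length p.
#' @param prob interval mass (default 0.95).
#' @return List of class \code{"slope_score"} with counts
#'   \code{n_true_nonzero}, \code{n_correct_nonzero}, \code{n_true_zero},
#'   \code{n_correct_zero}.
#' @export
score_slopes <- function(draws, beta_true, prob = 0.95) {
  draws <- as.matrix(draws)
  if (ncol(draws) != length(beta_true))
    stop("ncol(draws) must equal length(beta_true)")
  a <- (1 - prob) / 2
  ci <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a))
  excl_zero <- ci[1, ] > 0 | ci[2, ] < 0
  sign_ok <- sign(colMeans(draws)) == sign(beta_true)
  nz <- beta_true != 0
  structure(list(
    n_true_nonzero = sum(nz),
    n_correct_nonzero = sum(nz & excl_zero & sign_ok),
    n_true_zero = sum(!nz),
    n_correct_zero = sum(!nz & !excl_zero)),
    class = "slope_score")
}

#' @export
print.slope_score <- function(x, ...) {
  cat("Non-zero slopes:", x$n_correct_nonzero, "of", x$n_true_nonzero,
      "correctly identified\n")
  cat("Zero slopes:    ", x$n_correct_zero, "of", x$n_true_zero,
      "correctly identified\n")
  invisible(x)
}

#' Leave-one-cluster-out spatial cross-validation
#'
#' Each spatial cluster is held out once; the requested models are trained
#' on the remaining clusters and their posterior-mean expected counts are
#' scored on the held-out rows by mean squared error. Ordinal probit
#' predictions live on the training count support, so held-out counts
#' outside that support are still scored against it.
#'
#' @param data data frame holding the response, covariates and cluster ids.
#' @param response name of the count column.
#' @param covariates character vector of covariate column names.
#' @param cluster name of the cluster-id column.
#' @param models character vector among \code{"mn"}, \code{"mnms"},
#'   \code{"poisson"}, \code{"nb"}, \code{"zip"}, \code{"zinb"},
#'   \code{"intercept"} (the constant training-mean predictor).
#' @param n_iter,burn MCMC settings for the MN/MN-MS fits.
#' @param family_iter iterations for the parametric family fits.
#' @param splines use linear-spline bases for the MN/MN-MS designs.
#' @param seed optional integer seed.
#' @return Object of class \code{"cv_result"}: \code{mse} (folds x models),
#'   and \code{wins}, the pairwise matrix of fold-win proportions
#'   (\code{wins[A, B]} = share of folds where A has lower MSE than B).
#' @export
spatial_cv <- function(data, response, covariates, cluster,
                       models = c("mn", "intercept"), n_iter = 4000,
                       burn = n_iter %/% 2, family_iter = 4000,
                       splines = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cl_ids <- unique(data[[cluster]])
  if (length(cl_ids) < 2L) stop("need at least 2 clusters")
  mse <- matrix(NA_real_, length(cl_ids), length(models),
                dimnames = list(as.character(cl_ids), models))
  for (f in seq_along(cl_ids)) {
    hold <- data[[cluster]] == cl_ids[f]
    train <- data[!hold, , drop = FALSE]
    test <- data[hold, , drop = FALSE]
    wtr <- train[[response]]
    Xtr <- as.matrix(train[covariates])
    Xte <- as.matrix(test[covariates])
    wte <- test[[response]]
    for (m in models) {
      pred <- switch(m,
        intercept = rep(mean(wtr), nrow(test)),
        mn = predict(fit_mn(wtr, Xtr, n_iter = n_iter, burn = burn,
                            splines = splines), Xte)$mean,
        mnms = predict(fit_mn_ms(wtr, Xtr, n_iter = n_iter, burn = burn,
                                 splines = splines), Xte)$mean,
        predict(fit_family(m, wtr, cv_family_design(Xtr, splines)),
                cv_family_design(Xte, splines, Xtr)))
      mse[f, m] <- mean((wte - pred)^2)
    }
  }
  wins <- matrix(NA_real_, length(models), length(models),
                 dimnames = list(models, models))
  for (a in models) for (b in setdiff(models, a))
    wins[a, b] <- mean(mse[, a] < mse[, b])
  structure(list(mse = mse, wins = wins, clusters = cl_ids),
            class = "cv_result")
}

# Shared design for the family baselines inside spatial_cv: spline basis
# built on the training covariates, standardized with training moments.
cv_family_design <- function(X, splines, Xtrain = NULL) {
  ref <- if (is.null(Xtrain)) X else Xtrain
  d <- build_design(ref, splines = splines)
  if (is.null(Xtrain)) d$M else apply_design(d, X)
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Spatial cross-validation over", nrow(x$mse), "cluster folds\n")
  cat("Mean MSE per model:\n")
  print(round(colMeans(x$mse), 3))
  cat("Pairwise fold-win proportions (row beats column):\n")
  print(round(x$wins, 2))
  invisible(x)
}

#' Goodness-of-fit comparison on simulated single-covariate scenarios
#'
#' For each replicate dataset from a generating scenario
#' ([simulate_table1()]), fits the ordinal probit model with a quadratic
#' design (\code{x}, \code{x^2}, standardized) and the generating family
#' with its true structure, then applies the credible-interval overlap rule
#' ([compare_fit()]). Reports the fraction of datasets where the ordinal
#' model fits equally well or better.
#'
#' @param scenario scenario id from [table1_scenarios()].
#' @param n_datasets replicate datasets (default 10).
#' @param n_obs observations per dataset (default 500).
#' @param n_iter,burn MN sampler settings (defaults 50000, half).
#' @param family_iter iterations per chain for the family sampler.
#' @param seed integer seed; per-dataset seeds are derived from it.
#' @return List of class \code{"table3_run"}: \code{proportion},
#'   \code{verdicts}, per-dataset comparisons, and the scenario.
#' @export
run_table3 <- function(scenario, n_datasets = 10, n_obs = 500,
                       n_iter = 50000, burn = n_iter %/% 2,
                       family_iter = 10000, seed = 1) {
  row <- table1_scenarios()
  row <- row[row$scenario == scenario, ]
  if (nrow(row) != 1L) stop("unknown scenario: ", scenario)
  verdicts <- character(n_datasets)
  comps <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    ds_seed <- (seed * 1000L + i) %% .Machine$integer.max
    sim <- simulate_table1(scenario, seed = ds_seed, n = n_obs)
    mn <- fit_mn(sim$w, cbind(x = sim$x, x2 = sim$x^2),
                 n_iter = n_iter, burn = burn, seed = ds_seed + 1L)
    fam <- fit_family(row$family, sim$w, cbind(x = sim$x),
                      n_iter = family_iter, seed = ds_seed + 2L)
    comps[[i]] <- compare_fit(mn$llk, fam$llk)
    verdicts[i] <- comps[[i]]$verdict
  }
  structure(list(scenario = scenario,
                 proportion = mean(verdicts %in% c("equal", "A_better")),
                 verdicts = verdicts, comparisons = comps),
            class = "table3_run")
}

#' @export
print.table3_run <- function(x, ...) {
  cat("Scenario", x$scenario, ": ordinal model equal-or-better in",
      sprintf("%.0f%%", 100 * x$proportion), "of",
      length(x$verdicts), "datasets\n")
  invisible(x)
}
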