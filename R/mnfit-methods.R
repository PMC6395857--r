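#' @export
print.mnfit <- function(x, ...) {
  cat(if (isTRUE(x$selection)) "MN-MS ordinal probit fit (with model selection)"
      else "MN ordinal probit fit", "\n")
  cat("  n =", length(x$w), " rank categories J =", x$J,
      " design columns p =", ncol(x$beta), "\n")
  cat("  iterations:", x$n_iter, "(burn-in", x$burn, ", thin", x$thin,
      ")  stored draws:", nrow(x$beta), "\n")
  cat("  log-likelihood (median [95% CI]):",
      sprintf("%.1f [%.1f, %.1f]", stats::median(x$llk),
              stats::quantile(x$llk, 0.025), stats::quantile(x$llk, 0.975)),
      "\n")
  if (isTRUE(x$selection)) {
    pip <- colMeans(x$inclusion)
    top <- sort(pip, decreasing = TRUE)
    top <- top[top >= 0.5]
    cat("  columns with inclusion probability >= 0.5:",
        if (length(top)) paste0(names(top), " (", sprintf("%.2f", top), ")",
                                collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

#' Posterior summary of an MN fit
#'
#' @param object an \code{"mnfit"}.
#' @param prob credible-interval mass (default 0.95, equal-tailed).
#' @param ... unused.
#' @return List of class \code{"summary.mnfit"}: per-coefficient posterior
#'   median and interval, break summaries, log-likelihood summary and (for
#'   MN-MS fits) posterior inclusion probabilities.
#' @export
summary.mnfit <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  qs <- function(m) t(apply(m, 2, stats::quantile, probs = c(0.5, a, 1 - a)))
  co <- qs(object$beta)
  colnames(co) <- c("median", "lower", "upper")
  br <- qs(object$b)
  colnames(br) <- c("median", "lower", "upper")
  rownames(br) <- paste0("b", seq_len(nrow(br)))
  out <- list(coefficients = co, breaks = br,
              llk = stats::quantile(object$llk, c(0.5, a, 1 - a)),
              prob = prob, selection = isTRUE(object$selection),
              n = length(object$w), J = object$J,
              draws = nrow(object$beta), n_floored = object$n_floored)
  if (out$selection) out$inclusion <- colMeans(object$inclusion)
  class(out) <- "summary.mnfit"
  out
}

#' @export
print.summary.mnfit <- function(x, ...) {
  cat(if (x$selection) "MN-MS" else "MN",
      "ordinal probit fit: n =", x$n, ", J =", x$J,
      ",", x$draws, "stored draws\n\n")
  cat("Coefficients (posterior median and",
      sprintf("%d%%", round(100 * x$prob)), "CI):\n")
  print(round(x$coefficients, 3))
  if (x$selection) {
    cat("\nPosterior inclusion probabilities:\n")
    print(round(x$inclusion, 3))
  }
  cat("\nLog-likelihood:",
      sprintf("%.1f [%.1f, %.1f]", x$llk[1], x$llk[2], x$llk[3]), "\n")
  if (x$n_floored > 0)
    cat("Note:", x$n_floored,
        "interval probabilities were floored at 1e-300.\n")
  invisible(x)
}

#' @export
coef.mnfit <- function(object, ...) {
  apply(object$beta, 2, stats::median)
}

#' Posterior-predictive expected counts
#'
#' For each new row, computes the expected count
#' \code{E[w | x] = sum_j u_j P(y = j | x)} under every stored posterior draw
#' and returns the posterior mean together with pointwise equal-tailed
#' interval bounds. Predictions live on the training count support \code{u}:
#' held-out counts outside that support are still compared on it.
#'
#' @param object an \code{"mnfit"}.
#' @param newdata raw covariate matrix/data frame with the training columns;
#'   omitted means the training data.
#' @param prob interval mass (default 0.95).
#' @param ... unused.
#' @return \code{data.frame} with columns \code{mean}, \code{median},
#'   \code{lower}, \code{upper}.
#' @export
predict.mnfit <- function(object, newdata = NULL, prob = 0.95, ...) {
  M <- if (is.null(newdata)) object$design$M
       else apply_design(object$design, newdata)
  a <- (1 - prob) / 2
  S <- nrow(object$beta)
  E <- object$beta %*% t(M)                       # S x m linear predictors
  for (s in seq_len(S))
    E[s, ] <- expected_count(E[s, ], object$b[s, ], object$u)
  data.frame(mean = colMeans(E),
             median = apply(E, 2, stats::median),
             lower = apply(E, 2, stats::quantile, probs = a),
             upper = apply(E, 2, stats::quantile, probs = 1 - a))
}

#' @export
fitted.mnfit <- function(object, ...) predict(object)$mean

#' @export
residuals.mnfit <- function(object, ...) object$w - fitted(object)

#' Draw counts from the posterior predictive distribution
#'
#' For each replicate, picks a stored posterior draw and samples one count per
#' training row from the implied category distribution on the observed
#' support.
#'
#' @param object an \code{"mnfit"}.
#' @param nsim number of replicate count vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return \code{n x nsim} matrix of simulated counts.
#' @export
simulate.mnfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  M <- object$design$M
  n <- nrow(M)
  S <- nrow(object$beta)
  out <- matrix(0, n, nsim)
  pick <- sample.int(S, nsim, replace = TRUE)
  for (r in seq_len(nsim)) {
    s <- pick[r]
    P <- mn_cat_probs(drop(M %*% object$beta[s, ]), object$b[s, ])
    cum <- apply(P, 2, cumsum)
    j <- colSums(cum < matrix(stats::runif(n), nrow(cum), n, byrow = TRUE)) + 1L
    out[, r] <- object$u[pmin(j, object$J)]
  }
  out
}

#' Posterior response curves
#'
#' Varies one covariate over its observed range (others held at their
#' training means) and plots the posterior median and pointwise credible
#' band of the expected count, with knot locations marked for spline fits.
#'
#' @param x an \code{"mnfit"}.
#' @param which covariate names to plot (default all).
#' @param ngrid grid size along each covariate.
#' @param prob credible mass for the band.
#' @param ... passed to \code{plot}.
#' @return Invisibly, a list of per-covariate data frames (grid and curve).
#' @export
plot.mnfit <- function(x, which = NULL, ngrid = 50, prob = 0.95, ...) {
  curves <- response_curves(x, which = which, ngrid = ngrid, prob = prob)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(curves)))
  on.exit(graphics::par(old))
  for (v in names(curves)) {
    cv <- curves[[v]]
    graphics::plot(cv$x, cv$median, type = "l", xlab = v,
                   ylab = "expected count",
                   ylim = range(cv$lower, cv$upper), ...)
    graphics::lines(cv$x, cv$lower, lty = 2)
    graphics::lines(cv$x, cv$upper, lty = 2)
    spec <- x$design$specs[[v]]
    if (!is.null(spec))
      graphics::points(spec$knots,
                       stats::approx(cv$x, cv$median, spec$knots)$y)
  }
  invisible(curves)
}

#' Compute posterior response curves without plotting
#'
#' @inheritParams plot.mnfit
#' @param fit an \code{"mnfit"}.
#' @return Named list (one element per covariate) of data frames with columns
#'   \code{x}, \code{mean}, \code{median}, \code{lower}, \code{upper}.
#' @export
response_curves <- function(fit, which = NULL, ngrid = 50, prob = 0.95) {
  design <- fit$design
  raw_means <- raw_design_means(design)
  vars <- if (is.null(which)) design$vars else which
  out <- list()
  for (v in vars) {
    rng <- raw_range(design, v)
    g <- seq(rng[1], rng[2], length.out = ngrid)
    Xnew <- matrix(rep(raw_means, each = ngrid), ngrid,
                   dimnames = list(NULL, design$vars))
    Xnew[, v] <- g
    pr <- predict(fit, Xnew, prob = prob)
    out[[v]] <- cbind(x = g, pr)
  }
  out
}

# Means and ranges of the raw covariates, reconstructed from the stored
# design (the linear column of each covariate, de-standardized).
raw_design_means <- function(design) {
  vapply(design$vars, function(v) mean(raw_col(design, v)), 0)
}

raw_range <- function(design, v) range(raw_col(design, v))

raw_col <- function(design, v) {
  j <- which(design$groups == v)[1L]
  col <- design$M[, j]
  if (!is.null(design$center))
    col <- col * design$scale[j] + design$center[j]
  col
}
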