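# Bayesian fits of the parametric comparison families (Poisson, NB, ZIP,
# ZINB) by adaptive random-walk Metropolis, with split-chain potential scale
# reduction (R-hat) as the convergence criterion. These provide the "true
# model" fits that the ordinal probit model is compared against.

#' Exact log-likelihood of a parametric count family
#'
#' Families: \code{"poisson"} (\code{w ~ Poisson(lambda)}), \code{"nb"}
#' (\code{w ~ NB(mu = lambda, size)}), \code{"zip"} and \code{"zinb"}
#' (mixtures through a Bernoulli indicator \code{q ~ Bern(pi)} with
#' \code{w ~ family(lambda q)}, marginalized over \code{q}: zeros receive
#' mass \code{(1 - pi) + pi f(0 | lambda)}). Here
#' \code{lambda = exp(cbind(1, X) beta)} and for the zero-inflated families
#' \code{pi = plogis(cbind(1, X) alpha)}.
#'
#' @param family one of \code{"poisson"}, \code{"nb"}, \code{"zip"},
#'   \code{"zinb"}.
#' @param w counts.
#' @param X covariate matrix without intercept (or \code{NULL} for
#'   intercept-only).
#' @param beta count-part coefficients, length \code{ncol(X) + 1}.
#' @param alpha zero-inflation coefficients (same length), ZI families only.
#' @param size NB size parameter (> 0), NB families only.
#' @return Scalar log-likelihood.
#' @examples
#' loglik_family("poisson", w = 0, X = NULL, beta = 0)  # -1
#' @export
loglik_family <- function(family, w, X = NULL, beta, alpha = NULL,
                          size = NULL) {
  D <- cbind(rep(1, length(w)), X)
  if (length(beta) != ncol(D)) stop("length(beta) must be ncol(X) + 1")
  lambda <- exp(drop(D %*% beta))
  nbfam <- family %in% c("nb", "zinb")
  if (nbfam && (is.null(size) || size <= 0))
    stop("'size' must be a positive scalar for NB families")
  base_lpmf <- function(w, lam) {
    if (nbfam) stats::dnbinom(w, size = size, mu = lam, log = TRUE)
    else stats::dpois(w, lam, log = TRUE)
  }
  if (family %in% c("poisson", "nb")) return(sum(base_lpmf(w, lambda)))
  if (!family %in% c("zip", "zinb")) stop("unknown family: ", family)
  if (is.null(alpha)) stop("'alpha' required for zero-inflated families")
  lpi <- stats::plogis(drop(D %*% alpha), log.p = TRUE)          # log pi
  l1mpi <- stats::plogis(drop(D %*% alpha), log.p = TRUE, lower.tail = FALSE)
  lp <- lpi + base_lpmf(w, lambda)
  z <- w == 0
  if (any(z)) {
    # log[(1 - pi) + pi f(0|lambda)] via log-sum-exp
    a <- l1mpi[z]; b <- lp[z]
    m <- pmax(a, b)
    lp[z] <- m + log(exp(a - m) + exp(b - m))
  }
  sum(lp)
}

# Pack/unpack the unconstrained parameter vector for a family.
family_dims <- function(family, pX) {
  pD <- pX + 1L
  list(pD = pD,
       n_par = pD + (family %in% c("zip", "zinb")) * pD +
               (family %in% c("nb", "zinb")),
       zi = family %in% c("zip", "zinb"),
       nb = family %in% c("nb", "zinb"))
}

unpack_theta <- function(theta, dims) {
  beta <- theta[seq_len(dims$pD)]
  alpha <- if (dims$zi) theta[dims$pD + seq_len(dims$pD)]
  size <- if (dims$nb) exp(theta[length(theta)])
  list(beta = beta, alpha = alpha, size = size)
}

# Log posterior kernel: likelihood + N(0, 10^2) priors on coefficients and
# N(0, 5^2) on log size.
family_logpost <- function(theta, family, w, X, dims) {
  pars <- unpack_theta(theta, dims)
  ll <- loglik_family(family, w, X, beta = pars$beta, alpha = pars$alpha,
                      size = pars$size)
  lp <- sum(stats::dnorm(theta[seq_len(length(theta) - dims$nb)],
                         0, 10, log = TRUE))
  if (dims$nb)
    lp <- lp + stats::dnorm(theta[length(theta)], 0, 5, log = TRUE)
  list(lp = ll + lp, ll = ll)
}

#' Split-chain potential scale reduction factor
#'
#' Standard R-hat: each chain is split in half and the ratio of pooled to
#' within-half variance is computed. Values below 1.1 are conventionally
#' taken to indicate convergence.
#'
#' @param chains list of numeric vectors (one per chain, equal lengths).
#' @return Scalar R-hat.
#' @export
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(ch) {
    h <- length(ch) %/% 2L
    list(ch[seq_len(h)], ch[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); nn <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- nn * stats::var(means)
  W <- mean(vars)
  if (W < 1e-300) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Fit a parametric count family by adaptive Metropolis sampling
#'
#' Runs several adaptive random-walk Metropolis chains on the unconstrained
#' parameterization (log size for NB families) with diffuse priors
#' (\code{N(0, 10^2)} on coefficients, \code{N(0, 5^2)} on log size).
#' Proposal scales adapt per coordinate during burn-in. If any parameter's
#' split-chain R-hat exceeds 1.1, the run is repeated with doubled length,
#' up to \code{max_doublings}; non-convergence is flagged, not an error.
#'
#' @inheritParams loglik_family
#' @param n_iter iterations per chain before doubling (default 10000; half
#'   discarded as burn-in).
#' @param n_chains number of chains (default 4).
#' @param seed optional integer seed.
#' @param max_doublings maximum times the run is doubled (default 2).
#' @return Object of class \code{"familyfit"}: pooled post-burn-in
#'   \code{draws} (matrix), per-draw log-likelihood \code{llk}, \code{rhat}
#'   per parameter, \code{converged} flag, and the family.
#' @export
fit_family <- function(family, w, X = NULL, n_iter = 10000, n_chains = 4,
                       seed = NULL, max_doublings = 2) {
  if (!is.null(seed)) set.seed(seed)
  X <- if (is.null(X)) NULL else as.matrix(X)
  dims <- family_dims(family, if (is.null(X)) 0L else ncol(X))
  start0 <- numeric(dims$n_par)
  start0[1] <- log(mean(w) + 0.05)
  par_names <- c(paste0("beta", seq_len(dims$pD) - 1L),
                 if (dims$zi) paste0("alpha", seq_len(dims$pD) - 1L),
                 if (dims$nb) "log_size")

  run_once <- function(iters) {
    chains <- vector("list", n_chains)
    for (c in seq_len(n_chains)) {
      theta <- start0 + stats::rnorm(dims$n_par, 0, 0.3)
      sds <- rep(0.1, dims$n_par)
      cur <- family_logpost(theta, family, w, X, dims)
      keep <- (iters %/% 2L + 1L):iters
      dr <- matrix(0, length(keep), dims$n_par)
      llv <- numeric(length(keep))
      acc <- integer(dims$n_par); tries <- integer(dims$n_par)
      s <- 0L
      for (it in seq_len(iters)) {
        for (j in seq_len(dims$n_par)) {
          prop <- theta
          prop[j] <- prop[j] + stats::rnorm(1, 0, sds[j])
          cand <- family_logpost(prop, family, w, X, dims)
          tries[j] <- tries[j] + 1L
          if (is.finite(cand$lp) &&
              log(stats::runif(1)) < cand$lp - cur$lp) {
            theta <- prop; cur <- cand; acc[j] <- acc[j] + 1L
          }
        }
        if (it <= iters %/% 2L && it %% 50L == 0L) {
          rate <- acc / pmax(tries, 1L)
          sds <- sds * exp(0.5 * (rate - 0.44))
          acc[] <- 0L; tries[] <- 0L
        }
        if (it > iters %/% 2L) {
          s <- s + 1L
          dr[s, ] <- theta
          llv[s] <- cur$ll
        }
      }
      chains[[c]] <- list(draws = dr, llk = llv)
    }
    chains
  }

  iters <- n_iter
  for (d in 0:max_doublings) {
    chains <- run_once(iters)
    rhat <- vapply(seq_len(dims$n_par), function(j)
      split_rhat(lapply(chains, function(ch) ch$draws[, j])), 0)
    if (all(rhat < 1.1)) break
    if (d < max_doublings) iters <- iters * 2L
  }
  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(draws) <- par_names
  structure(list(family = family, draws = draws,
                 llk = unlist(lapply(chains, `[[`, "llk")),
                 rhat = stats::setNames(rhat, par_names),
                 converged = all(rhat < 1.1), n_iter_used = iters,
                 dims = dims, X = X, w = w),
            class = "familyfit")
}

#' @export
print.familyfit <- function(x, ...) {
  cat("Bayesian", toupper(x$family), "fit:", nrow(x$draws), "pooled draws,",
      "R-hat max", sprintf("%.3f", max(x$rhat)),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat("  log-likelihood (median [95% CI]):",
      sprintf("%.1f [%.1f, %.1f]", stats::median(x$llk),
              stats::quantile(x$llk, 0.025), stats::quantile(x$llk, 0.975)),
      "\n")
  invisible(x)
}

#' @export
coef.familyfit <- function(object, ...) {
  apply(object$draws, 2, stats::median)
}

#' Posterior-mean expected counts for a parametric family fit
#'
#' For Poisson/NB the conditional mean is \code{lambda}; for zero-inflated
#' families it is \code{pi * lambda}.
#'
#' @param object a \code{"familyfit"}.
#' @param newdata covariate matrix (training data if omitted).
#' @param ... unused.
#' @return Vector of posterior-mean expected counts.
#' @export
predict.familyfit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) object$X else as.matrix(newdata)
  D <- cbind(1, X)
  dims <- object$dims
  S <- nrow(object$draws)
  acc <- numeric(nrow(D))
  for (s in seq_len(S)) {
    pars <- unpack_theta(object$draws[s, ], dims)
    mu <- exp(drop(D %*% pars$beta))
    if (dims$zi) mu <- mu * stats::plogis(drop(D %*% pars$alpha))
    acc <- acc + mu
  }
  acc / S
}

#' Stepwise AIC covariate selection for a Poisson regression
#'
#' Fits the full Poisson GLM and runs bidirectional stepwise search
#' minimizing AIC (via \code{stats::step}). Deterministic given the data.
#'
#' @param w counts.
#' @param X covariate matrix without intercept.
#' @return List with \code{selected} (column names retained), \code{fit}
#'   (the final \code{glm}) and \code{aic}.
#' @export
greedy_aic_poisson <- function(w, X) {
  df <- data.frame(w = w, as.data.frame(X, check.names = TRUE))
  full <- suppressWarnings(stats::glm(w ~ ., family = stats::poisson,
                                      data = df))
  sel <- suppressWarnings(stats::step(full, direction = "both", trace = 0))
  keep <- setdiff(names(stats::coef(sel)), "(Intercept)")
  orig <- colnames(as.data.frame(X, check.names = TRUE))
  list(selected = colnames(X)[match(keep, make.names(orig))],
       fit = sel, aic = stats::AIC(sel))
}
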