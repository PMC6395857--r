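#' Fit the ordinal probit (MN) model to count data
#'
#' Ranks the observed counts (ties share a rank) and fits an ordered probit
#' regression by data-augmentation Gibbs sampling: a latent Gaussian variable
#' \code{z_i ~ N(x_i'beta, 1)} falls between estimated ordered breaks
#' \code{b_1 < ... < b_{J-1}} according to the rank of \code{w_i}. Priors are
#' \code{beta ~ N(0, I)} and the ordered-uniform prior on the breaks over
#' \code{(-100, 100)}. Because the rank categories can follow any discrete
#' distribution, the model absorbs zero-inflation and over-dispersion without
#' a parametric count family. The design excludes the intercept, which is
#' absorbed by the breaks.
#'
#' @param w non-negative integer counts.
#' @param X covariate matrix/data frame, or an \code{"mn_design"} from
#'   [build_design()]. A raw matrix is standardized by default (the
#'   \code{N(0, I)} prior assumes unit-scale columns).
#' @param n_iter total MCMC iterations (default 50000).
#' @param burn burn-in iterations discarded (default half).
#' @param thin keep every \code{thin}-th post-burn draw.
#' @param seed integer seed; identical seeds give identical chains.
#' @param splines,standardize passed to [build_design()] when \code{X} is a
#'   raw matrix.
#' @return An object of class \code{"mnfit"}: stored draws of \code{beta}
#'   (S x p), breaks \code{b} (S x (J-1)), per-draw log-likelihood
#'   \code{llk}, the rank mapping, and the design. Supports \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{fitted},
#'   \code{residuals}, \code{simulate} and \code{plot}.
#' @examples
#' sim <- simulate_table1("poisson-small", seed = 1, n = 120)
#' fit <- fit_mn(sim$w, cbind(x = sim$x), n_iter = 400, burn = 200, seed = 1)
#' summary(fit)
#' @seealso [fit_mn_ms()] for simultaneous variable selection.
#' @export
fit_mn <- function(w, X, n_iter = 50000, burn = n_iter %/% 2, thin = 1,
                   seed = NULL, splines = FALSE, standardize = TRUE) {
  mn_mcmc(w, X, n_iter = n_iter, burn = burn, thin = thin, seed = seed,
          splines = splines, standardize = standardize, select = FALSE)
}

#' Fit the MN model with simultaneous Bayesian variable selection (MN-MS)
#'
#' Extends [fit_mn()] with model selection inside the Gibbs loop: given the
#' latent data \code{z}, the coefficients of any covariate subset integrate
#' out in closed form ([log_marginal()]), so subsets are explored by
#' birth/death/swap Metropolis-Hastings moves under the combinatorial prior
#' [model_log_prior()]. Coefficients of excluded covariates are recorded as
#' zero, so the stored draws are model-averaged. Spline basis columns enter
#' selection individually.
#'
#' @inheritParams fit_mn
#' @param moves_per_iter number of model moves attempted per Gibbs iteration.
#' @param init_k integer indices of the initially active columns (default
#'   none).
#' @return An \code{"mnfit"} whose \code{inclusion} element is the S x P
#'   logical draw matrix of column inclusions; \code{summary} reports
#'   posterior inclusion probabilities.
#' @examples
#' sim <- simulate_table1("poisson-small", seed = 1, n = 120)
#' fit <- fit_mn_ms(sim$w, cbind(x = sim$x, x2 = sim$x^2),
#'                  n_iter = 400, burn = 200, seed = 1)
#' summary(fit)$inclusion
#' @export
fit_mn_ms <- function(w, X, n_iter = 50000, burn = n_iter %/% 2, thin = 1,
                      seed = NULL, splines = FALSE, standardize = TRUE,
                      moves_per_iter = 1, init_k = integer(0)) {
  mn_mcmc(w, X, n_iter = n_iter, burn = burn, thin = thin, seed = seed,
          splines = splines, standardize = standardize, select = TRUE,
          moves_per_iter = moves_per_iter, init_k = init_k)
}

mn_mcmc <- function(w, X, n_iter, burn, thin, seed, splines, standardize,
                    select, moves_per_iter = 1, init_k = integer(0)) {
  cl <- sys.call(-1)
  stopifnot(n_iter > burn, burn >= 0, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  design <- if (inherits(X, "mn_design")) X
            else build_design(X, splines = splines, standardize = standardize)
  M <- design$M
  rk <- rank_counts(w)
  if (rk$J < 2L)
    stop("all counts identical (J = 1): no breaks to estimate")
  if (nrow(M) != length(w)) stop("nrow(X) must match length(w)")
  n <- length(w); p <- ncol(M); J <- rk$J
  y <- rk$y
  cat_idx <- split(seq_len(n), y)

  st <- mn_init(y, J, p)
  z <- st$z; b <- st$b; beta <- st$beta
  keep <- seq(burn + 1L, n_iter, by = thin)
  S <- length(keep)
  beta_draws <- matrix(0, S, p, dimnames = list(NULL, colnames(M)))
  b_draws <- matrix(0, S, J - 1L)
  llk <- numeric(S)
  floored <- integer(S)

  if (select) {
    k <- sort(unique(as.integer(init_k)))
    XtX <- crossprod(M)
    incl_draws <- matrix(FALSE, S, p, dimnames = list(NULL, colnames(M)))
    n_moves <- 0L; n_acc <- 0L
  } else {
    Rchol <- chol(crossprod(M) + diag(p))
  }

  s <- 0L
  for (it in seq_len(n_iter)) {
    eta <- drop(M %*% beta)
    z <- sample_latent(y, eta, b)
    b <- sample_breaks(z, cat_idx)
    if (select) {
      v_full <- crossprod(M, z)
      zz <- sum(z^2)
      lm_k <- log_marginal_pre(k, XtX, v_full, zz)
      for (mv in seq_len(moves_per_iter)) {
        pr <- propose_move(k, p)
        lm_star <- log_marginal_pre(pr$kstar, XtX, v_full, zz)
        la <- (lm_star + model_log_prior(length(pr$kstar), p)) -
              (lm_k + model_log_prior(length(k), p)) + pr$log_R
        n_moves <- n_moves + 1L
        if (log(stats::runif(1)) < la) {
          k <- pr$kstar; lm_k <- lm_star; n_acc <- n_acc + 1L
        }
      }
      beta <- numeric(p)
      if (length(k)) {
        Rk <- chol(XtX[k, k, drop = FALSE] + diag(length(k)))
        mu <- backsolve(Rk, forwardsolve(t(Rk), v_full[k]))
        beta[k] <- mu + backsolve(Rk, stats::rnorm(length(k)))
      }
    } else {
      beta <- sample_beta(z, M, Rchol)
    }
    if (it > burn && (it - burn - 1L) %% thin == 0L) {
      s <- s + 1L
      beta_draws[s, ] <- beta
      b_draws[s, ] <- b
      eta_s <- drop(M %*% beta)
      ll <- mn_loglik(y, eta_s, b)
      llk[s] <- ll
      floored[s] <- attr(ll, "n_floored")
      if (select) incl_draws[s, ] <- seq_len(p) %in% k
    }
  }

  out <- list(beta = beta_draws, b = b_draws, llk = llk,
              u = rk$u, y = y, w = w, design = design, J = J,
              n_iter = n_iter, burn = burn, thin = thin, seed = seed,
              selection = select, n_floored = sum(floored), call = cl)
  if (select) {
    out$inclusion <- incl_draws
    out$accept_rate <- n_acc / max(n_moves, 1L)
  }
  class(out) <- "mnfit"
  out
}

# log_marginal on a precomputed Gram matrix: XtX and v = X'z for the full
# design, subset to the active columns.
log_marginal_pre <- function(k, XtX, v, zz) {
  pk <- length(k)
  if (pk == 0L) return(-0.5 * zz)
  R <- chol(XtX[k, k, drop = FALSE] + diag(pk))
  wv <- forwardsolve(t(R), v[k])
  -0.5 * (zz - sum(wv^2)) - sum(log(diag(R)))
}
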