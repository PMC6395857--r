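# Bayesian variable selection over covariate subsets, run inside the Gibbs
# sampler on the latent Gaussian data z. With the N(0, I) coefficient prior
# the coefficients integrate out in closed form, giving a marginal score per
# subset; model space is explored by birth/death/swap Metropolis-Hastings.

#' Log marginal score of a covariate subset
#'
#' For latent data \code{z ~ N(X_k beta_k, I)} with prior
#' \code{beta_k ~ N(0, I)}, the coefficients integrate out to give
#' \code{log p(M_k | z) = -0.5 (z'z - mu_k' Sigma_k^{-1} mu_k) +
#' 0.5 log|Sigma_k| + const}, where \code{Sigma_k^{-1} = X_k'X_k + I} and
#' \code{mu_k = Sigma_k X_k'z}. The constant \code{-(n/2) log(2 pi)} shared by
#' all subsets is omitted, so only differences across subsets are meaningful.
#' The empty subset returns \code{-0.5 z'z} (the \code{|Sigma| = 1}
#' convention).
#'
#' @param z numeric latent data vector.
#' @param Xk design matrix restricted to the subset (possibly 0 columns).
#' @return Scalar log marginal score (up to the shared constant).
#' @export
log_marginal <- function(z, Xk) {
  if (!all(is.finite(z))) stop("non-finite latent values")
  Xk <- as.matrix(Xk)
  p <- ncol(Xk)
  if (p == 0L) return(-0.5 * sum(z^2))
  if (!all(is.finite(Xk))) stop("non-finite design values")
  R <- chol(crossprod(Xk) + diag(p))
  v <- crossprod(Xk, z)
  wv <- forwardsolve(t(R), v)       # mu' Sigma^{-1} mu = ||R^{-T} X'z||^2
  -0.5 * (sum(z^2) - sum(wv^2)) - sum(log(diag(R)))
}

#' Combinatorial prior over covariate subsets
#'
#' \code{p(M_k) = (P + 1)^{-1} choose(P, p_k)^{-1}}: each model size
#' \code{0..P} is equally likely, and all subsets of a given size are equally
#' likely. Normalized over the \code{2^P} subsets.
#'
#' @param p_k number of covariates in the subset.
#' @param P total number of candidate covariates.
#' @return Log prior probability.
#' @examples
#' exp(model_log_prior(0, 2))  # 1/3
#' @export
model_log_prior <- function(p_k, P) {
  if (p_k < 0 || p_k > P) stop("'p_k' must lie in 0..P")
  -log(P + 1) - lchoose(P, p_k)
}

# Uniform draw of one element, safe for length-1 vectors.
draw_one <- function(v) v[[sample.int(length(v), 1L)]]

# Feasible move types at a given subset size.
feasible_moves <- function(p_k, P) {
  c(if (p_k < P) "birth", if (p_k > 0L) "death",
    if (p_k > 0L && p_k < P) "swap")
}

# Propose a birth (add), death (drop) or swap (simultaneous add+drop) of a
# covariate, uniformly over feasible move types and then uniformly within
# type. log_R is the log proposal-ratio correction q(k* -> k)/q(k -> k*):
# zero in the interior (all three types feasible both ways, and within-type
# selection probabilities cancel for swap), nonzero near the boundary sizes
# where the feasible-move sets differ, preserving detailed balance.
propose_move <- function(k, P) {
  p_k <- length(k)
  absent <- setdiff(seq_len(P), k)
  move <- draw_one(feasible_moves(p_k, P))
  if (move == "birth") {
    kstar <- sort(c(k, draw_one(absent)))
    fwd <- -log(length(feasible_moves(p_k, P))) - log(P - p_k)
    rev <- -log(length(feasible_moves(p_k + 1L, P))) - log(p_k + 1L)
  } else if (move == "death") {
    kstar <- setdiff(k, draw_one(k))
    fwd <- -log(length(feasible_moves(p_k, P))) - log(p_k)
    rev <- -log(length(feasible_moves(p_k - 1L, P))) - log(P - p_k + 1L)
  } else {
    kstar <- sort(c(setdiff(k, draw_one(k)), draw_one(absent)))
    fwd <- -log(length(feasible_moves(p_k, P))) - log(p_k) - log(P - p_k)
    rev <- fwd
  }
  list(kstar = as.integer(kstar), move = move, log_R = rev - fwd)
}

# Metropolis-Hastings accept/reject for a proposed subset, scored by the
# closed-form marginal and the combinatorial prior on fixed latent data z.
mh_accept <- function(k, kstar, z, X, log_R,
                      lm_k = log_marginal(z, X[, k, drop = FALSE])) {
  P <- ncol(X)
  lm_star <- log_marginal(z, X[, kstar, drop = FALSE])
  la <- (lm_star + model_log_prior(length(kstar), P)) -
        (lm_k + model_log_prior(length(k), P)) + log_R
  if (log(stats::runif(1)) < la) {
    list(k = kstar, log_marginal = lm_star, accepted = TRUE)
  } else {
    list(k = k, log_marginal = lm_k, accepted = FALSE)
  }
}
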