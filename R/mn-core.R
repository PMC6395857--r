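# Gibbs kernels for the ordinal probit (MN) model.
#
# Latent formulation: y_i = j iff b_{j-1} < z_i < b_j (sentinels b_0 = -Inf,
# b_J = +Inf), z_i ~ N(x_i' beta, 1), priors beta ~ N(0, I) and
# (b_1 < ... < b_{J-1}) uniform on (-100, 100). All three full conditionals
# are available in closed form, so the sampler is a systematic-scan Gibbs
# with scan order z -> b -> beta.

# z_i | . ~ N(eta_i, 1) truncated to (b_{y_i - 1}, b_{y_i}).
sample_latent <- function(y, eta, b) {
  bext <- c(-Inf, b, Inf)
  lo <- bext[y] - eta
  hi <- bext[y + 1L] - eta
  eta + rtnorm_std(lo, hi)
}

# b_j | . uniform on (max z in category j, min z in category j+1),
# intersected with the prior support (-100, 100). cat_idx is the fixed list
# of observation indices per rank category.
sample_breaks <- function(z, cat_idx) {
  J <- length(cat_idx)
  if (any(lengths(cat_idx) == 0L))
    stop("internal state error: empty rank category")
  mx <- vapply(cat_idx, function(ii) max(z[ii]), 0)
  mn <- vapply(cat_idx, function(ii) min(z[ii]), 0)
  lo <- pmax(mx[-J], -100)
  hi <- pmin(mn[-1L], 100)
  lo + stats::runif(J - 1L) * (hi - lo)
}

# beta | z ~ N(mu, Sigma) with Sigma^{-1} = X'X + I and mu = Sigma X'z.
# Rchol is the upper Cholesky factor of X'X + I, precomputed since X is fixed.
sample_beta <- function(z, X, Rchol = NULL) {
  if (!all(is.finite(z))) stop("non-finite latent values")
  p <- ncol(X)
  if (p == 0L) return(numeric(0))
  if (is.null(Rchol)) Rchol <- chol(crossprod(X) + diag(p))
  v <- crossprod(X, z)
  mu <- backsolve(Rchol, forwardsolve(t(Rchol), v))
  drop(mu + backsolve(Rchol, stats::rnorm(p)))
}

#' Log-likelihood of the ordinal probit model
#'
#' Sum over observations of \code{log[Phi(b_{y_i} - x_i'beta) -
#' Phi(b_{y_i - 1} - x_i'beta)]} with sentinels \code{b_0 = -Inf},
#' \code{b_J = +Inf}. Because the ranks are a bijection onto the observed
#' count support, this equals the log-likelihood of the counts themselves.
#' Interval probabilities are evaluated with tail-stable complementary-CDF
#' arithmetic and floored at 1e-300; the number of floored terms is attached
#' as attribute \code{"n_floored"}.
#'
#' @param y integer ranks in \code{1..J} (from [rank_counts()]).
#' @param eta linear predictor \code{X beta}, same length as \code{y}.
#' @param b strictly increasing breaks, length \code{J - 1}.
#' @return Scalar log-likelihood (attribute \code{"n_floored"}).
#' @export
mn_loglik <- function(y, eta, b) {
  J <- length(b) + 1L
  if (max(y) > J) stop("rank exceeds the number of categories implied by b")
  if (J > 2L && any(diff(b) <= 0)) stop("breaks must be strictly increasing")
  bext <- c(-Inf, b, Inf)
  lp <- log_pnorm_diff(bext[y] - eta, bext[y + 1L] - eta)
  structure(sum(lp), n_floored = attr(lp, "n_floored"))
}

# Per-category probabilities P(y = j | eta) as a J x length(eta) matrix.
mn_cat_probs <- function(eta, b) {
  bext <- c(-Inf, b, Inf)
  P <- stats::pnorm(outer(bext, eta, "-"))
  P[length(bext), ] <- 1
  P[1L, ] <- 0
  diff(P)
}

#' Expected count under the ordinal probit model
#'
#' \code{E[w | x] = sum_j u_j [Phi(b_j - x'beta) - Phi(b_{j-1} - x'beta)]}:
#' the category probabilities implied by the probit link, weighted by the
#' unique observed count values \code{u}.
#'
#' @param eta linear predictor value(s) \code{x'beta} (vectorized).
#' @param b strictly increasing breaks, length \code{J - 1}.
#' @param u ordered unique counts, length \code{J}.
#' @return Numeric vector of expected counts, one per element of \code{eta}.
#' @examples
#' expected_count(0, b = 0, u = c(0, 1))  # 1 - Phi(0) = 0.5
#' @export
expected_count <- function(eta, b, u) {
  if (length(u) != length(b) + 1L)
    stop("length(u) must equal length(b) + 1")
  drop(crossprod(mn_cat_probs(eta, b), u))
}

# Deterministic initial state: breaks at the standard-normal quantiles of the
# empirical cumulative rank frequencies (clipped), beta at 0, z at interval
# midpoints (+/- 1 beyond the extreme breaks).
mn_init <- function(y, J, p) {
  freq <- cumsum(tabulate(y, J)) / length(y)
  b <- stats::qnorm(freq[-J])
  b <- pmin(pmax(b, -99.9), 99.9)
  if (J > 2L) b <- sort(b) + cumsum(c(0, diff(b) <= 0)) * 1e-8
  bext <- c(-Inf, b, Inf)
  lo <- bext[y]; hi <- bext[y + 1L]
  z <- ifelse(is.finite(lo) & is.finite(hi), (lo + hi) / 2,
              ifelse(is.finite(lo), lo + 1, hi - 1))
  list(z = z, b = b, beta = numeric(p))
}
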