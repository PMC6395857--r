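# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own computational paths: dense grids, quadrature and
# exhaustive enumeration at tiny problem sizes.

# Dense-grid posterior for the ordinal probit model with one covariate and
# J = 3 categories: integrates the unnormalized posterior over
# (beta, b1, b2) on a grid and returns marginal moments of beta and b1.
grid_posterior_mn <- function(w, x, beta_grid = seq(-3, 3, length.out = 121),
                              b_grid = seq(-5, 5, length.out = 161)) {
  u <- sort(unique(w)); y <- match(w, u)
  stopifnot(length(u) == 3)
  i1 <- which(y == 1); i2 <- which(y == 2); i3 <- which(y == 3)
  nb <- length(b_grid)
  post_b1 <- numeric(nb)
  m1 <- 0; m2 <- 0; tot <- 0
  lower_tri <- outer(seq_len(nb), seq_len(nb), "<")  # b1 index < b2 index
  for (gi in seq_along(beta_grid)) {
    beta <- beta_grid[gi]
    P <- stats::pnorm(outer(x, b_grid, function(x, b) b - x * beta))
    A <- apply(P[i1, , drop = FALSE], 2, prod)            # over b1 grid
    C <- apply(1 - P[i3, , drop = FALSE], 2, prod)        # over b2 grid
    B <- matrix(1, nb, nb)
    for (i in i2) B <- B * pmax(outer(-P[i, ], P[i, ], "+"), 0)
    L <- (A * B) %*% diag(C) * lower_tri
    wgt <- stats::dnorm(beta)
    s <- sum(L) * wgt
    tot <- tot + s
    m1 <- m1 + beta * s
    m2 <- m2 + beta^2 * s
    post_b1 <- post_b1 + rowSums(L) * wgt
  }
  list(beta_mean = m1 / tot, beta_sd = sqrt(m2 / tot - (m1 / tot)^2),
       b1_mean = sum(b_grid * post_b1) / sum(post_b1))
}

# log of the coefficient-integrated likelihood int N(z | X b, I) N(b | 0, I) db
# by quadrature, for p = 1 or p = 2 columns.
quad_log_marginal <- function(z, X) {
  X <- as.matrix(X)
  if (ncol(X) == 1) {
    f <- function(b) vapply(b, function(bj)
      exp(sum(stats::dnorm(z - X[, 1] * bj, log = TRUE)) +
          stats::dnorm(bj, log = TRUE)), 0)
    log(stats::integrate(f, -8, 8, rel.tol = 1e-10)$value)
  } else {
    inner <- function(b1) stats::integrate(function(b2) vapply(b2,
      function(bj) exp(sum(stats::dnorm(z - X %*% c(b1, bj), log = TRUE)) +
                       stats::dnorm(b1, log = TRUE) +
                       stats::dnorm(bj, log = TRUE)), 0),
      -8, 8, rel.tol = 1e-10)$value
    log(stats::integrate(function(b1) vapply(b1, inner, 0), -8, 8,
                         rel.tol = 1e-8)$value)
  }
}

# Exact posterior over all 2^P covariate subsets for fixed latent data z.
enumerate_model_posterior <- function(z, X) {
  P <- ncol(X)
  subsets <- lapply(0:(2^P - 1), function(m) which(bitwAnd(m, 2^(0:(P - 1))) > 0))
  lp <- vapply(subsets, function(k)
    log_marginal(z, X[, k, drop = FALSE]) + model_log_prior(length(k), P), 0)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  names(p) <- vapply(subsets, subset_key, "")
  list(subsets = subsets, prob = p)
}

subset_key <- function(k) {
  if (length(k) == 0L) "empty" else paste(sort(k), collapse = ",")
}

# Generate data from the ordinal probit model itself (known beta and breaks).
simulate_mn_data <- function(n, beta, b, u = seq_len(length(b) + 1) - 1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(beta)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  X <- scale(X)[, , drop = FALSE]  # unit-scale so standardization is ~identity
  z <- drop(X %*% beta) + stats::rnorm(n)
  y <- findInterval(z, b) + 1L
  list(w = u[y], X = X, beta = beta, b = b)
}
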