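test_that("the subset prior enumerates correctly and normalizes", {
  # P = 2: sizes 0,1,1,2 get mass 1/3, 1/6, 1/6, 1/3
  expect_equal(exp(model_log_prior(0, 2)), 1 / 3)
  expect_equal(exp(model_log_prior(1, 2)), 1 / 6)
  expect_equal(exp(model_log_prior(2, 2)), 1 / 3)
  expect_equal(model_log_prior(5, 10), -log(11) - log(252))
  expect_error(model_log_prior(3, 2), "0..P")
  for (P in 1:8) {
    total <- sum(choose(P, 0:P) * exp(vapply(0:P, model_log_prior, 0, P = P)))
    expect_equal(total, 1)
  }
})

test_that("log marginal scores match quadrature over the coefficient prior", {
  # empty model convention
  expect_equal(log_marginal(c(1, 1), matrix(0, 2, 0)), -1)

  # p = 1, closed 2x1 case and a random instance; the quadrature value
  # includes the Gaussian normalizing constant -(n/2) log(2 pi)
  z <- c(1, 1); X <- matrix(1, 2, 1)
  expect_equal(log_marginal(z, X) - log(2 * pi),
               quad_log_marginal(z, X), tolerance = 1e-6)
  set.seed(41)
  for (p in 1:2) {
    n <- 12
    X <- matrix(rnorm(n * p), n, p)
    z <- rnorm(n, sd = 1.3)
    expect_equal(log_marginal(z, X) - n / 2 * log(2 * pi),
                 quad_log_marginal(z, X), tolerance = 1e-3)
  }
})

test_that("marginal-score differences equal Monte-Carlo Bayes factors", {
  set.seed(42)
  n <- 8
  X <- matrix(rnorm(n * 2), n, 2)
  z <- rnorm(n)
  mc_log_marg <- function(Xk) {
    S <- 2e5
    B <- matrix(rnorm(S * ncol(Xk)), S, ncol(Xk))
    ll <- vapply(seq_len(S), function(s)
      sum(dnorm(z - drop(Xk %*% B[s, ]), log = TRUE)), 0)
    m <- max(ll); m + log(mean(exp(ll - m)))
  }
  d_pkg <- log_marginal(z, X[, 1, drop = FALSE]) - log_marginal(z, X)
  d_mc <- mc_log_marg(X[, 1, drop = FALSE]) - mc_log_marg(X)
  expect_lt(abs(d_pkg - d_mc), 0.05)
})

test_that("proposals respect feasibility at the boundary subset sizes", {
  set.seed(43)
  for (r in 1:50) {
    pr <- ordcount:::propose_move(integer(0), 4)
    expect_equal(pr$move, "birth")
    expect_length(pr$kstar, 1)
    pr2 <- ordcount:::propose_move(1:4, 4)
    expect_true(pr2$move %in% "death")   # swap needs an absent covariate
    expect_length(pr2$kstar, 3)
  }
  moves <- replicate(200, ordcount:::propose_move(c(1L, 3L), 4)$move)
  expect_setequal(unique(moves), c("birth", "death", "swap"))
})

test_that("prior-only Metropolis chain targets the subset prior", {
  # acceptance using only the prior ratio and the proposal correction; the
  # stationary law must then be the combinatorial prior itself, including at
  # the boundary sizes (an empirical detailed-balance check)
  set.seed(44)
  P <- 4
  k <- integer(0)
  counts <- new.env()
  n_moves <- 5e4
  for (it in seq_len(n_moves)) {
    pr <- ordcount:::propose_move(k, P)
    la <- model_log_prior(length(pr$kstar), P) -
          model_log_prior(length(k), P) + pr$log_R
    if (log(runif(1)) < la) k <- pr$kstar
    key <- subset_key(k)
    counts[[key]] <- (if (is.null(counts[[key]])) 0 else counts[[key]]) + 1
  }
  freq <- unlist(as.list(counts)) / n_moves
  truth <- vapply(names(freq), function(key) {
    pk <- if (key == "empty") 0L else length(strsplit(key, ",")[[1]])
    exp(model_log_prior(pk, P))
  }, 0)
  expect_equal(length(freq), 16L)            # all subsets visited
  expect_lt(sum(abs(freq - truth)) / 2, 0.05)  # total-variation distance
})

test_that("model-space MH matches the exhaustively enumerated posterior", {
  set.seed(45)
  n <- 20; P <- 3
  X <- matrix(rnorm(n * P), n, P)
  z <- drop(X[, 1] * 0.8) + rnorm(n)
  exact <- enumerate_model_posterior(z, X)
  k <- integer(0)
  lm_k <- log_marginal(z, X[, k, drop = FALSE])
  visits <- setNames(numeric(length(exact$prob)), names(exact$prob))
  n_moves <- 1e5
  for (it in seq_len(n_moves)) {
    pr <- ordcount:::propose_move(k, P)
    res <- ordcount:::mh_accept(k, pr$kstar, z, X, pr$log_R, lm_k)
    k <- res$k; lm_k <- res$log_marginal
    key <- subset_key(k)
    visits[key] <- visits[key] + 1
  }
  expect_lt(sum(abs(visits / n_moves - exact$prob)) / 2, 0.05)
})

test_that("within-sampler selection finds strong signals and drops noise", {
  set.seed(46)
  n <- 300
  x1 <- rnorm(n)
  w <- rpois(n, exp(0.2 + 0.9 * x1))
  X <- cbind(x1 = x1, x2 = rnorm(n), x3 = rnorm(n))
  fit <- fit_mn_ms(w, X, n_iter = 2000, burn = 1000, seed = 11)
  pip <- colMeans(fit$inclusion)
  expect_gt(pip["x1"], 0.95)
  expect_lt(max(pip[c("x2", "x3")]), 0.5)
})

test_that("null designs rarely admit covariates", {
  # all-zero slopes: every column's inclusion probability should fall below
  # one half in nearly all replicates
  ok <- 0L
  n_rep <- 5
  for (r in seq_len(n_rep)) {
    sim <- simulate_selection(0, seed = 400 + r, n = 250)
    fit <- fit_mn_ms(sim$w, sim$X[, -1], n_iter = 1500, burn = 750,
                     seed = 500 + r)
    if (max(colMeans(fit$inclusion)) < 0.5) ok <- ok + 1L
  }
  expect_gte(ok, n_rep - 1L)
})
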