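test_that("family log-likelihoods reduce to closed forms", {
  # Poisson with rate 1 at w = 0: log e^{-1}
  expect_equal(loglik_family("poisson", w = 0L, X = NULL, beta = 0), -1)
  # degenerate mixture: P(q = 0) ~ 1 makes all-zero data certain
  expect_equal(loglik_family("zip", w = rep(0L, 5), X = NULL, beta = 1,
                             alpha = -40), 0, tolerance = 1e-12)
  expect_error(loglik_family("nb", w = 1L, X = NULL, beta = 0, size = -1),
               "positive")
  expect_error(loglik_family("poisson", w = 1L, X = NULL, beta = c(0, 1)),
               "length")
})

test_that("NB mass equals the Poisson-Gamma mixture evaluated numerically", {
  mu <- 1.7; size <- 0.6
  for (w in c(0L, 1L, 4L, 9L)) {
    mix <- integrate(function(lam)
      dpois(w, lam) * dgamma(lam, shape = size, rate = size / mu),
      0, Inf, rel.tol = 1e-12)$value
    expect_equal(loglik_family("nb", w, X = NULL, beta = log(mu),
                               size = size), log(mix), tolerance = 1e-8)
  }
})

test_that("ZINB collapses to its limits in the mixture weight", {
  w <- c(0L, 2L, 5L, 0L)
  x <- cbind(c(-1, 0, 1, 2))
  # pi -> 1: q = 1 almost surely, ZINB equals plain NB
  expect_equal(loglik_family("zinb", w, x, beta = c(0.2, 0.3),
                             alpha = c(40, 0), size = 0.8),
               loglik_family("nb", w, x, beta = c(0.2, 0.3), size = 0.8),
               tolerance = 1e-10)
  # pi -> 0: all mass at zero
  expect_equal(loglik_family("zinb", c(0L, 0L), NULL, beta = 1,
                             alpha = -40, size = 1), 0, tolerance = 1e-12)
  expect_lt(loglik_family("zinb", c(0L, 3L), NULL, beta = 1,
                          alpha = -40, size = 1), -20)
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(81)
  mixed <- replicate(4, rnorm(500), simplify = FALSE)
  expect_lt(split_rhat(mixed), 1.05)
  apart <- list(rnorm(500), rnorm(500) + 5, rnorm(500), rnorm(500) - 5)
  expect_gt(split_rhat(apart), 1.5)
  # a drifting chain is flagged even when all chains look alike
  drift <- replicate(4, cumsum(rnorm(500, 0.05)), simplify = FALSE)
  expect_gt(split_rhat(drift), 1.1)
})

test_that("the Poisson sampler recovers generating parameters", {
  set.seed(82)
  x <- rnorm(250)
  w <- rpois(250, exp(0.4 + 0.6 * x))
  fit <- fit_family("poisson", w, cbind(x), n_iter = 3000, seed = 1)
  expect_true(fit$converged)
  est <- coef(fit)
  sds <- apply(fit$draws, 2, sd)
  expect_lt(abs(est["beta0"] - 0.4), 3 * sds["beta0"])
  expect_lt(abs(est["beta1"] - 0.6), 3 * sds["beta1"])
})

test_that("the ZIP sampler reproduces the empirical zero fraction", {
  sim <- simulate_table1("zip-small", seed = 83, n = 400)
  fit <- fit_family("zip", sim$w, cbind(x = sim$x), n_iter = 3000, seed = 2)
  # posterior-predictive zero fraction across draws
  D <- cbind(1, sim$x)
  idx <- seq(1, nrow(fit$draws), by = 20)
  zf <- vapply(idx, function(s) {
    pars <- ordcount:::unpack_theta(fit$draws[s, ], fit$dims)
    lam <- exp(drop(D %*% pars$beta))
    pi <- plogis(drop(D %*% pars$alpha))
    mean((1 - pi) + pi * exp(-lam))
  }, 0)
  emp <- mean(sim$w == 0)
  expect_gt(emp, quantile(zf, 0.005))
  expect_lt(emp, quantile(zf, 0.995))
})

test_that("stepwise AIC selection keeps strong covariates and is deterministic", {
  set.seed(84)
  X <- cbind(x1 = rnorm(300), x2 = rnorm(300), x3 = rnorm(300))
  w <- rpois(300, exp(0.3 + 0.8 * X[, "x1"]))
  sel <- greedy_aic_poisson(w, X)
  expect_true("x1" %in% sel$selected)
  sel2 <- greedy_aic_poisson(w, X)
  expect_identical(sel$selected, sel2$selected)
  # intercept-only AIC closed form: -2 sum log Poisson(w; wbar) + 2
  null_fit <- glm(w ~ 1, family = poisson)
  expect_equal(AIC(null_fit),
               -2 * sum(dpois(w, mean(w), log = TRUE)) + 2)
})
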