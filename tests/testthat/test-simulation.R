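test_that("the scenario catalog encodes the twelve generating models", {
  cat <- table1_scenarios()
  expect_equal(nrow(cat), 12L)
  expect_equal(sum(cat$family == "nb"), 4L)
  ps <- cat[cat$scenario == "poisson-small", ]
  expect_equal(exp(ps$beta0), 1)              # E[w | x = 0] = 1
  pl <- cat[cat$scenario == "poisson-large", ]
  expect_equal(exp(pl$beta0), 5)              # E[w | x = 0] = 5
  zs <- cat[cat$scenario == "zip-small", ]
  # Bernoulli component: p(q = 0 | x = 0) = 1/4, and the marginal mean at
  # x = 0 is (3/4) (4/3) = 1
  expect_equal(1 - plogis(zs$alpha0), 1 / 4)
  expect_equal(plogis(zs$alpha0) * exp(zs$beta0), 1)
  expect_equal(cat$beta1, rep(0.5, 12))
  expect_equal(sort(unique(cat$size[cat$family %in% c("nb", "zinb")])),
               c(0.1, 1))
})

test_that("scenario draws use the fixed covariate grid and are reproducible", {
  sim <- simulate_table1("zinb-large-large", seed = 3, n = 500)
  expect_equal(sim$x, seq(-2, 2, length.out = 500))
  sim2 <- simulate_table1("zinb-large-large", seed = 3, n = 500)
  expect_identical(sim$w, sim2$w)
  expect_true(all(sim$w >= 0))
})

test_that("generated moments match the stated mean-variance structure", {
  # flat scenarios (slopes zeroed) make every observation identically
  # distributed, so empirical moments can be checked against closed forms
  flat <- function(id, ...) {
    row <- table1_scenarios()
    row <- row[row$scenario == id, ]
    row$beta1 <- 0; row$alpha1[!is.na(row$alpha1)] <- 0
    simulate_table1(row, ...)
  }
  n <- 1e5
  pois <- flat("poisson-small", seed = 61, n = n)
  expect_lt(abs(mean(pois$w) - 1), 3 * sqrt(1 / n))

  nb <- flat("nb-small-large", seed = 62, n = n)    # mu = 1, size = 0.1
  v_true <- 1 + 1 / 0.1
  expect_lt(abs(mean(nb$w) - 1), 3 * sqrt(v_true / n))
  expect_lt(abs(var(nb$w) - v_true) / v_true, 0.15)

  zip <- flat("zip-small", seed = 63, n = n)        # mixture mean 3/4 * 4/3
  expect_lt(abs(mean(zip$w) - 1), 3 * sqrt(2 / n))
  expect_lt(abs(mean(zip$w == 0) -
                (1 / 4 + 3 / 4 * exp(-4 / 3))), 3 * sqrt(0.25 / n))
})

test_that("the selection design has 56 parameters and the stated sparsity", {
  sim0 <- simulate_selection(0, seed = 64)
  expect_equal(ncol(sim0$X), 56L)               # 1 + 10 + 45
  expect_equal(sum(sim0$beta_true[-1] != 0), 0L)
  sim10 <- simulate_selection(10, seed = 65)
  expect_equal(sum(sim10$beta_true[-1] != 0), 10L)
  expect_true(all(sim10$beta_true[-1] %in% c(-0.5, 0, 0.5)))
  expect_equal(unname(sim10$X[, 1]), rep(1, 500))
  # interaction columns are products of the base covariates
  expect_equal(unname(sim10$X[, "x1:x2"]),
               unname(sim10$X[, "x1"] * sim10$X[, "x2"]))
})

test_that("the nonlinear design has the stated mean surface and dispersion", {
  sim <- simulate_nonlinear(seed = 66, n = 2e4)
  # plug-in at x = (0, 0, 0): mu = exp(0 + 0 + 1) = e
  expect_equal(sim$mean_fun(matrix(0, 1, 6)), exp(1))
  # the quadratic contribution vanishes at its vertex x3 = 0.5
  at <- function(x3) sim$mean_fun(matrix(c(0, 0, x3, 0, 0, 0), 1))
  expect_equal(log(at(0.5)) - log(at(0)), -4 * 0.5 + 4 * 0.25)
  # law of total variance: Var[w] = E[mu + mu^2/20] + Var[mu]
  v_true <- mean(sim$mu + sim$mu^2 / 20) + var(sim$mu)
  expect_lt(abs(var(sim$w) - v_true) / v_true, 0.1)
  expect_lt(abs(mean(sim$w) - mean(sim$mu)) / mean(sim$mu), 0.05)
})

test_that("clustered designs have the right shape and are seed-deterministic", {
  d <- simulate_clustered(14, 4, 16, seed = 67)
  expect_equal(nrow(d), 896L)
  expect_equal(length(unique(d$cluster)), 14L)
  expect_equal(as.vector(table(d$cluster)), rep(64L, 14L))
  d2 <- simulate_clustered(14, 4, 16, seed = 67)
  expect_identical(d, d2)
  # covariates are constant within a site across visits
  expect_equal(tapply(d$x1, d$site, function(v) max(v) - min(v)),
               tapply(d$x1, d$site, function(v) 0))
})
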