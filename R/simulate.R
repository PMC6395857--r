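# Synthetic count-data generators covering the package's three simulation
# studies: (1) twelve single-covariate scenarios spanning Poisson, NB, ZIP
# and ZINB families at small/large means and variances; (2) a sparse
# 56-parameter Poisson selection design; (3) a negative-binomial design with
# nonlinear mean response; plus a spatially clustered zero-inflated design
# for exercising leave-one-cluster-out cross-validation.

#' Catalog of single-covariate generating scenarios
#'
#' Twelve generating models: Poisson and zero-inflated Poisson (ZIP) at small
#' and large means, and negative binomial (NB) and zero-inflated NB (ZINB)
#' at small/large means crossed with small/large variances. The count mean is
#' \code{lambda_i = exp(beta0 + beta1 x_i)}; zero-inflated families mix
#' through \code{q_i ~ Bernoulli(pi_i)} with
#' \code{pi_i = plogis(alpha0 + alpha1 x_i)} and \code{w_i ~ family(lambda_i
#' q_i)}; NB families have \code{Var[w] = mu + mu^2/n} with size \code{n}.
#' Small/large mean gives \code{E[w | x = 0]} of 1 and 5; small/large
#' variance is size 1 and 0.1; zero-inflated scenarios have
#' \code{P(q = 0 | x = 0) = 1/4}.
#'
#' @return \code{data.frame} with one row per scenario: \code{scenario},
#'   \code{family}, \code{mean_level}, \code{var_level}, \code{beta0},
#'   \code{beta1}, \code{alpha0}, \code{alpha1}, \code{size}.
#' @export
table1_scenarios <- function() {
  rows <- list(
    list("poisson-small",    "poisson", "small", NA,      log(1),    NA),
    list("poisson-large",    "poisson", "large", NA,      log(5),    NA),
    list("nb-small-small",   "nb",      "small", "small", log(1),    1),
    list("nb-small-large",   "nb",      "small", "large", log(1),    0.1),
    list("nb-large-small",   "nb",      "large", "small", log(5),    1),
    list("nb-large-large",   "nb",      "large", "large", log(5),    0.1),
    list("zip-small",        "zip",     "small", NA,      log(4/3),  NA),
    list("zip-large",        "zip",     "large", NA,      log(20/3), NA),
    list("zinb-small-small", "zinb",    "small", "small", log(4/3),  1),
    list("zinb-small-large", "zinb",    "small", "large", log(4/3),  0.1),
    list("zinb-large-small", "zinb",    "large", "small", log(20/3), 1),
    list("zinb-large-large", "zinb",    "large", "large", log(20/3), 0.1))
  out <- data.frame(
    scenario = vapply(rows, `[[`, "", 1),
    family = vapply(rows, `[[`, "", 2),
    mean_level = vapply(rows, `[[`, "", 3),
    var_level = vapply(rows, function(r) as.character(r[[4]]), ""),
    beta0 = vapply(rows, `[[`, 0, 5),
    beta1 = 0.5,
    alpha0 = NA_real_, alpha1 = NA_real_,
    size = vapply(rows, function(r) as.numeric(r[[6]]), 0))
  zi <- out$family %in% c("zip", "zinb")
  out$alpha0[zi] <- log(3)
  out$alpha1[zi] <- 0.5
  out
}

#' Simulate one single-covariate scenario
#'
#' Draws \code{n} counts from the chosen generating model of
#' [table1_scenarios()], with the covariate fixed at \code{n} equally spaced
#' values between -2 and 2.
#'
#' @param scenario scenario id (e.g. \code{"nb-small-small"}) or a one-row
#'   subset of [table1_scenarios()].
#' @param seed optional integer seed.
#' @param n number of observations (default 500).
#' @return List with \code{w} (counts), \code{x} (covariate grid) and
#'   \code{params} (the scenario row).
#' @examples
#' sim <- simulate_table1("zip-small", seed = 1)
#' mean(sim$w == 0)
#' @export
simulate_table1 <- function(scenario, seed = NULL, n = 500) {
  if (is.character(scenario)) {
    cat <- table1_scenarios()
    row <- cat[cat$scenario == scenario, ]
    if (nrow(row) != 1L) stop("unknown scenario: ", scenario)
  } else row <- as.data.frame(scenario)
  if (!is.null(seed)) set.seed(seed)
  x <- seq(-2, 2, length.out = n)
  lambda <- exp(row$beta0 + row$beta1 * x)
  q <- if (row$family %in% c("zip", "zinb"))
    stats::rbinom(n, 1, stats::plogis(row$alpha0 + row$alpha1 * x)) else 1
  w <- switch(row$family,
    poisson = stats::rpois(n, lambda),
    zip     = stats::rpois(n, lambda * q),
    nb      = stats::rnbinom(n, size = row$size, mu = lambda),
    zinb    = ifelse(q == 0, 0L,
                     stats::rnbinom(n, size = row$size, mu = lambda)),
    stop("unknown family: ", row$family))
  list(w = as.integer(w), x = x, params = row)
}

#' Simulate the sparse Poisson variable-selection design
#'
#' Generates \code{n} observations from
#' \code{y_i ~ Poisson(exp(x_i' beta))} where the design holds an intercept,
#' 10 standard-normal covariates and all 45 pairwise interactions (56
#' parameters in total). \code{beta} is zero except for the intercept and
#' \code{m} randomly chosen slope entries set to +0.5 or -0.5 at random.
#'
#' @param m number of non-zero slopes, 0 to 10.
#' @param seed optional integer seed.
#' @param n observations (default 500).
#' @param beta0 intercept of the generating model (default 0).
#' @return List with \code{w} (counts), \code{X} (n x 56 design including the
#'   intercept column), and \code{beta_true} (length 56).
#' @examples
#' ncol(simulate_selection(3, seed = 1)$X)  # 56
#' @export
simulate_selection <- function(m, seed = NULL, n = 500, beta0 = 0) {
  stopifnot(m >= 0, m <= 10)
  if (!is.null(seed)) set.seed(seed)
  X0 <- matrix(stats::rnorm(n * 10), n, 10,
               dimnames = list(NULL, paste0("x", 1:10)))
  pairs <- utils::combn(10, 2)
  XI <- apply(pairs, 2, function(ij) X0[, ij[1]] * X0[, ij[2]])
  colnames(XI) <- apply(pairs, 2, function(ij)
    paste0("x", ij[1], ":x", ij[2]))
  X <- cbind("(Intercept)" = 1, X0, XI)
  beta <- numeric(ncol(X))
  beta[1] <- beta0
  if (m > 0) {
    idx <- 1L + sample.int(ncol(X) - 1L, m)
    beta[idx] <- sample(c(-0.5, 0.5), m, replace = TRUE)
  }
  w <- stats::rpois(n, exp(drop(X %*% beta)))
  list(w = as.integer(w), X = X,
       beta_true = stats::setNames(beta, colnames(X)))
}

#' Simulate the nonlinear-mean negative-binomial design
#'
#' Six uniform(0, 1) covariates of which only the first three act on the
#' mean: \code{mu = exp(sin(x1) + 3 (plogis(x2) - 0.5) + 1 - 4 x3 +
#' 4 x3^2)}, with \code{y ~ NB(mu, size = 20)}. Covariates 4-6 are pure
#' noise, so a selection method should leave their response curves flat.
#'
#' @param seed optional integer seed.
#' @param n observations (default 500).
#' @return List with \code{w} (counts), \code{X} (n x 6), \code{mu} (true
#'   means) and \code{mean_fun(X)}, the true mean function.
#' @export
simulate_nonlinear <- function(seed = NULL, n = 500) {
  if (!is.null(seed)) set.seed(seed)
  X <- matrix(stats::runif(n * 6), n, 6,
              dimnames = list(NULL, paste0("x", 1:6)))
  mean_fun <- function(X)
    exp(sin(X[, 1]) + 3 * (stats::plogis(X[, 2]) - 0.5) +
        1 - 4 * X[, 3] + 4 * X[, 3]^2)
  mu <- mean_fun(X)
  w <- stats::rnbinom(n, size = 20, mu = mu)
  list(w = as.integer(w), X = X, mu = mu, mean_fun = mean_fun)
}

#' Simulate spatially clustered zero-inflated counts
#'
#' Emulates a field design where sites are grouped into spatial clusters and
#' visited repeatedly: covariates have a shared cluster-level component plus
#' site-level noise (constant across visits), and counts are zero-inflated
#' negative binomial. Intended for exercising leave-one-cluster-out
#' cross-validation.
#'
#' @param n_clusters,sites_per_cluster,visits design dimensions (defaults
#'   14, 4, 16).
#' @param effects list with \code{beta0}, \code{beta} (covariate slopes;
#'   length sets the number of covariates), \code{alpha0} (logit of the
#'   Bernoulli success probability; lower means more structural zeros) and
#'   \code{size} (NB size).
#' @param seed optional integer seed.
#' @return \code{data.frame} with \code{cluster}, \code{site}, covariates
#'   \code{x1..xp} and counts \code{w}.
#' @examples
#' nrow(simulate_clustered(14, 4, 16, seed = 1))  # 896
#' @export
simulate_clustered <- function(n_clusters = 14, sites_per_cluster = 4,
                               visits = 16,
                               effects = list(beta0 = log(2),
                                              beta = c(0.8, -0.5),
                                              alpha0 = stats::qlogis(0.5),
                                              size = 0.7),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(effects$beta)
  n_sites <- n_clusters * sites_per_cluster
  clus <- rep(seq_len(n_clusters), each = sites_per_cluster)
  Cmat <- matrix(stats::rnorm(n_clusters * p), n_clusters, p)
  Xsite <- Cmat[clus, , drop = FALSE] * 0.8 +
           matrix(stats::rnorm(n_sites * p), n_sites, p) * 0.6
  colnames(Xsite) <- paste0("x", seq_len(p))
  rows <- rep(seq_len(n_sites), each = visits)
  X <- Xsite[rows, , drop = FALSE]
  eta <- effects$beta0 + drop(X %*% effects$beta)
  q <- stats::rbinom(length(rows), 1, stats::plogis(effects$alpha0))
  w <- ifelse(q == 0, 0L,
              stats::rnbinom(length(rows), size = effects$size,
                             mu = exp(eta)))
  data.frame(cluster = clus[rows], site = rows, X, w = as.integer(w))
}
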