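# ordcount

Bayesian ordinal probit regression for count data that are zero-inflated,
over-dispersed, or both — aimed at ecologists and epidemiologists who would
otherwise have to guess which parametric count family (Poisson, negative
binomial, ZIP, ZINB, ...) their data came from.

## The idea

A multinomial distribution can approximate any discrete marginal
distribution. So instead of committing to a count family, the observed
counts `w_i` are ranked — `y_i = rank(w_i)`, ties sharing a rank, with `J`
unique values `u_1 < ... < u_J` — and the ranks are modelled with an
ordered probit regression:

```
y_i = j  iff  b_{j-1} < z_i < b_j,        z_i ~ N(x_i' beta, 1)
```

with estimated breaks `b_1 < ... < b_{J-1}` (sentinels `b_0 = -Inf`,
`b_J = +Inf`), priors `beta ~ N(0, I)` and ordered-uniform breaks on
(-100, 100). The count scale returns through the expected count

```
E[w | x] = sum_j u_j [ Phi(b_j - x'beta) - Phi(b_{j-1} - x'beta) ]
```

Fitting is by data-augmentation Gibbs sampling (`fit_mn()`); all full
conditionals are conjugate. The MN-MS variant (`fit_mn_ms()`) additionally
performs Bayesian variable selection inside the sampler: conditional on the
latent `z` the coefficients of any covariate subset integrate out in closed
form, and subsets are explored by birth/death/swap Metropolis–Hastings
under a prior that weights every model size equally. Nonlinear responses
use linear-spline bases with knots at the 0.2/0.4/0.6/0.8 covariate
quantiles, each basis column selectable individually.

The package also ships the surrounding study machinery: generators for
twelve Poisson/NB/ZIP/ZINB scenarios, a sparse 56-parameter selection
design, a nonlinear NB design and spatially clustered counts
(`simulate_*`); adaptive-Metropolis fits of the parametric families with
split-chain R-hat monitoring (`fit_family()`); stepwise-AIC Poisson
selection (`greedy_aic_poisson()`); and the evaluation protocols —
credible-interval overlap of log-likelihoods (`compare_fit()`,
`run_table3()`), slope-identification scoring (`score_slopes()`) and
leave-one-cluster-out spatial cross-validation (`spatial_cv()`).

## Worked example

Zero-inflated negative-binomial data (61% zeros) fitted without being told
the family, then compared against the true-family fit:

```r
library(ordcount)
sim <- simulate_table1("zinb-small-small", seed = 42)   # 500 obs, x on [-2, 2]
mean(sim$w == 0)                                        # 0.608
fit <- fit_mn(sim$w, cbind(x = sim$x, x2 = sim$x^2),
              n_iter = 10000, burn = 5000, seed = 1)
summary(fit)
#> MN ordinal probit fit: n = 500 , J = 13 , 5000 stored draws
#>
#> Coefficients (posterior median and 95% CI):
#>    median  lower  upper
#> x   0.677  0.552  0.812
#> x2 -0.144 -0.270 -0.028
#>
#> Log-likelihood: -653.7 [-659.9, -649.9]

nb <- fit_family("nb", sim$w, cbind(x = sim$x), n_iter = 5000, seed = 2)
compare_fit(fit$llk, nb$llk)
#> A: median -653.7, CI [-659.9, -649.9]
#> B: median -670.6, CI [-674.2, -669.5]
#> Verdict: A_better
```

The positive slope on `x` (posterior median 0.68, CI excluding zero) is the
latent-scale trend induced by the generating slope of 0.5 on the log-mean;
the ordinal fit's log-likelihood interval sits wholly above the plain NB
fit's because the NB model here lacks the zero-inflation component while
the ordinal model absorbs it. `predict()` returns posterior-mean expected
counts with pointwise intervals, and `plot()` draws response curves with
knot locations for spline fits.

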