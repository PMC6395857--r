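---
title: "Ordinal probit regression for zero-inflated, over-dispersed counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal probit regression for zero-inflated, over-dispersed counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordcount)
```

## The model

Count data in ecology and epidemiology are routinely zero-inflated,
over-dispersed, or both, and the analyst rarely knows which parametric count
family (Poisson, negative binomial, their zero-inflated variants, ...) is
appropriate. `ordcount` side-steps that choice: since a multinomial
distribution can approximate any discrete marginal distribution, the observed
counts $w_i$ are reduced to ranks $y_i \in \{1, \dots, J\}$ of their $J$
unique values (ties share a rank) and modelled with an ordered probit
regression,

$$y_i = j \iff b_{j-1} < z_i < b_j, \qquad z_i \sim N(x_i^\top \beta, 1),$$

with sentinels $b_0 = -\infty$, $b_J = +\infty$. The breaks
$b_1 < \dots < b_{J-1}$ are estimated jointly with $\beta$ under the priors
$\beta \sim N(0, I)$ and an ordered uniform prior on $(-100, 100)$ for the
breaks. The design contains no intercept: a location shift of $z$ is
indistinguishable from a shift of all breaks, so the intercept is absorbed by
the breaks (this is the identifiability choice made by `build_design()`,
which also standardizes the columns because the unit-variance Gaussian prior
on $\beta$ presumes unit-scale covariates).

The count scale re-enters through the expected count

$$E[w \mid x] = \sum_{j=1}^{J} u_j \,
  [\Phi(b_j - x^\top \beta) - \Phi(b_{j-1} - x^\top \beta)],$$

where $u_1 < \dots < u_J$ are the unique observed counts. Because the rank
map is a bijection onto the observed support, $P(w_i = u_j) = P(y_i = j)$:
the model's log-likelihood on the rank scale *is* its log-likelihood on the
count scale, which is what makes it directly comparable with parametric
count-family fits.

### Sampling

All three full conditionals are conjugate, so `fit_mn()` runs a
systematic-scan Gibbs sampler with scan order $z \to b \to \beta$:

* $z_i \mid \cdot$ is $N(x_i^\top\beta, 1)$ truncated to
  $(b_{y_i - 1}, b_{y_i})$, drawn by the inverse-CDF method. The draw is
  reflected into the lower Gaussian tail before the CDF inversion so that
  far-tail intervals lose precision gracefully instead of saturating;
* $b_j \mid \cdot$ is uniform on $(\max\{z_i : y_i = j\},
  \min\{z_i : y_i = j + 1\})$ intersected with $(-100, 100)$ — with
  standardized covariates the prior bound is effectively inactive;
* $\beta \mid z \sim N(\Sigma X^\top z, \Sigma)$ with
  $\Sigma^{-1} = X^\top X + I$, drawn through a Cholesky factor computed
  once (the design is fixed).

Initialization is deterministic: breaks at the standard-normal quantiles of
the empirical cumulative rank frequencies (clipped to $\pm 99.9$), $\beta =
0$, and $z$ at interval midpoints ($\pm 1$ beyond the extreme breaks). This
is a valid state, mixes quickly, and makes chains bit-reproducible given a
seed. The default protocol is 50,000 iterations with the first half
discarded; the per-draw log-likelihood is stored so fits can be compared
afterwards without touching the draws.

Interval probabilities $\Phi(h) - \Phi(l)$ are evaluated on the log scale
with complementary-CDF arithmetic when both endpoints share a tail, and
floored at $10^{-300}$ with a counter (`n_floored` on the fit) rather than
returning $-\infty$.

## Simultaneous model selection (MN-MS)

Given the latent $z$, the coefficients of any covariate subset $k$
integrate out in closed form:

$$p(M_k \mid z) \propto \exp\!\big(\tfrac12 \mu_k^\top \Sigma_k^{-1} \mu_k
  - \tfrac12 z^\top z\big)\, |\Sigma_k|^{1/2},
  \qquad \Sigma_k^{-1} = X_k^\top X_k + I,\;
  \mu_k = \Sigma_k X_k^\top z,$$

with the prior $p(M_k) \propto (P+1)^{-1} \binom{P}{p_k}^{-1}$ that puts
equal mass on every model size. `fit_mn_ms()` explores subsets by proposing
the birth of an absent covariate, the death of an active one, or a swap
(simultaneous uniform add + drop), one move per Gibbs iteration by default
(`moves_per_iter`). The proposal ratio is 1 in the interior of model space;
at the boundary sizes ($p_k \in \{0, 1, P-1, P\}$) the feasible-move sets
differ between the current and proposed states, and the acceptance ratio
carries the corresponding correction so that detailed balance holds (the
suite verifies the stationary law empirically against exhaustive
enumeration). Coefficients of excluded columns are recorded as zero, so
posterior summaries and response curves are model-averaged; spline basis
columns enter selection individually rather than grouped per covariate,
which lets the data prune individual knots.

Two representational choices here were genuinely open. The swap move is
implemented as a simultaneous uniform add-and-drop rather than a sequential
death-then-birth; and excluded coefficients are stored as zeros rather than
dropped, because the zero-filled draws are exactly what the
slope-identification rules and model-averaged curves need.

## Splines and standardization

Nonlinear responses use linear splines: each covariate expands to
$[x, (x - \kappa_1)_+, \dots, (x - \kappa_K)_+]$ with knots at its 0.2,
0.4, 0.6 and 0.8 empirical quantiles (`quantile_knots()`, type-7
interpolated order statistics; the quantile definition is a documented
convention, since several exist). Knots are computed on the raw covariate
scale — keeping their quantile interpretation — and standardization is
applied to the basis columns afterwards; duplicate or boundary knots are
collapsed with a warning. Standardization divides by the population
standard deviation (a `sd_type` switch gives the sample version); either
satisfies "unit variance" to within $O(1/n)$.

## What the generators emulate

`simulate_table1()` draws from twelve single-covariate scenarios — Poisson,
NB, ZIP and ZINB crossed over small/large means ($E[w|x{=}0] \in \{1, 5\}$)
and, for NB families, small/large variance (size $n \in \{1, 0.1\}$, with
$\mathrm{Var} = \mu + \mu^2/n$) — over a fixed grid of 500 covariate values
equally spaced on $[-2, 2]$, slopes of $0.5$ on the log-mean and, for
zero-inflated families, a Bernoulli mixture with $P(q = 0 \mid x = 0) =
1/4$. `simulate_selection()` builds the sparse 56-parameter Poisson design
(intercept + 10 covariates + 45 pairwise interactions, $m$ slopes set to
$\pm 0.5$); `simulate_nonlinear()` draws NB counts (size 20) whose log-mean
combines a sinusoid, a scaled logistic and a quadratic in the first three
of six uniform covariates. The covariate distributions of the latter two
designs are a modelling choice (they are not implied by the designs
themselves): i.i.d. $N(0, 1)$ for the selection design and i.i.d.
$U(0, 1)$ for the nonlinear design — the unit interval keeps the
quadratic's vertex at $x_3 = 0.5$ inside the data range and the logistic
term active. The intercept of the selection design defaults to 0 (counts
of order 1). `simulate_clustered()` adds a spatially blocked ZINB design
(cluster-level covariate components plus site noise, repeated visits) for
exercising leave-one-cluster-out validation.

What these generators deliberately do *not* emulate: spatial covariate
fields, measurement error in covariates, temporal autocorrelation across
visits, and the heavy right tails of real trapping data. Tests passing on
these designs therefore demonstrate correctness of the algorithms and
calibration under the stated conditions, not performance on any particular
field dataset.

## Comparison protocols

* **Goodness of fit** (`compare_fit()`, `run_table3()`): two Bayesian fits
  are "equal" when the equal-tailed 95% credible intervals of their
  posterior log-likelihood draws overlap; otherwise the higher *median*
  wins (a summary had to be chosen for "highest log-likelihood"; with
  disjoint intervals any reasonable summary agrees). The ordinal fit uses
  the quadratic design $x + x^2$ for the single-covariate scenarios.
* **Slope identification** (`score_slopes()`): a truly non-zero slope is
  correct when its 95% CI excludes zero with the right sign; a true zero is
  correct when its CI covers zero; covariates excluded by a selection
  procedure count as estimated at zero.
* **Spatial validation** (`spatial_cv()`): each cluster is held out once;
  the point prediction is the posterior-mean expected count (the natural
  point predictor under squared-error loss), and fold MSE is compared
  pairwise across models. Held-out counts larger than anything seen in
  training are still scored against predictions on the training support
  $u$ — the expected count cannot exceed $\max u$, a documented limitation
  of the rank representation rather than an error.

The parametric baselines are fitted by 4-chain adaptive random-walk
Metropolis on the unconstrained scale (log size for NB), with diffuse
$N(0, 10^2)$ priors on coefficients and $N(0, 5^2)$ on log size, split-chain
$\hat{R} < 1.1$ as the convergence bar, and automatic doubling of the run
length (capped) when it is missed. These choices are this package's own;
they aim for likelihood-dominated posteriors so that fit comparisons are
about the likelihoods, not the priors.

## Problem sizes used by the test suite

The suite verifies the samplers against brute-force oracles at tiny sizes
(dense 3-D grid integration for a 6-observation fit; quadrature for the
closed-form marginal at $p \le 2$; exhaustive enumeration of all subsets at
$P \le 4$), checks interval coverage over 20 replicate fits at $n = 150$,
and runs the goodness-of-fit protocol at 10 datasets with 5,000-iteration
chains — enough for the CI-overlap verdicts, which stabilize well before
full chain length. The nonlinear-recovery check runs one dataset at the
full 50,000-iteration protocol. `scripts/acceptance.R` recomputes the NB
small-mean/small-variance goodness-of-fit proportion at the full protocol
(10 datasets, 50,000 iterations).

## Known limitations

* Predictions live on the training count support; extrapolation beyond
  $\max u$ is impossible by construction.
* A response with a single unique value has no breaks to estimate and is
  refused.
* The closed-form selection machinery is tied to the $N(0, I)$ coefficient
  prior; other priors would forfeit the closed-form marginal.
* Ranks discard the spacing of the observed counts during fitting (it
  re-enters only through $u$ in the expected count); with very few unique
  values the latent-scale resolution is coarse.
* The break prior's $(-100, 100)$ support is enforced but essentially
  never active once covariates are standardized.
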