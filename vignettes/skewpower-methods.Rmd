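---
title: "Sample size for skewed outcomes on the link scale: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample size for skewed outcomes on the link scale: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skewpower)
```

## The problem

A two-arm trial compares the mean of a heavily skewed outcome between a
reference and an intervention group: faecal hookworm egg counts per
Kato-Katz slide (negative binomial with dispersion `k` as small as 0.33),
insecticide concentrations on bednets (gamma with shape `kappa` well below
1), event counts (Poisson), or binary responses (binomial). Such data are
routinely analysed with a generalized linear model on the log (or logit)
scale, yet sample sizes are still often computed from a normal
approximation to the difference in raw means. When the analysis and the
sample-size calculation live on different scales, the achieved power can
drift away from the nominal value. `skewpower` computes sample sizes on the
*analysis* scale, quantifies how bad the normal approximation actually is
for a given design, and verifies achieved power by simulation.

## Sample sizes from GLM theory

For a two-group GLM with link `g` and variance function `V`, the covariance
of the coefficient estimates is `(X'WX)^{-1}` with diagonal weights
`w = (dmu/deta)^2 / V(mu)`. The group-effect estimate (the difference of
transformed means) therefore has variance `1/(N0 w0) + 1/(N1 w1)`. Treating
that estimate as normal and requiring two-sided level `alpha` and power
`1 - beta` for the effect `g(mu0) - g(mu1)` gives, with allocation
fractions `Q0 + Q1 = 1` and `v_i = V(mu_i) / (dmu/deta|_{mu_i})^2`:

* **method 2** (each arm's variance at its own mean; the default and the
  better-calibrated choice):
  `N = [ (z_{1-alpha/2} + z_{1-beta}) * sqrt(v1/Q1 + v0/Q0) / (g(mu0) - g(mu1)) ]^2`
* **method 1** (reference mean in both arms under the null): the
  `z_{1-alpha/2}` term instead uses `sqrt(v0 (1/Q1 + 1/Q0))`. Method 1 is
  asymmetric in the arm labels; method 2 is not. Both are exposed because
  parts of the sample-size literature use method 1.

The family specializations follow by substitution: with the log link
`v = 1/mu + 1/k` (negative binomial), `1/mu` (Poisson), `1/kappa` (gamma,
where the weight is exactly the shape), and with the logit link
`v = 1/(d mu (1 - mu))` (binomial proportion out of `d` trials). The
identity link recovers the classical difference-of-means formulas with
per-arm variances `V(mu_i)` — these are the "normal approximation" sizes
the package compares against. Note two conventions baked in deliberately:
the Poisson formula is the exact `k -> Inf` limit of the negative-binomial
one, and the binomial identity-scale formula keeps the per-arm (unpooled)
variances rather than a pooled `p(1-p)` term, so it is the direct identity
link specialization of the same engine.

```{r sizes}
glm_sample_size(71.4, 50, nb_family(0.33), link = "log",
                rounding = "nearest")
normal_approx_sample_size(71.4, 50, nb_family(0.33), rounding = "nearest")
```

### Parameters and their units

* `mu0`, `mu1` — arm means in outcome units (eggs/slide, mg/m^2, a
  probability for binomial). The effect is often given as efficacy
  `1 - mu1/mu0`.
* `k`, `kappa` — dispersion/shape; unitless. Small values mean heavy
  skewness; `k` here is the `size` of `rnbinom()` (some packages use its
  reciprocal — check before transplanting values). Both may differ between
  arms (`nb_family(k, k1 = )`), though the common case is equal.
* `Q0` — allocation fraction of the reference arm; default 0.5.
* `alpha` (two-sided, default 0.05) and `power` (default 0.9).

Normal quantiles are computed exactly with `qnorm()`, never from 2-decimal
tables; this keeps the monotonicity properties of the formulas exact.

### Rounding

`N_real` is reported unrounded and the per-arm sizes are
`Q_i * N_real` rounded per the `rounding` argument. The default is
`ceiling` (never deliver less than the computed size); `nearest` (halves
up, via `floor(x + 0.5)`, avoiding round-half-to-even) exists because
published worked examples round that way, and `504.5 -> 505` /
`531.05 -> 531` only reproduces under nearest rounding of the half-total.
The two conventions never differ by more than one subject per arm.

## How wrong is the normal approximation?

Two diagnostics, both for the standardized mean of `n` iid observations.

**Berry–Esséen bound.** `|F_n(y) - Phi(y)| <= C * rho / (sigma^3 sqrt(n))`
where `rho = E|Y - mu|^3`. The constant is chosen explicitly: 0.4690
(general iid case, Shevtsova), or the sharper 0.3051 admissible for
Poisson sums — including the Poisson itself and the negative binomial as a
Poisson mixture. `suggest_be_constant()` encodes that rule;
`third_abs_moment()` computes `rho` by direct summation with a rigorous
tail bound: past a cutoff the pmf ratio `p(y+1)/p(y)` is below some
`r < 1` (`mu/(y+1)` for Poisson, `mu/(mu+k)` for the negative binomial),
so the neglected cubic-weighted tail is dominated by a geometric series
with a closed-form sum. Summation extends until that remainder is below
`tol` (default 1e-10, far finer than the 3 significant figures anyone
reports), and the remainder is returned as `truncation_error_bound`. The
Bernoulli case uses the closed form `mu(1-mu)(mu^2 + (1-mu)^2)`; the gamma
case uses adaptive quadrature and is flagged experimental since the
discrete families are the ones this diagnostic is aimed at.

**Exact CDF discrepancy.** The three discrete families are closed under
iid summation, so `max_y |F_sum(y) - Phi((y - n mu)/sqrt(n V(mu)))|` can be
computed exactly. Conventions, fixed once: the discrepancy is evaluated at
every lattice point using the *right-continuous* CDF value; the
standardization uses the exact sum mean and standard deviation with no
continuity correction; the support is scanned until both tails hold less
than `eps = 1e-12`. A `sup = TRUE` flag additionally compares the CDF
against the normal at the right end of each flat segment (the true
supremum over the real line). For the small-mean configurations of
interest the two agree; the supremum convention is also the one under
which the binomial `mu <-> 1 - mu` relabeling symmetry is exact, because
mirroring maps right segment ends onto left ones.

```{r errgrid}
normal_error_grid(
  tibble::tibble(family = "poisson", mu = c(0.05, 0.1, 10, 50)),
  n = 100
)
```

The bound is loose — typically 2–5 times the exact discrepancy — but it is
distribution-independent given three moments and available when exact
computation is not. Both show the same structure: the approximation
deteriorates as means shrink and skewness grows, with errors above 10% of
probability for rare-event designs (`mu` around 1–5% at `n = 100`).

## Monte-Carlo verification of achieved power

`estimate_power()` generates replicate two-arm datasets, fits the
two-group GLM on the canonical analysis scale (log for counts and gamma,
logit for binomial — datasets sized by the identity-scale formulas are
still *analysed* on the canonical scale, since what is being compared is
sizing methods, not analyses), applies Wald and/or likelihood-ratio tests
at the design's `alpha`, and reports the rejection proportion with a
Wilson 95% interval as the Monte-Carlo error (well-behaved near 0 and 1,
where the Wald interval for a proportion is not).

Numerical choices worth knowing:

* Saturated two-group models with these links have closed-form mean MLEs
  (the arm sample means), so no IRLS is run. The common negative-binomial
  `k` and gamma `kappa` are estimated by solving the profile-likelihood
  score equation in `log k` with Brent's method (`uniroot`), bracketed
  from a method-of-moments start; Brent was preferred over Newton with
  bisection fallback purely for robustness — the profile score is smooth
  and monotone decreasing in the bracket, so both find the same root. The
  fits agree with `MASS::glm.nb` / `MASS::gamma.shape` to at least 1e-6,
  which the test suite verifies against those independent references.
* A sample less dispersed than Poisson has no finite root of the `k`
  score; the fit then returns `k = Inf` and Poisson weights rather than
  failing.
* The likelihood-ratio test re-estimates the dispersion under the
  common-mean null, and the statistic is floored at 0.
* An arm whose sample mean sits on the link boundary (all-zero counts, or
  an all-0/all-1 binary arm) is flagged `converged = FALSE`, counted in
  `n_nonconverged`, and excluded from the rejection denominator — never
  silently dropped into either tally. How published simulation studies
  handled such replicates is generally unstated; this is the package's
  own documented rule.
* Replicate `r` seeds its RNG substream as a fixed counter-based function
  of the root seed and `r`, so results are reproducible and independent
  of execution order or parallel chunking.

```{r power, eval = FALSE}
n <- glm_sample_size(71.4, 50, nb_family(0.33), rounding = "nearest")
plan <- simulation_plan(71.4, 50, nb_family(0.33), N0 = n$N0, N1 = n$N1,
                        n_reps = 2000, seed = 1, test = c("wald", "lrt"))
estimate_power(plan)
```

## What the generator emulates, and what it does not

The simulation engine draws iid observations from the exact parametric
families — precisely the sampling model under which the size formulas are
derived. Passing power checks therefore demonstrate *internal* calibration:
that the formulas deliver their nominal power when the data truly are
negative binomial (or Poisson, binomial, gamma) with the stated
parameters. They say nothing about misspecification: real egg-count data
may be zero-inflated, have dispersion varying with covariates, or
correlate within clusters, none of which the generator produces. Nor are
pilot-estimate uncertainties in `k` or `kappa` propagated — the inputs are
treated as known design constants.

Default problem sizes in the shipped tests and acceptance script — 2,000
replicates for power and type-I error checks, 1,000 for the conservatism
and test-comparison properties, 200 subjects per arm for null simulations —
were chosen so the Monte-Carlo error (about ±1.7 percentage points at 99%
confidence around 90% power with 2,000 replicates) is small relative to
the effects being demonstrated. Full publication-grade grids at 10,000
replicates per point are a long-running script a user can write with
`estimate_power_grid()`, not something the test suite re-runs.

## Known limitations

* Two arms only; no covariates, non-inferiority margins, or cluster
  designs.
* Per-arm dispersions are accepted by the size formulas, but the fitting
  engine estimates a single common `k` (or `kappa`) — the standard
  `glm.nb`-style analysis.
* The exact-discrepancy diagnostic covers the discrete families; the gamma
  enters only through the (experimental) quadrature moments in the
  Berry–Esséen bound.
* The sharper Berry–Esséen constants published for special binomial cases
  (success probability 0.5, or unit denominator at `n >= 200`) are not
  implemented; the general 0.4690 is used for all binomial configurations.
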