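# skewpower

Sample-size and power calculations for comparing two group means of
**skewed outcomes** — negative binomial, Poisson, binomial, and gamma —
done on the scale the data will actually be analysed on.

Trials with heavily skewed endpoints (hookworm egg counts per Kato-Katz
slide, insecticide concentrations on bednets, event counts, costs) are
usually analysed by a generalized linear model with a log or logit link,
yet their sample sizes are often still computed from a normal
approximation to the difference in raw means. `skewpower` is for
biostatisticians and trial designers who want the two to match. It
provides:

* **GLM-theory sample sizes.** For a two-group comparison with link `g`,
  variance function `V` and GLM weight `w = (dμ/dη)²/V(μ)`, the required
  total size is

  ```
  N = [ (z₁₋α/₂ + z₁₋β) · √( v₁/Q₁ + v₀/Q₀ ) / (g(μ₀) − g(μ₁)) ]²,
      vᵢ = V(μᵢ) / (dμ/dη|μᵢ)²
  ```

  ("method 2"; a "method 1" variant evaluating the null variance at the
  reference mean is also available). Family specializations: log-link
  negative binomial (`vᵢ = 1/μᵢ + 1/kᵢ`), Poisson (`1/μᵢ`, the `k → ∞`
  limit), logit-link binomial (`1/(d μᵢ(1−μᵢ))`), log-link gamma
  (`1/κᵢ`). The identity link recovers the classical difference-of-means
  formulas for comparison.
* **Normal-approximation diagnostics**: Berry–Esséen bounds
  `C·ρ/(σ³√n)` with numerically computed absolute third central moments
  (constant 0.3051 for Poisson/negative-binomial sums, 0.4690 otherwise),
  and the *exact* maximum discrepancy between the CDF of a standardized
  iid sum and the standard normal, computed from the closed-form sum
  distributions of the discrete families.
* **Monte-Carlo power verification**: seeded replicate datasets, exact
  ML two-group GLM fits (profile-likelihood dispersion), Wald and
  likelihood-ratio tests, Wilson confidence intervals for the rejection
  proportion, explicit nonconvergence accounting.

Everything returns tibbles, pipes cleanly, and has `tidy()`/`glance()`
and `autoplot()` methods. A thin command-line wrapper
(`inst/cli/skewpower`) exposes `size`, `bounds`, `discrepancy` and
`verify` subcommands with JSON/CSV/text reports.

## Worked example: a hookworm vaccine trial

Faecal egg counts with reference mean 71.4 eggs/slide, 30% vaccine
efficacy (intervention mean 50), heavy overdispersion `k = 0.33`, equal
allocation, two-sided α = 0.05, 90% power:

```r
library(skewpower)

glm_sample_size(71.4, 50, nb_family(0.33), link = "log",
                rounding = "nearest")
#> # A tibble: 1 × 16
#>   family   link  method   mu0   mu1    Q0    Q1 alpha power N_real    N0    N1
#>   <chr>    <chr> <chr>  <dbl> <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl> <int> <int>
#> 1 negativ… log   metho…  71.4    50   0.5   0.5  0.05   0.9  1009.   505   505
#> # ℹ 4 more variables: N_total <int>, sigma_null <dbl>, sigma_alt <dbl>,
#> #   rounding <chr>

normal_approx_sample_size(71.4, 50, nb_family(0.33), rounding = "nearest")$N1
#> [1] 531
```

The log-link calculation asks for **505 subjects per arm** (unrounded
total 1009.0); sizing the same trial from the normal approximation to the
difference in means asks for **531 per arm** — 5% more, and the gap widens
rapidly at higher efficacy, where the identity-scale size can overshoot by
more than 50%. Simulation confirms the log-link size holds its nominal
power:

```r
plan <- simulation_plan(71.4, 50, nb_family(0.33), N0 = 505, N1 = 505,
                        n_reps = 2000, seed = 1, test = "wald")
estimate_power(plan)[, c("test", "power", "conf.low", "conf.high")]
#> # A tibble: 1 × 4
#>   test  power conf.low conf.high
#>   <chr> <dbl>    <dbl>     <dbl>
#> 1 wald  0.895    0.881     0.908
```

i.e. an estimated 89.5% rejection rate (Wilson 95% interval 88.1–90.8%)
against the nominal 90%. How trustworthy was the normal approximation to
begin with? For 100 observations of a rare binary event (`μ = 0.05`):

```r
max_normal_discrepancy(binomial_family(1), 0.05, 100)[, 1:5]
#> # A tibble: 1 × 5
#>   family      mu     n max_abs_diff at_sum
#>   <chr>    <dbl> <int>        <dbl>  <dbl>
#> 1 binomial  0.05   100        0.116      5
```

The true CDF of the standardized mean differs from the normal by up to
0.116 — 11.6 percentage points of probability, at 5 observed events.

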