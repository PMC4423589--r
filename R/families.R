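#' Outcome family specifications
#'
#' Constructors for the four exponential-family outcome models used by the
#' sample-size formulas, the normal-approximation diagnostics and the power
#' simulations. Each returns an `outcome_family` object holding the family
#' identifier and its per-arm dispersion parameters.
#'
#' Parameterizations:
#' * **Negative binomial**: mean `mu` and shape `k`, with variance function
#'   `V(mu) = mu + mu^2/k`. Small `k` means heavy overdispersion and
#'   `k -> Inf` recovers the Poisson. Note that some software (and some of
#'   the sample-size literature) uses the *reciprocal* of this `k`; here `k`
#'   is the `size` argument of [stats::rnbinom()].
#' * **Poisson**: mean `mu`, `V(mu) = mu`; no dispersion parameter.
#' * **Binomial**: each observation is the *proportion* of successes out of
#'   `d` independent Bernoulli trials with success probability `mu`, so
#'   `E(Y) = mu` and `V(mu) = mu(1-mu)/d`. The common person-level 0/1
#'   outcome is `d = 1`.
#' * **Gamma**: mean `mu` and shape `kappa`; the scale `theta = mu/kappa` is
#'   always derived, never stored, so `V(mu) = mu^2/kappa`.
#'
#' Dispersion parameters may differ between the reference arm (arm 0) and
#' the intervention arm (arm 1); the single-argument forms cover the common
#' equal-dispersion case.
#'
#' @param k,k1 Negative binomial shape (dispersion) parameter for arm 0 and
#'   arm 1. `k1` defaults to `k`.
#' @param kappa,kappa1 Gamma shape parameter for arm 0 and arm 1.
#' @param d Binomial denominator: number of Bernoulli trials per
#'   observation (positive integer, default 1).
#' @return An object of class `outcome_family`: a list with elements
#'   `family_id`, `dispersion0`, `dispersion1` and `denominator_d`.
#' @examples
#' nb_family(0.33)
#' binomial_family(d = 5)
#' gamma_family(0.639)
#' @name outcome_family
NULL

#' @rdname outcome_family
#' @export
nb_family <- function(k, k1 = k) {
  new_outcome_family("negative_binomial", dispersion0 = k, dispersion1 = k1)
}

#' @rdname outcome_family
#' @export
poisson_family <- function() {
  new_outcome_family("poisson")
}

#' @rdname outcome_family
#' @export
binomial_family <- function(d = 1) {
  if (length(d) != 1 || !is.finite(d) || d < 1 || d != round(d)) {
    stop("`d` must be a single integer >= 1", call. = FALSE)
  }
  new_outcome_family("binomial", denominator_d = as.integer(d))
}

#' @rdname outcome_family
#' @export
gamma_family <- function(kappa, kappa1 = kappa) {
  new_outcome_family("gamma", dispersion0 = kappa, dispersion1 = kappa1)
}

FAMILY_IDS <- c("negative_binomial", "poisson", "binomial", "gamma")

new_outcome_family <- function(family_id, dispersion0 = NA_real_,
                               dispersion1 = NA_real_, denominator_d = 1L) {
  family_id <- match.arg(family_id, FAMILY_IDS)
  if (family_id %in% c("negative_binomial", "gamma")) {
    for (nm in c("dispersion0", "dispersion1")) {
      val <- get(nm)
      if (length(val) != 1 || !is.finite(val) && !identical(val, Inf) ||
          is.na(val) || val <= 0) {
        stop(sprintf("`%s` must be a single positive number", nm),
             call. = FALSE)
      }
    }
  }
  structure(
    list(family_id = family_id,
         dispersion0 = as.numeric(dispersion0),
         dispersion1 = as.numeric(dispersion1),
         denominator_d = as.integer(denominator_d)),
    class = "outcome_family"
  )
}

#' @export
print.outcome_family <- function(x, ...) {
  cat("<outcome_family> ", x$family_id, "\n", sep = "")
  if (x$family_id %in% c("negative_binomial", "gamma")) {
    lab <- if (x$family_id == "gamma") "kappa" else "k"
    cat("  ", lab, "0 = ", format(x$dispersion0),
        ", ", lab, "1 = ", format(x$dispersion1), "\n", sep = "")
  }
  if (x$family_id == "binomial") {
    cat("  denominator d =", x$denominator_d, "\n")
  }
  invisible(x)
}

# dispersion parameter for one arm; NA for families without one
dispersion <- function(family, arm) {
  stopifnot(inherits(family, "outcome_family"), arm %in% c(0, 1))
  if (arm == 0) family$dispersion0 else family$dispersion1
}

check_mu <- function(family, mu) {
  if (length(mu) != 1 || !is.finite(mu)) {
    stop("`mu` must be a single finite number", call. = FALSE)
  }
  if (family$family_id == "binomial") {
    if (mu <= 0 || mu >= 1) {
      stop("`mu` must lie strictly between 0 and 1 for the binomial family",
           call. = FALSE)
    }
  } else if (mu <= 0) {
    stop(sprintf("`mu` must be positive for the %s family", family$family_id),
         call. = FALSE)
  }
  invisible(mu)
}

#' Link function specifications
#'
#' A link maps the mean `mu` to the linear predictor `eta = g(mu)`. The GLM
#' weight and sample-size machinery needs the forward map, its inverse, and
#' the derivative `dmu/deta` expressed as a function of `mu`:
#' `mu` for the log link, `mu (1 - mu)` for the logit link, and 1 for the
#' identity link.
#'
#' @param link_id One of `"log"`, `"logit"`, `"identity"`.
#' @return An object of class `glm_link`: a list with elements `link_id`,
#'   `g` (forward map), `ginv` (inverse map) and `dmu_deta` (derivative as a
#'   function of `mu`).
#' @examples
#' lk <- link_spec("logit")
#' lk$g(0.3)
#' lk$dmu_deta(0.3)
#' @export
link_spec <- function(link_id = c("log", "logit", "identity")) {
  link_id <- match.arg(link_id)
  spec <- switch(link_id,
    log = list(g = log, ginv = exp, dmu_deta = function(mu) mu),
    logit = list(g = stats::qlogis, ginv = stats::plogis,
                 dmu_deta = function(mu) mu * (1 - mu)),
    identity = list(g = identity, ginv = identity,
                    dmu_deta = function(mu) rep(1, length(mu)))
  )
  structure(c(list(link_id = link_id), spec), class = "glm_link")
}

as_link <- function(link) {
  if (inherits(link, "glm_link")) link else link_spec(link)
}

#' Variance function of an outcome family
#'
#' Evaluates the mean-variance relationship `V(mu)` of the family, using the
#' dispersion parameter of the requested arm: `mu + mu^2/k` (negative
#' binomial), `mu` (Poisson), `mu(1-mu)/d` (binomial proportion out of `d`
#' trials), `mu^2/kappa` (gamma).
#'
#' @param family An [outcome_family] object.
#' @param mu The mean (in `(0,1)` for binomial, positive otherwise).
#' @param arm Which arm's dispersion parameter to use: 0 (reference) or
#'   1 (intervention).
#' @return The variance of a single observation, a positive number.
#' @examples
#' variance_function(nb_family(0.33), 71.4)  # 71.4 + 71.4^2 / 0.33
#' variance_function(binomial_family(), 0.5) # 0.25
#' @export
variance_function <- function(family, mu, arm = 0) {
  stopifnot(inherits(family, "outcome_family"))
  check_mu(family, mu)
  switch(family$family_id,
    negative_binomial = mu + mu^2 / dispersion(family, arm),
    poisson = mu,
    binomial = mu * (1 - mu) / family$denominator_d,
    gamma = mu^2 / dispersion(family, arm)
  )
}

#' GLM weight for a family/link pair
#'
#' The diagonal weight of the GLM information matrix,
#' `w = (dmu/deta)^2 / V(mu)`. For the gamma family with log link this is
#' exactly the shape `kappa`; for the binomial with logit link it is
#' `d mu (1 - mu)`; for the negative binomial with log link it is
#' `1 / (1/mu + 1/k)`.
#'
#' @inheritParams variance_function
#' @param link A [link_spec] object or one of `"log"`, `"logit"`,
#'   `"identity"`.
#' @return The weight, a positive number.
#' @examples
#' glm_weight(gamma_family(0.639), "log", 8.46) # = 0.639
#' glm_weight(poisson_family(), "log", 2)       # = 2
#' @export
glm_weight <- function(family, link, mu, arm = 0) {
  stopifnot(inherits(family, "outcome_family"))
  link <- as_link(link)
  check_mu(family, mu)
  if (family$family_id == "binomial" && link$link_id == "log" && mu >= 1) {
    stop("log link requires mu < 1 for the binomial family", call. = FALSE)
  }
  link$dmu_deta(mu)^2 / variance_function(family, mu, arm)
}

#' Exact distribution of a sum of iid observations
#'
#' The negative binomial, Poisson and binomial families are closed under iid
#' summation: the sum of `n` observations is again in the family, with the
#' shape (NB), mean (Poisson) or denominator (binomial) scaled by `n`. The
#' gamma sum (shape `n * kappa`) is provided for completeness. The returned
#' object carries the exact CDF of the sum, used to compute the maximum
#' discrepancy from the approximating normal.
#'
#' For the binomial family, the "observation" is a proportion out of `d`, so
#' the sum lives on the lattice `{0, 1/d, 2/d, ...}`; `count_cdf`/`count_pmf`
#' operate on the underlying integer success count `s`, and `scale` converts
#' a count to a sum value (`y = s * scale`).
#'
#' @inheritParams variance_function
#' @param n Number of iid observations summed, a positive integer.
#' @return An object of class `sum_distribution`: a list with
#'   `family_id`, `n`, `mean`, `variance`, `support`
#'   (`"integer lattice"` or `"positive reals"`), `scale` (lattice step),
#'   and functions `count_cdf`, `count_pmf`, `count_quantile` (discrete
#'   families) or `cdf` (gamma).
#' @examples
#' sd5 <- sum_distribution(poisson_family(), 0.05, 100)
#' sd5$mean      # 5
#' sd5$count_cdf(5)
#' @export
sum_distribution <- function(family, mu, n, arm = 0) {
  stopifnot(inherits(family, "outcome_family"))
  check_mu(family, mu)
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  mean_sum <- n * mu
  var_sum <- n * variance_function(family, mu, arm)
  base <- list(family_id = family$family_id, n = n,
               mean = mean_sum, variance = var_sum)
  out <- switch(family$family_id,
    negative_binomial = {
      shape <- n * dispersion(family, arm)
      c(base, list(
        support = "integer lattice", scale = 1, shape = shape,
        count_cdf = function(s) stats::pnbinom(s, size = shape, mu = mean_sum),
        count_pmf = function(s) stats::dnbinom(s, size = shape, mu = mean_sum),
        count_quantile = function(p) stats::qnbinom(p, size = shape,
                                                    mu = mean_sum)
      ))
    },
    poisson = c(base, list(
      support = "integer lattice", scale = 1,
      count_cdf = function(s) stats::ppois(s, lambda = mean_sum),
      count_pmf = function(s) stats::dpois(s, lambda = mean_sum),
      count_quantile = function(p) stats::qpois(p, lambda = mean_sum)
    )),
    binomial = {
      size <- n * family$denominator_d
      c(base, list(
        support = "integer lattice", scale = 1 / family$denominator_d,
        size = size,
        count_cdf = function(s) stats::pbinom(s, size = size, prob = mu),
        count_pmf = function(s) stats::dbinom(s, size = size, prob = mu),
        count_quantile = function(p) stats::qbinom(p, size = size, prob = mu)
      ))
    },
    gamma = {
      shape <- n * dispersion(family, arm)
      scale_par <- mu / dispersion(family, arm)
      c(base, list(
        support = "positive reals", scale = NA_real_, shape = shape,
        cdf = function(y) stats::pgamma(y, shape = shape, scale = scale_par)
      ))
    }
  )
  structure(out, class = "sum_distribution")
}

#' Draw iid observations from an outcome family
#'
#' Random draws for the Monte-Carlo power engine. Binomial draws are
#' returned on the proportion scale (`y/d`) so that the empirical mean
#' converges to `mu` for every family.
#'
#' @inheritParams variance_function
#' @param n Number of draws.
#' @param seed Optional integer; if supplied the draws are reproducible and
#'   the caller's RNG state is left untouched.
#' @return A numeric vector of length `n`.
#' @examples
#' sample_outcomes(nb_family(0.33), 50, 5, seed = 1)
#' @export
sample_outcomes <- function(family, mu, n, arm = 0, seed = NULL) {
  stopifnot(inherits(family, "outcome_family"))
  if (length(mu) != 1 || !is.finite(mu) || mu < 0) {
    stop("`mu` must be a single nonnegative number", call. = FALSE)
  }
  if (mu > 0) check_mu(family, mu)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  if (mu == 0 && family$family_id != "gamma") return(numeric(n))
  switch(family$family_id,
    negative_binomial = stats::rnbinom(n, size = dispersion(family, arm),
                                       mu = mu),
    poisson = stats::rpois(n, lambda = mu),
    binomial = stats::rbinom(n, size = family$denominator_d, prob = mu) /
      family$denominator_d,
    gamma = stats::rgamma(n, shape = dispersion(family, arm),
                          scale = mu / dispersion(family, arm))
  )
}
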