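#' Sample size for comparing two means on the link scale
#'
#' Computes the total and per-arm sample sizes required to detect a
#' difference between two group means with a two-sided test at level
#' `alpha` and power `power`, where the analysis is a two-group GLM on the
#' scale of the link function. The derivation treats the GLM estimate of
#' the difference in transformed means as approximately normal, with
#' variance `1/(N0 w0) + 1/(N1 w1)` from the inverse information matrix,
#' where `w = (dmu/deta)^2 / V(mu)` is the GLM weight.
#'
#' Two conventions are offered for the variance under the null hypothesis:
#'
#' * **method 1** evaluates both arms at the reference mean `mu0` under the
#'   null, so the alpha and beta terms use different variances;
#' * **method 2** evaluates each arm at its own mean, so the null and
#'   alternative standard deviations coincide and the formula collapses to
#'   `N = [(z_{1-a/2} + z_{1-b}) * sqrt(V_1/Q1 + V_0/Q0) / (g(mu0) - g(mu1))]^2`
#'   with `V_i = V(mu_i)/(dmu/deta|mu_i)^2`.
#'
#' Method 2 is the default and the recommended choice. With the identity
#' link, method 2 reproduces the classical normal-approximation formulas
#' (see [normal_approx_sample_size()]).
#'
#' Normal quantiles are computed exactly via [stats::qnorm()], not from
#' tabulated 2-decimal values. The unrounded `N_real` is always reported;
#' per-arm integer sizes are obtained with [allocate_and_round()], by
#' default conservatively (`ceiling`).
#'
#' @param mu0,mu1 Means in the reference (arm 0) and intervention (arm 1)
#'   groups, in outcome units. Must differ.
#' @param family An [outcome_family] object.
#' @param link A [link_spec] or one of `"log"`, `"logit"`, `"identity"`.
#'   The log link is the usual analysis scale for counts and gamma
#'   outcomes; logit for binomial.
#' @param Q0 Allocation fraction of the reference arm, in (0,1);
#'   `Q1 = 1 - Q0`.
#' @param alpha Two-sided significance level.
#' @param power Target power `1 - beta`.
#' @param method `"method2"` (default) or `"method1"`; see Details.
#' @param rounding Per-arm rounding mode, `"ceiling"` (default,
#'   conservative) or `"nearest"`.
#' @return A one-row tibble of class `sample_size_result` with columns
#'   `family`, `link`, `method`, `mu0`, `mu1`, `Q0`, `Q1`, `alpha`,
#'   `power`, `N_real` (unrounded total), `N0`, `N1` (rounded per-arm
#'   sizes), `N_total`, `sigma_null`, `sigma_alt` (the null/alternative
#'   standard deviations of the link-scale difference at `N = 1`), and
#'   `rounding`.
#' @examples
#' # hookworm vaccine trial: 30% efficacy on egg counts, heavy overdispersion
#' glm_sample_size(71.4, 50, nb_family(0.33), link = "log",
#'                 rounding = "nearest")
#' @seealso [normal_approx_sample_size()], [allocate_and_round()]
#' @export
glm_sample_size <- function(mu0, mu1, family, link = "log", Q0 = 0.5,
                            alpha = 0.05, power = 0.9,
                            method = c("method2", "method1"),
                            rounding = c("ceiling", "nearest")) {
  stopifnot(inherits(family, "outcome_family"))
  link <- as_link(link)
  method <- match.arg(method)
  rounding <- match.arg(rounding)
  check_design(mu0, mu1, family, Q0, alpha, power)
  Q1 <- 1 - Q0
  if (isTRUE(all.equal(link$g(mu0), link$g(mu1)))) {
    stop("degenerate effect: g(mu0) equals g(mu1); sample size is undefined",
         call. = FALSE)
  }
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)

  # per-observation link-scale variances V(mu)/(dmu/deta)^2, per arm
  v0 <- variance_function(family, mu0, arm = 0) / link$dmu_deta(mu0)^2
  v1 <- variance_function(family, mu1, arm = 1) / link$dmu_deta(mu1)^2
  delta <- link$g(mu0) - link$g(mu1)

  sigma_alt1 <- sqrt(v1 / Q1 + v0 / Q0)
  sigma_null1 <- switch(method,
    method1 = sqrt(v0 * (1 / Q1 + 1 / Q0)),
    method2 = sigma_alt1
  )
  sqrtN <- (za * sigma_null1 + zb * sigma_alt1) / abs(delta)
  N_real <- sqrtN^2
  arms <- allocate_and_round(N_real, Q0, Q1, mode = rounding)

  tibble::new_tibble(
    tibble::tibble(
      family = family$family_id,
      link = link$link_id,
      method = method,
      mu0 = mu0, mu1 = mu1, Q0 = Q0, Q1 = Q1,
      alpha = alpha, power = power,
      N_real = N_real,
      N0 = arms[[1]], N1 = arms[[2]],
      N_total = arms[[1]] + arms[[2]],
      sigma_null = sigma_null1,
      sigma_alt = sigma_alt1,
      rounding = rounding
    ),
    class = "sample_size_result"
  )
}

#' Normal-approximation sample size (identity scale)
#'
#' The classical difference-in-means formula: method 2 applied on the
#' identity link, i.e.
#' `N = [(z_{1-a/2} + z_{1-b}) * sqrt(V(mu1)/Q1 + V(mu0)/Q0) / (mu0 - mu1)]^2`
#' with each family's own variance function. For the negative binomial this
#' is the familiar normal approximation with per-arm variances
#' `mu + mu^2/k`; for the binomial it is the unpooled difference-in-
#' proportions formula (no pooled `p(1-p)` term).
#'
#' @inheritParams glm_sample_size
#' @return A one-row `sample_size_result` tibble; see [glm_sample_size()].
#' @examples
#' normal_approx_sample_size(71.4, 50, nb_family(0.33), rounding = "nearest")
#' @export
normal_approx_sample_size <- function(mu0, mu1, family, Q0 = 0.5,
                                      alpha = 0.05, power = 0.9,
                                      rounding = c("ceiling", "nearest")) {
  glm_sample_size(mu0, mu1, family, link = "identity", Q0 = Q0,
                  alpha = alpha, power = power, method = "method2",
                  rounding = match.arg(rounding))
}

#' Split a total sample size into rounded per-arm sizes
#'
#' @param N_real Unrounded total sample size, positive.
#' @param Q0,Q1 Allocation fractions (must sum to 1).
#' @param mode `"ceiling"` rounds each arm up (conservative default);
#'   `"nearest"` rounds each arm to the nearest integer (halves round up).
#' @return An integer vector `c(N0, N1)`.
#' @examples
#' allocate_and_round(1009.1, 0.5, 0.5, "nearest")  # 505 per arm
#' @export
allocate_and_round <- function(N_real, Q0, Q1 = 1 - Q0,
                               mode = c("ceiling", "nearest")) {
  mode <- match.arg(mode)
  if (!is.finite(N_real) || N_real <= 0) {
    stop("`N_real` must be a positive finite number", call. = FALSE)
  }
  if (abs(Q0 + Q1 - 1) > 1e-12 || Q0 <= 0 || Q0 >= 1) {
    stop("allocation fractions must lie in (0,1) and sum to 1",
         call. = FALSE)
  }
  raw <- c(Q0, Q1) * N_real
  n <- switch(mode,
    ceiling = ceiling(raw),
    nearest = floor(raw + 0.5)  # half always rounds up, unlike round()
  )
  as.integer(pmax(n, 1))
}

#' Convert an event rate to a probability over a time window
#'
#' An endpoint observed as a count with rate `mu` per unit time can instead
#' be dichotomized as "at least one event in duration `T`", a binomial
#' proportion `1 - exp(-mu * T)`. Useful to compare the sample size cost of
#' analysing a rate versus a proportion for the same underlying process
#' (the rate retains more information).
#'
#' @param mu Event rate per unit time, nonnegative.
#' @param T_duration Length of the observation window, positive.
#' @return The probability of at least one event, in `[0, 1)`.
#' @examples
#' proportion_from_rate(log(2), 1)  # 0.5
#' @export
proportion_from_rate <- function(mu, T_duration) {
  if (any(!is.finite(mu)) || any(mu < 0)) {
    stop("`mu` must be a nonnegative rate", call. = FALSE)
  }
  if (any(!is.finite(T_duration)) || any(T_duration <= 0)) {
    stop("`T_duration` must be positive", call. = FALSE)
  }
  1 - exp(-mu * T_duration)
}

check_design <- function(mu0, mu1, family, Q0, alpha, power) {
  check_mu(family, mu0)
  check_mu(family, mu1)
  if (mu0 == mu1) {
    stop("degenerate effect: `mu0` and `mu1` must differ", call. = FALSE)
  }
  if (!is.finite(Q0) || Q0 <= 0 || Q0 >= 1) {
    stop("`Q0` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.finite(power) || power <= 0 || power >= 1) {
    stop("`power` must lie strictly between 0 and 1", call. = FALSE)
  }
  invisible(TRUE)
}

# ---- hand-coded family specializations -------------------------------------
# Direct transcriptions of the closed-form per-family formulas; the generic
# engine above must agree with these to numerical precision (cross-checked in
# the test suite). All return the unrounded total N.

size_nb_log_m2 <- function(mu0, mu1, k0, k1, Q0, alpha, power) {
  Q1 <- 1 - Q0
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  (z * sqrt((1 / mu1 + 1 / k1) / Q1 + (1 / mu0 + 1 / k0) / Q0) /
     (log(mu0) - log(mu1)))^2
}

size_nb_log_m1 <- function(mu0, mu1, k0, k1, Q0, alpha, power) {
  Q1 <- 1 - Q0
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  num <- za * sqrt((1 / mu0 + 1 / k0) * (1 / Q1 + 1 / Q0)) +
    zb * sqrt((1 / mu1 + 1 / k1) / Q1 + (1 / mu0 + 1 / k0) / Q0)
  (num / (log(mu0) - log(mu1)))^2
}

size_nb_identity <- function(mu0, mu1, k0, k1, Q0, alpha, power) {
  Q1 <- 1 - Q0
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  (z * sqrt((mu1 + mu1^2 / k1) / Q1 + (mu0 + mu0^2 / k0) / Q0) /
     (mu0 - mu1))^2
}

# k -> Inf limit of the overdispersed count formula
size_poisson_log <- function(mu0, mu1, Q0, alpha, power) {
  Q1 <- 1 - Q0
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  (z * sqrt(1 / (Q1 * mu1) + 1 / (Q0 * mu0)) / (log(mu0) - log(mu1)))^2
}

# equal-allocation identity-scale rate formula (factor 2 gives the total)
size_poisson_identity_equal <- function(mu0, mu1, alpha, power) {
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  (z * sqrt(2 * (mu1 + mu0)) / (mu0 - mu1))^2
}

size_binomial_logit <- function(mu0, mu1, d, Q0, alpha, power) {
  Q1 <- 1 - Q0
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  (z * sqrt(1 / (Q1 * mu1 * (1 - mu1)) + 1 / (Q0 * mu0 * (1 - mu0))) /
     (sqrt(d) * (stats::qlogis(mu0) - stats::qlogis(mu1))))^2
}

size_binomial_identity <- function(mu0, mu1, d, Q0, alpha, power) {
  Q1 <- 1 - Q0
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  (z * sqrt(mu1 * (1 - mu1) / Q1 + mu0 * (1 - mu0) / Q0) /
     (sqrt(d) * (mu0 - mu1)))^2
}

size_gamma_log <- function(mu0, mu1, kappa0, kappa1, Q0, alpha, power) {
  Q1 <- 1 - Q0
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  (z * sqrt(1 / (Q1 * kappa1) + 1 / (Q0 * kappa0)) /
     (log(mu0) - log(mu1)))^2
}
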