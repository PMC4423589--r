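#' Berry-Esseen constants
#'
#' The Berry-Esseen theorem bounds the maximum error of the normal
#' approximation to a standardized iid mean by `C * rho / (sigma^3 sqrt(n))`
#' with a distribution-independent constant `C`. Three published values are
#' exposed:
#'
#' * `"shevtsova"` — 0.4690, the general iid constant (Shevtsova, 2013);
#' * `"poisson_sum"` — 0.3051, valid for sums of Poisson variables,
#'   including the Poisson itself and the negative binomial as a Poisson
#'   mixture;
#' * `"esseen"` — 7.59, Esseen's original historical bound, exposed for
#'   context only.
#'
#' @param which Which constant to return.
#' @return A named numeric scalar.
#' @examples
#' be_constant("poisson_sum")
#' @export
be_constant <- function(which = c("shevtsova", "poisson_sum", "esseen")) {
  which <- match.arg(which)
  c(shevtsova = 0.4690, poisson_sum = 0.3051, esseen = 7.59)[which]
}

#' Suggest the Berry-Esseen constant for a family
#'
#' Poisson and negative binomial sums admit the sharper constant 0.3051;
#' everything else uses the general 0.4690. The choice is always explicit
#' in [berry_esseen_bound()]; this helper only encodes the admissibility
#' rule.
#'
#' @param family An [outcome_family] object.
#' @return A named numeric scalar (see [be_constant()]).
#' @export
suggest_be_constant <- function(family) {
  stopifnot(inherits(family, "outcome_family"))
  if (family$family_id %in% c("poisson", "negative_binomial")) {
    be_constant("poisson_sum")
  } else {
    be_constant("shevtsova")
  }
}

#' Absolute third central moment of a single observation
#'
#' Computes `rho = E|Y - mu|^3` for one observation from the family, the
#' distribution-dependent ingredient of the Berry-Esseen bound. For the
#' Bernoulli (`binomial` with `d = 1`) the closed form
#' `mu(1-mu)(mu^2 + (1-mu)^2)` is used; other binomial denominators are
#' finite sums over the proportion lattice; Poisson and negative binomial
#' are summed over the count support until a rigorous geometric-domination
#' bound on the neglected tail falls below `tol`; the gamma family is
#' handled by adaptive quadrature (flagged experimental since the
#' Berry-Esseen machinery here is aimed at the discrete families).
#'
#' The tail bound for the discrete sums: beyond a cutoff `Y` past the mean,
#' the pmf ratio `p(y+1)/p(y)` is bounded by some `r < 1` (`mu/(y+1)` for
#' Poisson, `mu/(mu+k)` for negative binomial), so the neglected mass is
#' dominated by a geometric series whose cubic-weighted sum has a closed
#' form; that closed-form remainder is what `truncation_error_bound`
#' reports.
#'
#' @inheritParams variance_function
#' @param tol Target bound on the truncation error of the tail sum.
#' @return A one-row tibble (class `moment_summary`) with columns `family`,
#'   `mu`, `mean`, `variance`, `rho` (the absolute third central moment)
#'   and `truncation_error_bound`.
#' @examples
#' third_abs_moment(binomial_family(), 0.5)   # rho = 0.125 exactly
#' third_abs_moment(poisson_family(), 0.05)
#' @export
third_abs_moment <- function(family, mu, arm = 0, tol = 1e-10) {
  stopifnot(inherits(family, "outcome_family"))
  check_mu(family, mu)
  if (!is.finite(tol) || tol <= 0) stop("`tol` must be positive", call. = FALSE)

  res <- switch(family$family_id,
    binomial = {
      d <- family$denominator_d
      if (d == 1) {
        list(rho = mu * (1 - mu) * (mu^2 + (1 - mu)^2), err = 0)
      } else {
        s <- 0:d
        list(rho = sum(abs(s / d - mu)^3 * stats::dbinom(s, d, mu)), err = 0)
      }
    },
    poisson = rho_discrete_tail(
      mu = mu, tol = tol,
      pmf = function(y) stats::dpois(y, mu),
      quant = function(p) stats::qpois(p, mu),
      ratio_bound = function(y) mu / (y + 1)
    ),
    negative_binomial = {
      k <- dispersion(family, arm)
      rho_discrete_tail(
        mu = mu, tol = tol,
        pmf = function(y) stats::dnbinom(y, size = k, mu = mu),
        quant = function(p) stats::qnbinom(p, size = k, mu = mu),
        # p(y+1)/p(y) = (y+k)/(y+1) * mu/(mu+k) <= mu/(mu+k) once y >= k-1
        ratio_bound = function(y) {
          q <- mu / (mu + k)
          if (y >= k - 1) q else (y + k) / (y + 1) * q
        }
      )
    },
    gamma = {
      kappa <- dispersion(family, arm)
      scale_par <- mu / kappa
      f <- function(y) abs(y - mu)^3 * stats::dgamma(y, shape = kappa,
                                                     scale = scale_par)
      lo <- stats::integrate(f, 0, mu, rel.tol = 1e-10)
      hi <- stats::integrate(f, mu, Inf, rel.tol = 1e-10)
      list(rho = lo$value + hi$value,
           err = lo$abs.error + hi$abs.error,
           experimental = TRUE)
    }
  )

  sigma2 <- variance_function(family, mu, arm)
  out <- tibble::new_tibble(
    tibble::tibble(
      family = family$family_id,
      mu = mu,
      mean = mu,
      variance = sigma2,
      rho = res$rho,
      truncation_error_bound = res$err
    ),
    class = "moment_summary"
  )
  if (isTRUE(res$experimental)) attr(out, "experimental") <- TRUE
  out
}

# Sum |y - mu|^3 p(y) over the count support, extending the upper cutoff
# until the geometric-domination bound on the remainder is below tol.
rho_discrete_tail <- function(mu, tol, pmf, quant, ratio_bound) {
  upper <- max(quant(1 - 1e-12), ceiling(mu) + 30)
  repeat {
    r <- ratio_bound(upper)
    if (r < 1) {
      # remainder <= p(upper+1) * sum_{j>=0} (a + j)^3 r^j, a = upper+1-mu
      a <- upper + 1 - mu
      s0 <- 1 / (1 - r)
      s1 <- r / (1 - r)^2
      s2 <- r * (1 + r) / (1 - r)^3
      s3 <- r * (1 + 4 * r + r^2) / (1 - r)^4
      rem <- pmf(upper + 1) * (a^3 * s0 + 3 * a^2 * s1 + 3 * a * s2 + s3)
      if (is.finite(rem) && rem < tol) break
    }
    upper <- upper * 2 + 50
    if (upper > 1e8) {
      stop("tail truncation failed to converge; increase `tol`",
           call. = FALSE)
    }
  }
  y <- 0:upper
  list(rho = sum(abs(y - mu)^3 * pmf(y)), err = rem)
}

#' Berry-Esseen bound on the normal-approximation error
#'
#' The uniform bound `C * rho / (sigma^3 * sqrt(n))` on the maximum
#' absolute difference between the CDF of the standardized mean of `n` iid
#' observations and the standard normal CDF. The constant `C` must be
#' chosen explicitly by the caller (see [be_constant()] and
#' [suggest_be_constant()]): 0.3051 is admissible for Poisson and negative
#' binomial sums, 0.4690 in general.
#'
#' @param moments A `moment_summary` row from [third_abs_moment()] (or any
#'   list/one-row data frame with elements `variance` and `rho`).
#' @param n Sample size (number of iid observations averaged).
#' @param C The Berry-Esseen constant, a positive number.
#' @return The bound, a nonnegative number on the probability scale.
#' @examples
#' m <- third_abs_moment(poisson_family(), 0.05)
#' berry_esseen_bound(m, n = 100, C = be_constant("poisson_sum"))  # 0.137
#' @export
berry_esseen_bound <- function(moments, n, C = be_constant("shevtsova")) {
  if (is.data.frame(moments)) moments <- as.list(moments[1, ])
  sigma2 <- moments$variance
  rho <- moments$rho
  if (is.null(sigma2) || is.null(rho)) {
    stop("`moments` must carry `variance` and `rho`", call. = FALSE)
  }
  if (!is.finite(sigma2) || sigma2 <= 0) {
    stop("degenerate distribution: variance must be positive", call. = FALSE)
  }
  if (length(n) != 1 || n < 1 || n != round(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.finite(C) || C <= 0) stop("`C` must be positive", call. = FALSE)
  unname(C * rho / (sigma2^1.5 * sqrt(n)))
}
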