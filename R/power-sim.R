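#' Fit a two-group GLM
#'
#' Maximum-likelihood fit of the saturated two-group model on the analysis
#' link scale (log for negative binomial, Poisson and gamma; logit for
#' binomial). Because the model is saturated, the fitted arm means are the
#' arm sample means for every family; the dispersion (a single `k` for the
#' negative binomial, a single shape `kappa` for the gamma, common to both
#' arms) is estimated by solving the profile-likelihood score equation at
#' the fitted means. The standard error of the group effect comes from the
#' inverse information: `SE^2 = 1/(N0 w0) + 1/(N1 w1)` with the GLM weights
#' evaluated at the fitted means and dispersion.
#'
#' An arm whose sample mean falls on the boundary of the link's domain
#' (all-zero counts under the log link; all-0 or all-1 Bernoulli outcomes
#' under the logit) yields `converged = FALSE` rather than an error, so
#' simulation loops can tally nonconvergence separately.
#'
#' @param y0,y1 Outcome vectors for the reference and intervention arms
#'   (counts for NB/Poisson, proportions out of `d` for binomial, positive
#'   reals for gamma). Each arm needs at least 2 observations.
#' @param family An [outcome_family] object.
#' @param link Analysis link: `"log"` (NB, Poisson, gamma) or `"logit"`
#'   (binomial).
#' @return An object of class `two_group_fit`: a list with `mu_hat`
#'   (fitted means, arm 0 then arm 1), `coef` (link-scale intercept and
#'   group effect), `dispersion_hat`, `se_effect`, `loglik`, `converged`,
#'   `n0`, `n1`, `family_id` and `link_id`.
#' @examples
#' y0 <- sample_outcomes(nb_family(0.33), 71.4, 200, seed = 1)
#' y1 <- sample_outcomes(nb_family(0.33), 50, 200, arm = 1, seed = 2)
#' fit <- fit_two_group(y0, y1, nb_family(0.33))
#' tidy(fit)
#' @export
fit_two_group <- function(y0, y1, family, link = NULL) {
  stopifnot(inherits(family, "outcome_family"))
  if (length(y0) < 2 || length(y1) < 2) {
    stop("each arm needs at least 2 observations", call. = FALSE)
  }
  link_id <- link %||% if (family$family_id == "binomial") "logit" else "log"
  if (inherits(link_id, "glm_link")) link_id <- link_id$link_id
  canonical <- if (family$family_id == "binomial") "logit" else "log"
  if (link_id != canonical) {
    stop(sprintf("analysis link '%s' not supported for the %s family; use '%s'",
                 link_id, family$family_id, canonical), call. = FALSE)
  }
  lk <- link_spec(link_id)
  if (any(!is.finite(c(y0, y1)))) stop("outcomes must be finite", call. = FALSE)
  if (family$family_id != "gamma" && any(c(y0, y1) < 0)) {
    stop("outcomes must be nonnegative", call. = FALSE)
  }
  if (family$family_id == "gamma" && any(c(y0, y1) <= 0)) {
    stop("gamma outcomes must be strictly positive", call. = FALSE)
  }

  n0 <- length(y0); n1 <- length(y1)
  m0 <- mean(y0);  m1 <- mean(y1)
  mu_vec <- c(rep(m0, n0), rep(m1, n1))
  y <- c(y0, y1)
  d <- family$denominator_d

  boundary <- switch(family$family_id,
    binomial = m0 <= 0 || m0 >= 1 || m1 <= 0 || m1 >= 1,
    m0 <= 0 || m1 <= 0
  )
  if (boundary) {
    return(structure(
      list(mu_hat = c(m0, m1), coef = c(NA_real_, NA_real_),
           dispersion_hat = NA_real_, se_effect = NA_real_,
           loglik = NA_real_, converged = FALSE,
           n0 = n0, n1 = n1, family_id = family$family_id,
           link_id = link_id),
      class = "two_group_fit"))
  }

  disp <- switch(family$family_id,
    negative_binomial = nb_shape_mle(y, mu_vec),
    gamma = gamma_shape_mle(y, mu_vec),
    NA_real_
  )
  w <- function(m) {
    switch(family$family_id,
      negative_binomial = if (is.infinite(disp)) m else 1 / (1 / m + 1 / disp),
      poisson = m,
      binomial = d * m * (1 - m),
      gamma = disp
    )
  }
  se <- sqrt(1 / (n0 * w(m0)) + 1 / (n1 * w(m1)))
  ll <- family_loglik(y, mu_vec, family, disp)

  structure(
    list(mu_hat = c(m0, m1),
         coef = c(intercept = lk$g(m0), effect = lk$g(m1) - lk$g(m0)),
         dispersion_hat = disp, se_effect = se, loglik = ll,
         converged = TRUE, n0 = n0, n1 = n1,
         family_id = family$family_id, link_id = link_id),
    class = "two_group_fit"
  )
}

#' @export
print.two_group_fit <- function(x, ...) {
  cat("<two_group_fit> ", x$family_id, " / ", x$link_id, " link\n", sep = "")
  if (!x$converged) {
    cat("  did not converge (boundary arm mean)\n")
    return(invisible(x))
  }
  cat(sprintf("  arm means: %.4g, %.4g   group effect (%s scale): %.4g (SE %.4g)\n",
              x$mu_hat[1], x$mu_hat[2], x$link_id, x$coef[["effect"]],
              x$se_effect))
  if (!is.na(x$dispersion_hat)) {
    cat(sprintf("  dispersion: %.4g\n", x$dispersion_hat))
  }
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

# profile-ML common NB shape: root of the score in log(k), Brent bracketing;
# data less dispersed than Poisson => score positive everywhere => k = Inf
nb_shape_mle <- function(y, mu) {
  score <- function(logk) {
    k <- exp(logk)
    sum(digamma(y + k) - digamma(k) + log(k) + 1 - log(k + mu) -
          (y + k) / (k + mu))
  }
  vbar <- mean((y - mu)^2)
  excess <- vbar - mean(mu)
  k0 <- if (excess > 0) mean(mu^2) / excess else 100
  k0 <- min(max(k0, 1e-4), 1e4)
  lo <- log(k0); hi <- log(k0)
  while (score(lo) <= 0 && lo > log(1e-8)) lo <- lo - 2
  while (score(hi) >= 0 && hi < log(1e7)) hi <- hi + 2
  if (score(hi) >= 0) return(Inf)       # underdispersed: Poisson limit
  if (score(lo) <= 0) return(exp(lo))   # pathological; extreme overdispersion
  exp(stats::uniroot(score, c(lo, hi), tol = 1e-10)$root)
}

# common gamma shape by ML at fixed means
gamma_shape_mle <- function(y, mu) {
  score <- function(logk) {
    k <- exp(logk)
    sum(log(k) + 1 - log(mu) + log(y) - y / mu) - length(y) * digamma(k)
  }
  lo <- log(1e-4); hi <- log(1e6)
  if (score(hi) >= 0) return(exp(hi))
  if (score(lo) <= 0) return(exp(lo))
  exp(stats::uniroot(score, c(lo, hi), tol = 1e-10)$root)
}

family_loglik <- function(y, mu, family, disp) {
  switch(family$family_id,
    negative_binomial = if (is.infinite(disp)) {
      sum(stats::dpois(y, lambda = mu, log = TRUE))
    } else {
      sum(stats::dnbinom(y, size = disp, mu = mu, log = TRUE))
    },
    poisson = sum(stats::dpois(y, lambda = mu, log = TRUE)),
    binomial = {
      d <- family$denominator_d
      sum(stats::dbinom(round(y * d), size = d, prob = mu, log = TRUE))
    },
    gamma = sum(stats::dgamma(y, shape = disp, scale = mu / disp, log = TRUE))
  )
}

#' Wald test of the group effect
#'
#' Two-sided test of the link-scale group effect from a [fit_two_group()]
#' fit, referring `effect / SE` to the standard normal.
#'
#' @param fit A `two_group_fit` object.
#' @return A one-row tibble with `estimate`, `std.error`, `statistic` and
#'   `p.value`; all `NA` (with a message-free pass-through) if the fit did
#'   not converge.
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "two_group_fit"))
  if (!fit$converged) {
    return(tibble::tibble(estimate = NA_real_, std.error = NA_real_,
                          statistic = NA_real_, p.value = NA_real_))
  }
  z <- fit$coef[["effect"]] / fit$se_effect
  tibble::tibble(
    estimate = fit$coef[["effect"]],
    std.error = fit$se_effect,
    statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(z))
  )
}

#' Likelihood-ratio test of equal means
#'
#' Compares the saturated two-mean model with the common-mean null model,
#' re-estimating the dispersion under the null, and refers twice the
#' log-likelihood difference to chi-square with 1 degree of freedom.
#'
#' @inheritParams fit_two_group
#' @return A one-row tibble with `statistic`, `df`, `p.value`,
#'   `loglik_full`, `loglik_null` and `converged`.
#' @export
lr_test <- function(y0, y1, family, link = NULL) {
  full <- fit_two_group(y0, y1, family, link)
  y <- c(y0, y1)
  mbar <- mean(y)
  null_boundary <- switch(family$family_id,
    binomial = mbar <= 0 || mbar >= 1,
    mbar <= 0
  )
  if (!full$converged || null_boundary) {
    return(tibble::tibble(statistic = NA_real_, df = 1L, p.value = NA_real_,
                          loglik_full = NA_real_, loglik_null = NA_real_,
                          converged = FALSE))
  }
  mu_null <- rep(mbar, length(y))
  disp_null <- switch(family$family_id,
    negative_binomial = nb_shape_mle(y, mu_null),
    gamma = gamma_shape_mle(y, mu_null),
    NA_real_
  )
  ll_null <- family_loglik(y, mu_null, family, disp_null)
  stat <- max(0, 2 * (full$loglik - ll_null))
  tibble::tibble(
    statistic = stat, df = 1L,
    p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    loglik_full = full$loglik, loglik_null = ll_null, converged = TRUE
  )
}

#' Define a Monte-Carlo power simulation
#'
#' Bundles the design, family, per-arm sizes and replication settings for
#' [estimate_power()]. With `null_mode = TRUE` both arms are generated at
#' `mu0`, so the rejection proportion estimates the type-I error instead of
#' power.
#'
#' @inheritParams glm_sample_size
#' @param N0,N1 Per-arm sample sizes (at least 2 each).
#' @param n_reps Number of replicate datasets.
#' @param seed Root seed; replicate `r` derives its own substream
#'   deterministically from `seed` and `r`, independent of execution order.
#' @param test Character vector: any of `"wald"`, `"lrt"`. Both tests are
#'   applied to the same replicate datasets when both are requested.
#' @param null_mode Simulate under the null (`mu1` ignored)?
#' @return A `simulation_plan` object.
#' @examples
#' plan <- simulation_plan(71.4, 50, nb_family(0.33), N0 = 505, N1 = 505,
#'                         n_reps = 200, seed = 1)
#' @export
simulation_plan <- function(mu0, mu1, family, link = NULL, N0, N1,
                            n_reps = 2000, alpha = 0.05, seed = 1,
                            test = "wald", null_mode = FALSE) {
  stopifnot(inherits(family, "outcome_family"))
  test <- match.arg(test, c("wald", "lrt"), several.ok = TRUE)
  if (N0 < 2 || N1 < 2) stop("per-arm sizes must be at least 2", call. = FALSE)
  if (n_reps < 1) stop("`n_reps` must be at least 1", call. = FALSE)
  structure(
    list(mu0 = mu0, mu1 = mu1, family = family, link = link,
         N0 = as.integer(N0), N1 = as.integer(N1),
         n_reps = as.integer(n_reps), alpha = alpha,
         seed = as.integer(seed), test = test,
         null_mode = isTRUE(null_mode)),
    class = "simulation_plan"
  )
}

#' Estimate achieved power (or type-I error) by simulation
#'
#' Generates `n_reps` replicate two-arm datasets from the plan's family,
#' fits the two-group GLM, applies the requested test(s) at the plan's
#' two-sided `alpha`, and reports the rejection proportion with a Wilson
#' 95\% confidence interval (the Monte-Carlo error). Replicates whose fit
#' does not converge are counted in `n_nonconverged` and excluded from the
#' denominator. Replicate `r` seeds its own RNG substream as a fixed
#' function of the root seed and `r`, so results are reproducible and
#' order-independent.
#'
#' @param plan A [simulation_plan()].
#' @return A tibble of class `power_estimate`, one row per requested test,
#'   with columns `test`, `power` (rejection proportion), `conf.low`,
#'   `conf.high`, `rejections`, `n_converged`, `n_nonconverged`, `n_reps`,
#'   `alpha`, `seed`, `null_mode` and the design echo (`family`, `mu0`,
#'   `mu1`, `N0`, `N1`).
#' @examples
#' plan <- simulation_plan(71.4, 50, nb_family(0.33), N0 = 50, N1 = 50,
#'                         n_reps = 100, seed = 1)
#' estimate_power(plan)
#' @export
estimate_power <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  fam <- plan$family
  mu1_eff <- if (plan$null_mode) plan$mu0 else plan$mu1
  want_wald <- "wald" %in% plan$test
  want_lrt <- "lrt" %in% plan$test
  p_wald <- p_lrt <- rep(NA_real_, plan$n_reps)

  for (r in seq_len(plan$n_reps)) {
    set.seed(replicate_seed(plan$seed, r))
    y0 <- sample_outcomes(fam, plan$mu0, plan$N0, arm = 0)
    y1 <- sample_outcomes(fam, mu1_eff, plan$N1, arm = 1)
    if (want_wald) {
      fit <- fit_two_group(y0, y1, fam, plan$link)
      if (fit$converged) p_wald[r] <- wald_test(fit)$p.value
    }
    if (want_lrt) {
      lr <- lr_test(y0, y1, fam, plan$link)
      if (isTRUE(lr$converged)) p_lrt[r] <- lr$p.value
    }
  }

  one <- function(test, p) {
    ok <- !is.na(p)
    rej <- sum(p[ok] < plan$alpha)
    ci <- wilson_ci(rej, sum(ok))
    tibble::tibble(
      test = test, power = if (sum(ok)) rej / sum(ok) else NA_real_,
      conf.low = ci[1], conf.high = ci[2],
      rejections = rej, n_converged = sum(ok),
      n_nonconverged = sum(!ok), n_reps = plan$n_reps,
      alpha = plan$alpha, seed = plan$seed, null_mode = plan$null_mode,
      family = fam$family_id, mu0 = plan$mu0, mu1 = mu1_eff,
      N0 = plan$N0, N1 = plan$N1
    )
  }
  out <- dplyr::bind_rows(
    if (want_wald) one("wald", p_wald),
    if (want_lrt) one("lrt", p_lrt)
  )
  tibble::new_tibble(out, class = "power_estimate")
}

# deterministic per-replicate substream seed (counter-based, < 2^31)
replicate_seed <- function(seed, r) {
  as.integer((abs(seed) * 69069 + r * 2654435761) %% 2147483647)
}

# Wilson 95% score interval for a binomial proportion
wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Run a grid of power simulations
#'
#' Maps [estimate_power()] over the rows of a design tibble, binding the
#' results. Columns must match the arguments of [simulation_plan()] except
#' `family`, which is given as a list-column of [outcome_family] objects or
#' a single object recycled for all rows.
#'
#' @param designs A data frame with columns `mu0`, `mu1`, `N0`, `N1` and
#'   optionally `n_reps`, `alpha`, `seed`, `test`, `null_mode`.
#' @param family An [outcome_family] or a list of them (one per row).
#' @return A `power_estimate` tibble with one row per design/test.
#' @export
estimate_power_grid <- function(designs, family) {
  stopifnot(is.data.frame(designs))
  fams <- if (inherits(family, "outcome_family")) {
    rep(list(family), nrow(designs))
  } else {
    family
  }
  defaults <- list(n_reps = 2000, alpha = 0.05, seed = 1, test = "wald",
                   null_mode = FALSE)
  rows <- purrr::map(seq_len(nrow(designs)), function(i) {
    row <- as.list(designs[i, , drop = FALSE])
    args <- utils::modifyList(defaults, row[!vapply(row, anyNA, TRUE) |
                                              names(row) %in% c("mu0", "mu1")])
    plan <- simulation_plan(
      mu0 = args$mu0, mu1 = args$mu1, family = fams[[i]],
      N0 = args$N0, N1 = args$N1, n_reps = args$n_reps,
      alpha = args$alpha, seed = args$seed,
      test = unlist(args$test), null_mode = args$null_mode
    )
    estimate_power(plan)
  })
  tibble::new_tibble(dplyr::bind_rows(rows), class = "power_estimate")
}
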