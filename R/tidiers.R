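#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a two-group GLM fit
#'
#' @param x A [fit_two_group()] result.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`); the intercept row has no test.
#' @method tidy two_group_fit
#' @export
tidy.two_group_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble::tibble(term = c("intercept", "effect"),
                          estimate = NA_real_, std.error = NA_real_,
                          statistic = NA_real_, p.value = NA_real_))
  }
  w <- wald_test(x)
  tibble::tibble(
    term = c("intercept", "effect"),
    estimate = unname(x$coef),
    std.error = c(NA_real_, x$se_effect),
    statistic = c(NA_real_, w$statistic),
    p.value = c(NA_real_, w$p.value)
  )
}

#' Glance at a two-group GLM fit
#'
#' @inheritParams tidy.two_group_fit
#' @return A one-row tibble: `family`, `link`, fitted means, dispersion,
#'   `logLik`, `nobs`, `converged`.
#' @method glance two_group_fit
#' @export
glance.two_group_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family_id, link = x$link_id,
    mu0_hat = x$mu_hat[1], mu1_hat = x$mu_hat[2],
    dispersion = x$dispersion_hat,
    logLik = x$loglik, nobs = x$n0 + x$n1, converged = x$converged
  )
}

#' Plot power estimates with Monte-Carlo error bars
#'
#' Plots the rejection proportion of each scenario in a `power_estimate`
#' tibble (as produced by [estimate_power()] or [estimate_power_grid()])
#' with its Wilson 95\% interval, optionally against a chosen design
#' variable, with a dashed reference line at the nominal level.
#'
#' @param object A `power_estimate` tibble.
#' @param x Name of the column to place on the horizontal axis (default
#'   the scenario index).
#' @param nominal Reference level to draw (e.g. target power 0.9, or
#'   `alpha` for null simulations); `NULL` suppresses the line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_estimate
#' @export
autoplot.power_estimate <- function(object, x = NULL, nominal = 0.9, ...) {
  df <- tibble::as_tibble(object)
  if (is.null(x)) {
    df$.x <- seq_len(nrow(df))
    xlab <- "scenario"
  } else {
    df$.x <- df[[x]]
    xlab <- x
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$.x, y = .data$power,
                                        colour = .data$test)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high),
                             position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::labs(x = xlab, y = "rejection proportion", colour = "test") +
    ggplot2::theme_minimal()
  if (!is.null(nominal)) {
    p <- p + ggplot2::geom_hline(yintercept = nominal, linetype = "dashed")
  }
  p
}

#' Plot a normal-approximation error grid
#'
#' Companion plot for [normal_error_grid()]: exact maximum CDF discrepancy
#' (points, solid line) and Berry-Esseen bound (open points, dotted line)
#' against the mean, one panel per family.
#'
#' @param grid Output of [normal_error_grid()].
#' @return A ggplot object.
#' @export
plot_normal_error <- function(grid) {
  stopifnot(is.data.frame(grid))
  long <- tidyr_pivot(grid)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mu, y = .data$error,
                                     linetype = .data$measure,
                                     shape = .data$measure)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~family) +
    ggplot2::labs(x = "mean", y = "maximum CDF error",
                  linetype = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (avoids importing tidyr for one call)
tidyr_pivot <- function(grid) {
  base <- grid[c("family", "mu")]
  dplyr::bind_rows(
    dplyr::mutate(base, measure = "Berry-Esseen bound",
                  error = grid$be_bound),
    dplyr::mutate(base, measure = "exact CDF",
                  error = grid$exact_max_discrepancy)
  )
}

#' @importFrom rlang .data
NULL
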