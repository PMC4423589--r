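# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force sums, closed forms, and MASS fits.

# classical two-sample difference-of-means total size with per-arm variances
classical_normal_N <- function(mu0, mu1, v0, v1, Q0, alpha, power) {
  z <- qnorm(1 - alpha / 2) + qnorm(power)
  z^2 * (v1 / (1 - Q0) + v0 / Q0) / (mu0 - mu1)^2
}

# absolute third central moment of an NB(mu, k) by pmf recurrence
# P(y+1) = P(y) * (y + k)/(y + 1) * mu/(mu + k)
rho_nb_recurrence <- function(mu, k, upper = 5000) {
  p <- (k / (mu + k))^k
  total <- abs(0 - mu)^3 * p
  for (y in 0:(upper - 1)) {
    p <- p * (y + k) / (y + 1) * mu / (mu + k)
    total <- total + abs(y + 1 - mu)^3 * p
  }
  total
}

# brute-force scan of |F - Phi| for a binomial sum using manual pmf cumsum
brute_binom_discrepancy <- function(n, d, mu) {
  size <- n * d
  s <- 0:size
  pmf <- choose(size, s) * mu^s * (1 - mu)^(size - s)
  Fs <- cumsum(pmf)
  z <- (s / d - n * mu) / sqrt(n * mu * (1 - mu) / d)
  max(abs(Fs - pnorm(z)))
}

# chi-square goodness-of-fit of integer draws against a pmf, collapsing the
# upper tail so all expected counts are >= 5
gof_pvalue <- function(draws, pmf_fun, max_cells = 60) {
  n <- length(draws)
  upper <- max(draws)
  probs <- pmf_fun(0:upper)
  probs <- c(probs, max(0, 1 - sum(probs)))
  expected <- probs * n
  # collapse trailing cells with small expectation into one bin
  keep <- which(cumsum(rev(expected) >= 5) == 0)
  cut_at <- length(expected) - length(keep)
  cut_at <- max(2, min(cut_at, max_cells))
  obs <- tabulate(pmin(draws, cut_at - 1) + 1, nbins = cut_at)
  p <- c(probs[1:(cut_at - 1)], 1 - sum(probs[1:(cut_at - 1)]))
  suppressWarnings(chisq.test(obs, p = p)$p.value)
}
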