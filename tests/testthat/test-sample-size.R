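test_that("the hookworm egg-count example reproduces 505 and 531 per arm", {
  for (mode in c("nearest", "ceiling")) {
    res <- glm_sample_size(71.4, 50, nb_family(0.33), link = "log",
                           rounding = mode)
    expect_equal(res$N0, 505)
    expect_equal(res$N1, 505)
  }
  expect_equal(
    normal_approx_sample_size(71.4, 50, nb_family(0.33),
                              rounding = "nearest")$N1,
    531)
  # method 1 lands within one subject of method 2 here because 1/k
  # dominates 1/mu (half-total 504.18: ceiling 505, nearest 504)
  m1 <- glm_sample_size(71.4, 50, nb_family(0.33), "log", method = "method1",
                        rounding = "ceiling")
  expect_equal(m1$N1, 505)
  expect_lt(abs(m1$N_real / 2 - 504.2), 0.1)
})

test_that("identity-link method 2 is the classical difference-of-means formula", {
  grid <- expand.grid(mu0 = c(5, 71.4), eff = c(0.3, 0.5), Q0 = c(0.5, 0.3),
                      alpha = c(0.05, 0.01), power = c(0.8, 0.9))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    mu1 <- g$mu0 * (1 - g$eff)
    fam <- nb_family(0.33)
    res <- glm_sample_size(g$mu0, mu1, fam, "identity", Q0 = g$Q0,
                           alpha = g$alpha, power = g$power)
    oracle <- classical_normal_N(g$mu0, mu1,
                                 variance_function(fam, g$mu0, 0),
                                 variance_function(fam, mu1, 1),
                                 g$Q0, g$alpha, g$power)
    expect_equal(res$N_real, oracle, tolerance = 1e-9)
  }
})

test_that("the generic engine agrees with every hand-coded family formula", {
  za_grid <- expand.grid(mu0 = c(0.5, 5, 71.4), eff = c(0.2, 0.3, 0.6),
                         k = c(0.1, 0.33, 2, 50), Q0 = c(0.3, 0.5),
                         power = c(0.8, 0.9))
  for (i in seq_len(nrow(za_grid))) {
    g <- za_grid[i, ]
    mu1 <- g$mu0 * (1 - g$eff)
    # negative binomial, log link: methods 1 and 2 and the identity variant
    fam <- nb_family(g$k)
    expect_equal(
      glm_sample_size(g$mu0, mu1, fam, "log", Q0 = g$Q0,
                      power = g$power)$N_real,
      skewpower:::size_nb_log_m2(g$mu0, mu1, g$k, g$k, g$Q0, 0.05, g$power),
      tolerance = 1e-9)
    expect_equal(
      glm_sample_size(g$mu0, mu1, fam, "log", Q0 = g$Q0, power = g$power,
                      method = "method1")$N_real,
      skewpower:::size_nb_log_m1(g$mu0, mu1, g$k, g$k, g$Q0, 0.05, g$power),
      tolerance = 1e-9)
    expect_equal(
      glm_sample_size(g$mu0, mu1, fam, "identity", Q0 = g$Q0,
                      power = g$power)$N_real,
      skewpower:::size_nb_identity(g$mu0, mu1, g$k, g$k, g$Q0, 0.05,
                                   g$power),
      tolerance = 1e-9)
    # Poisson
    expect_equal(
      glm_sample_size(g$mu0, mu1, poisson_family(), "log", Q0 = g$Q0,
                      power = g$power)$N_real,
      skewpower:::size_poisson_log(g$mu0, mu1, g$Q0, 0.05, g$power),
      tolerance = 1e-9)
    # gamma (reuse k as the shape)
    expect_equal(
      glm_sample_size(g$mu0, mu1, gamma_family(g$k), "log", Q0 = g$Q0,
                      power = g$power)$N_real,
      skewpower:::size_gamma_log(g$mu0, mu1, g$k, g$k, g$Q0, 0.05, g$power),
      tolerance = 1e-9)
  }
  # binomial on the probability scale
  bin_grid <- expand.grid(mu0 = c(0.5, 0.3), mu1 = c(0.1, 0.2),
                          d = c(1, 5, 10), Q0 = c(0.3, 0.5))
  for (i in seq_len(nrow(bin_grid))) {
    g <- bin_grid[i, ]
    expect_equal(
      glm_sample_size(g$mu0, g$mu1, binomial_family(g$d), "logit",
                      Q0 = g$Q0)$N_real,
      skewpower:::size_binomial_logit(g$mu0, g$mu1, g$d, g$Q0, 0.05, 0.9),
      tolerance = 1e-9)
    expect_equal(
      glm_sample_size(g$mu0, g$mu1, binomial_family(g$d), "identity",
                      Q0 = g$Q0)$N_real,
      skewpower:::size_binomial_identity(g$mu0, g$mu1, g$d, g$Q0, 0.05, 0.9),
      tolerance = 1e-9)
  }
  # equal-allocation identity-scale rate formula
  expect_equal(
    glm_sample_size(5, 2, poisson_family(), "identity")$N_real,
    skewpower:::size_poisson_identity_equal(5, 2, 0.05, 0.9),
    tolerance = 1e-9)
})

test_that("overdispersed sizes shrink with k and converge to the Poisson", {
  ks <- c(0.1, 0.33, 1, 10, 100, 1e4, 1e9)
  sizes <- vapply(ks, function(k) {
    glm_sample_size(71.4, 50, nb_family(k), "log")$N_real
  }, numeric(1))
  expect_true(all(diff(sizes) < 0))
  pois <- glm_sample_size(71.4, 50, poisson_family(), "log")$N_real
  expect_lt(abs(sizes[length(sizes)] - pois), 1)
})

test_that("size grows with target power and shrinks with effect size", {
  powers <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  n_pow <- vapply(powers, function(p) {
    glm_sample_size(71.4, 50, nb_family(0.33), "log", power = p)$N_real
  }, numeric(1))
  expect_true(all(diff(n_pow) > 0))
  effs <- c(0.2, 0.3, 0.5, 0.7)
  n_eff <- vapply(effs, function(e) {
    glm_sample_size(71.4, 71.4 * (1 - e), nb_family(0.33), "log")$N_real
  }, numeric(1))
  expect_true(all(diff(n_eff) < 0))
})

test_that("method 2 is symmetric under arm relabeling, method 1 is not", {
  fam <- nb_family(0.2, k1 = 1)
  fam_swap <- nb_family(1, k1 = 0.2)
  a <- glm_sample_size(71.4, 50, fam, "log", Q0 = 0.3)$N_real
  b <- glm_sample_size(50, 71.4, fam_swap, "log", Q0 = 0.7)$N_real
  expect_equal(a, b, tolerance = 1e-12)
  a1 <- glm_sample_size(71.4, 50, fam, "log", Q0 = 0.3,
                        method = "method1")$N_real
  b1 <- glm_sample_size(50, 71.4, fam_swap, "log", Q0 = 0.7,
                        method = "method1")$N_real
  expect_gt(abs(a1 - b1), 1)
})

test_that("per-arm rounding follows the requested convention", {
  expect_identical(allocate_and_round(1009.1, 0.5, mode = "nearest"),
                   c(505L, 505L))
  expect_identical(allocate_and_round(1062.2, 0.5, mode = "nearest"),
                   c(531L, 531L))
  expect_identical(allocate_and_round(100, 0.5, mode = "ceiling"),
                   c(50L, 50L))
  expect_identical(allocate_and_round(101, 0.5, mode = "ceiling"),
                   c(51L, 51L))
  # halves round up, never to even
  expect_identical(allocate_and_round(1009, 0.5, mode = "nearest"),
                   c(505L, 505L))
  # ceiling covers each allocation fraction
  n <- allocate_and_round(333.4, 0.4, mode = "ceiling")
  expect_gte(n[1], 0.4 * 333.4)
  expect_gte(n[2], 0.6 * 333.4)
})

test_that("rates convert to window probabilities", {
  expect_equal(proportion_from_rate(0, 5), 0)
  expect_equal(proportion_from_rate(log(2), 1), 0.5)
  expect_equal(proportion_from_rate(0.1, 1), 1 - exp(-0.1))
  expect_lt(abs(proportion_from_rate(0.1, 1) - 0.09516), 5e-6)
  expect_error(proportion_from_rate(-1, 1), "nonnegative")
  expect_error(proportion_from_rate(1, 0), "positive")
})

test_that("degenerate designs fail with a clear message", {
  expect_error(glm_sample_size(50, 50, nb_family(0.33)), "degenerate")
  expect_error(glm_sample_size(71.4, 50, nb_family(0.33), Q0 = 1), "Q0")
  expect_error(glm_sample_size(71.4, 50, nb_family(0.33), alpha = 0), "alpha")
  expect_error(glm_sample_size(0.5, 1.2, binomial_family()), "mu")
})
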