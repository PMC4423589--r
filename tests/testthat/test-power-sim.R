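test_that("saturated log-link fits recover the arm sample means", {
  y0 <- c(3, 0, 7, 2, 1)
  y1 <- c(10, 4, 6, 8, 12)
  for (fam in list(nb_family(1), poisson_family())) {
    fit <- fit_two_group(y0, y1, fam)
    expect_equal(fit$mu_hat, c(mean(y0), mean(y1)))
    expect_equal(unname(exp(fit$coef[["intercept"]])), mean(y0),
                 tolerance = 1e-8)
    expect_equal(unname(fit$coef[["effect"]]), log(mean(y1) / mean(y0)),
                 tolerance = 1e-12)
    expect_gt(fit$se_effect, 0)
  }
  g0 <- c(0.4, 2.1, 5.2, 1.1)
  g1 <- c(8.2, 3.3, 12.5, 6.1)
  gfit <- fit_two_group(g0, g1, gamma_family(0.639))
  expect_equal(unname(gfit$coef[["effect"]]), log(mean(g1) / mean(g0)),
               tolerance = 1e-12)
})

test_that("the NB fit agrees with the MASS maximum-likelihood oracle", {
  skip_if_not_installed("MASS")
  set.seed(99)
  y0 <- rnbinom(10, size = 0.5, mu = 20)
  y1 <- rnbinom(10, size = 0.5, mu = 8)
  fit <- fit_two_group(y0, y1, nb_family(0.5))
  oracle <- MASS::glm.nb(y ~ grp,
                         data = data.frame(y = c(y0, y1),
                                           grp = rep(0:1, c(10, 10))))
  sm <- summary(oracle)$coefficients
  expect_equal(fit$dispersion_hat, oracle$theta, tolerance = 1e-6)
  expect_equal(unname(fit$coef[["effect"]]), sm[2, 1], tolerance = 1e-8)
  expect_equal(fit$se_effect, sm[2, 2], tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(oracle)), tolerance = 1e-6)
  expect_equal(wald_test(fit)$p.value, sm[2, 4], tolerance = 1e-6)
})

test_that("NB dispersion is recovered from large simulated samples", {
  y0 <- sample_outcomes(nb_family(0.33), 71.4, 1e4, seed = 5)
  y1 <- sample_outcomes(nb_family(0.33), 50, 1e4, arm = 1, seed = 6)
  fit <- fit_two_group(y0, y1, nb_family(0.33))
  expect_lt(abs(fit$dispersion_hat - 0.33) / 0.33, 0.1)
})

test_that("gamma and binomial fits match their glm oracles", {
  skip_if_not_installed("MASS")
  set.seed(42)
  g0 <- rgamma(30, shape = 0.639, scale = 8.46 / 0.639)
  g1 <- rgamma(30, shape = 0.639, scale = 4 / 0.639)
  fit <- fit_two_group(g0, g1, gamma_family(0.639))
  glm_fit <- glm(y ~ grp, family = Gamma(link = "log"),
                 data = data.frame(y = c(g0, g1), grp = rep(0:1, c(30, 30))))
  kap <- MASS::gamma.shape(glm_fit)$alpha
  expect_equal(fit$dispersion_hat, kap, tolerance = 1e-5)
  expect_equal(fit$se_effect,
               summary(glm_fit, dispersion = 1 / kap)$coefficients[2, 2],
               tolerance = 1e-6)

  s0 <- rbinom(40, 1, 0.5)
  s1 <- rbinom(40, 1, 0.2)
  bfit <- fit_two_group(s0, s1, binomial_family(1))
  bglm <- glm(y ~ grp, family = binomial,
              data = data.frame(y = c(s0, s1), grp = rep(0:1, c(40, 40))))
  expect_equal(unname(bfit$coef[["effect"]]),
               unname(coef(bglm)[2]), tolerance = 1e-8)
  expect_equal(bfit$se_effect, summary(bglm)$coefficients[2, 2],
               tolerance = 1e-6)
})

test_that("identical arms give a null Wald statistic and unit p-value", {
  y <- c(2, 5, 1, 0, 8, 3)
  fit <- fit_two_group(y, y, nb_family(1))
  expect_equal(unname(fit$coef[["effect"]]), 0)
  expect_equal(wald_test(fit)$statistic, 0)
  expect_equal(wald_test(fit)$p.value, 1)
  lr <- lr_test(y, y, nb_family(1))
  expect_lt(lr$statistic, 1e-8)
  expect_gt(lr$p.value, 0.999)
})

test_that("the Poisson deviance matches its closed form and is never negative", {
  set.seed(3)
  y0 <- rpois(25, 4); y1 <- rpois(25, 7)
  lr <- lr_test(y0, y1, poisson_family())
  ybar <- c(mean(y0), mean(y1)); pool <- mean(c(y0, y1))
  oracle <- 2 * (sum(y0) * log(ybar[1] / pool) + sum(y1) * log(ybar[2] / pool))
  expect_equal(lr$statistic, oracle, tolerance = 1e-9)
  for (s in 1:20) {
    set.seed(s)
    a <- rpois(10, 2); b <- rpois(10, 2)
    if (mean(a) > 0 && mean(b) > 0) {
      expect_gte(lr_test(a, b, poisson_family())$statistic, 0)
    }
  }
})

test_that("boundary arms flag nonconvergence instead of erroring", {
  fit <- fit_two_group(c(0, 0, 0), c(1, 2, 1), poisson_family())
  expect_false(fit$converged)
  expect_true(is.na(wald_test(fit)$p.value))
  bfit <- fit_two_group(c(1, 1, 1), c(0, 1, 0), binomial_family(1))
  expect_false(bfit$converged)
  # degenerate plan: tiny Poisson mean with 2 per arm mostly yields zero arms
  plan <- simulation_plan(0.01, 0.005, poisson_family(), N0 = 2, N1 = 2,
                          n_reps = 50, seed = 1)
  res <- estimate_power(plan)
  expect_gt(res$n_nonconverged, 0)
  expect_equal(res$n_converged + res$n_nonconverged, 50)
})

test_that("power estimation is deterministic under a fixed seed", {
  plan <- simulation_plan(71.4, 50, nb_family(0.33), N0 = 60, N1 = 60,
                          n_reps = 40, seed = 123, test = c("wald", "lrt"))
  a <- estimate_power(plan)
  b <- estimate_power(plan)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 2)
  expect_true(all(a$conf.low <= a$power & a$power <= a$conf.high))
  c2 <- estimate_power(simulation_plan(71.4, 50, nb_family(0.33), N0 = 60,
                                       N1 = 60, n_reps = 40, seed = 124))
  expect_false(identical(a$power[1], c2$power[1]))
})

test_that("tidiers expose coefficients and fit summaries", {
  y0 <- sample_outcomes(nb_family(0.33), 71.4, 100, seed = 2)
  y1 <- sample_outcomes(nb_family(0.33), 50, 100, arm = 1, seed = 3)
  fit <- fit_two_group(y0, y1, nb_family(0.33))
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "effect"))
  expect_equal(td$estimate[2], unname(fit$coef[["effect"]]))
  expect_equal(td$p.value[2], wald_test(fit)$p.value)
  gl <- glance(fit)
  expect_equal(gl$nobs, 200)
  expect_true(gl$converged)
})

test_that("power grids map over designs and autoplot returns a ggplot", {
  designs <- tibble::tibble(mu0 = 71.4, mu1 = c(50, 35.7),
                            N0 = 40L, N1 = 40L, n_reps = 20L, seed = 9L)
  out <- estimate_power_grid(designs, nb_family(0.33))
  expect_equal(nrow(out), 2)
  expect_s3_class(autoplot(out, x = "mu1"), "ggplot")
})
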