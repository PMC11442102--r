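# Uncertainty quantification: linear-model oracle equivalence, band
# ordering, Bayesian bands, and residual diagnostics.

test_that("asymptotic intervals reduce to classical linear regression", {
  set.seed(8)
  n <- 40
  x <- seq(0, 10, length.out = n)
  X <- cbind(`(Intercept)` = 1, x = x)
  beta <- c(2, 0.7)
  y <- drop(X %*% beta) + rnorm(n, 0, 1.5)
  lmfit <- lm(y ~ x)
  est <- coef(lmfit)
  ci <- asymptotic_ci(est, residuals(lmfit), X, alpha = 0.05)
  ref <- confint(lmfit)
  expect_equal(unname(as.matrix(ci[, c("lower", "upper")])), unname(ref),
               tolerance = 1e-8)
  expect_equal(attr(ci, "sigma2"), summary(lmfit)$sigma^2, tolerance = 1e-10)
})

test_that("output bands reduce to classical regression bands", {
  set.seed(9)
  n <- 30
  x <- seq(-3, 3, length.out = n)
  X <- cbind(1, x)
  y <- drop(X %*% c(1, -2)) + rnorm(n, 0, 0.8)
  lmfit <- lm(y ~ x)
  bands <- regression_bands(fitted(lmfit), residuals(lmfit), X, X,
                            alpha = 0.05)
  ref_ci <- predict(lmfit, interval = "confidence")
  ref_pi <- suppressWarnings(predict(lmfit, interval = "prediction"))
  expect_equal(bands$ci_lo, unname(ref_ci[, "lwr"]), tolerance = 1e-8)
  expect_equal(bands$ci_hi, unname(ref_ci[, "upr"]), tolerance = 1e-8)
  expect_equal(bands$pi_lo, unname(ref_pi[, "lwr"]), tolerance = 1e-8)
  expect_equal(bands$pi_hi, unname(ref_pi[, "upr"]), tolerance = 1e-8)
})

test_that("zero residuals collapse every interval onto the fit", {
  X <- cbind(1, 1:10)
  y <- drop(X %*% c(1, 2))
  est <- c(a = 1, b = 2)
  ci <- asymptotic_ci(est, y - y, X)
  expect_equal(ci$lower, ci$estimate)
  expect_equal(ci$upper, ci$estimate)
  bands <- regression_bands(y, y - y, X, X)
  expect_equal(bands$ci_lo, bands$ci_hi)
  expect_equal(bands$pi_lo, bands$pi_hi)
})

test_that("a singular design is reported as an identifiability failure", {
  X <- cbind(a = 1:6, b = 2 * (1:6))
  expect_error(asymptotic_ci(c(a = 1, b = 1), rnorm(6), X), "identifiab")
})

test_that("frequentist bands keep prediction outside confidence pointwise", {
  fit <- quick_fit()
  bands <- predict(fit, interval = "prediction")
  for (s in names(bands)) {
    b <- bands[[s]]
    expect_true(all(b$ci_lo <= b$center & b$center <= b$ci_hi))
    expect_true(all(b$pi_lo <= b$ci_lo))
    expect_true(all(b$pi_hi >= b$ci_hi))
    expect_true(all(b$pi_hi - b$pi_lo > b$ci_hi - b$ci_lo))
  }
})

test_that("timing parameters are far better resolved than the mitral resistance", {
  fit <- quick_fit()
  ci <- confint(fit)
  rel_half <- (ci$upper - ci$lower) / 2 / abs(ci$estimate)
  names(rel_half) <- rownames(ci)
  expect_gt(rel_half[["r_mv"]], 5 * rel_half[["t_s"]])
  expect_gt(rel_half[["r_mv"]], 5 * rel_half[["t_e"]])
  expect_lt(rel_half[["t_s"]], 0.05)
  expect_lt(rel_half[["t_e"]], 0.05)
})

test_that("Bayesian bands nest correctly and report failed draws", {
  d <- noisy_mouse()
  ch <- pv_mcmc(d, params = quick_fit()$theta_full, n_iter = 600, seed = 2,
                adapt_start = 150)
  bands <- bayesian_output_bands(ch, n_draws = 100, seed = 4)
  for (s in names(bands)) {
    b <- bands[[s]]
    expect_true(all(b$ci_lo <= b$center & b$center <= b$ci_hi))
    expect_true(all(b$pi_lo <= b$ci_lo & b$pi_hi >= b$ci_hi))
    expect_identical(attr(b, "n_failed"), 0L)
  }
})

test_that("residual diagnostics flag each generating error model", {
  x <- seq(0, 5, length.out = 150)
  tb_c <- noise_testbed(x, noise_spec("correlated", sigma = 0.5, rho = 0.8,
                                      seed = 6))
  d_c <- cardiofit:::.diagnose_residuals(tb_c$y_noisy - tb_c$y_true, x)
  expect_true(d_c$correlated)
  expect_equal(d_c$lag1, 0.8, tolerance = 0.1)
  tb_h <- noise_testbed(x, noise_spec("heteroskedastic", sigma = 0.5,
                                      gamma = 1, seed = 6))
  expect_equal(classify_residuals(tb_h$y_noisy - tb_h$y_true, x),
               "heteroskedastic")
  tb_i <- noise_testbed(x, noise_spec("iid", sigma = 0.5, seed = 6))
  expect_equal(classify_residuals(tb_i$y_noisy - tb_i$y_true, x), "iid")
})

test_that("model-based residual diagnostics run per signal with a verdict", {
  d <- noisy_mouse()
  diag <- residual_diagnostics(coef(quick_fit()), d, params = mouse_truth)
  expect_named(diag$signals, c("v_lv", "p_lv", "p_ao"))
  expect_true(diag$verdict %in% c("iid", "non-iid"))
  for (s in diag$signals) {
    expect_length(s$residuals, length(d$time))
    expect_equal(nrow(s$qq), length(d$time))
  }
})
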