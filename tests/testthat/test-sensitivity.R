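# Sensitivity analysis, influence ranking, correlation analysis, subset
# selection, and profile likelihood.

test_that("finite differences reproduce analytic derivatives on the quadratic testbed", {
  x <- seq(0, 5, length.out = 50)
  f <- function(th) th[1] * x^2 + th[2] * x + th[3]
  th0 <- c(0.4, -0.1, 2)
  J <- cardiofit:::fd_jacobian(f, th0, rel_step = 1e-4)
  exact <- cbind(x^2, x, rep(1, length(x)))
  expect_lt(max(abs(J - exact) / pmax(abs(exact), 1)), 1e-6)
})

test_that("influence scores equal a brute-force double loop and ignore row order", {
  d <- noiseless_mouse()
  sens <- local_sensitivity(mouse_truth, d)
  rk <- influence_ranking(sens)
  brute <- numeric(ncol(sens$S))
  for (j in seq_len(ncol(sens$S)))
    for (i in seq_len(nrow(sens$S)))
      brute[j] <- brute[j] + sens$S[i, j]^2
  names(brute) <- colnames(sens$S)
  expect_equal(rk, sort(brute, decreasing = TRUE))
  perm <- sample(nrow(sens$S))
  sens2 <- sens
  sens2$S <- sens$S[perm, ]
  expect_equal(influence_ranking(sens2), rk)
  expect_true(all(rk >= 0))
})

test_that("aortic valve resistance is the least influential parameter", {
  d <- noiseless_mouse()
  sens <- local_sensitivity(mouse_truth, d)
  rk <- influence_ranking(sens)
  expect_equal(names(rk)[length(rk)], "r_av")
  # a ten-percent tornado tells the same story
  tor <- tornado_analysis(mouse_truth, delta = 0.10)
  span <- tapply(pmax(abs(tor$up_pct), abs(tor$down_pct)), tor$parameter, max)
  expect_equal(names(which.min(span)), "r_av")
})

test_that("correlation matrix is well-formed and finds the elastance-dead-volume pair", {
  d <- noiseless_mouse()
  sens <- local_sensitivity(mouse_truth, d)
  C <- parameter_correlation(sens)
  expect_equal(diag(C), setNames(rep(1, 9), rownames(C)))
  expect_equal(C, t(C), tolerance = 1e-10)
  expect_true(all(abs(C) <= 1 + 1e-10))
  expect_gt(C["e_es", "v_lv_d"], 0.9)
})

test_that("structurally coupled parameters show near-perfect correlation", {
  # y = a * b * x: the two columns of F are proportional
  x <- seq(0.1, 5, length.out = 60)
  a <- 2; b <- 3
  S <- cbind(a = b * x * a, b = a * x * b)  # relative scaling included
  fake <- structure(list(S = S, parameters = c("a", "b")),
                    class = "pv_sensitivity")
  C <- parameter_correlation(fake)
  expect_gt(abs(C["a", "b"]), 0.999)
})

test_that("subset selection applies the ranking and correlation rules", {
  rk <- c(a = 10, b = 5, c = 0.001)
  C <- diag(3); dimnames(C) <- list(names(rk), names(rk))
  sel <- select_subset(rk, C)
  expect_setequal(sel$free, c("a", "b"))
  expect_match(sel$fixed[["c"]], "noninfluential")
  # no floor violation, no correlation: everything stays free
  C2 <- C; rk2 <- c(a = 10, b = 5, c = 4)
  expect_setequal(select_subset(rk2, C2)$free, c("a", "b", "c"))
  # correlated pair drops the lower-ranked member
  C3 <- C; C3["a", "b"] <- C3["b", "a"] <- 0.99
  sel3 <- select_subset(rk2, C3)
  expect_true("b" %in% names(sel3$fixed))
  expect_true("a" %in% sel3$free)
})

test_that("the mouse-like problem reduces to the seven-parameter subset", {
  d <- noiseless_mouse()
  sens <- local_sensitivity(mouse_truth, d)
  sel <- select_subset(influence_ranking(sens), parameter_correlation(sens))
  expect_setequal(sel$free, mouse_free7)
  expect_setequal(names(sel$fixed), c("r_av", "v_lv_d"))
})

test_that("profile likelihood classifies a well-identified parameter", {
  d <- noisy_mouse()
  fit <- quick_fit()
  est <- coef(fit)[["t_s"]]
  grid <- seq(0.9, 1.1, length.out = 7) * est
  pr <- profile_likelihood(d, fit$theta_full, mouse_free7, "t_s", grid)
  expect_s3_class(pr, "pv_profile")
  expect_equal(pr$classification, "identifiable")
  # minimum sits within one grid step of the estimate
  expect_lt(abs(pr$grid[which.min(pr$cost)] - est), 1.5 * diff(grid)[1])
  # threshold uses the chi-square quantile with one degree of freedom
  n <- 3 * length(d$time)
  expect_equal(pr$threshold,
               pr$j_min * (1 + qchisq(0.95, 1) / (n - 7)))
})

test_that("profile classification tracks how far the sweep stresses r_av", {
  d <- noisy_mouse()
  fit <- quick_fit()
  th <- fit$theta_full
  free8 <- c(mouse_free7, "r_av")
  # within +/-20% of its value the profiled cost never reaches the
  # threshold: locally flat, the basis for fixing r_av a priori
  flat <- profile_likelihood(d, th, free8, "r_av",
                             c(8e-4, 9e-4, 1e-3, 1.1e-3, 1.2e-3))
  expect_equal(flat$classification, "flat")
  # over the full physiological decade the data do constrain r_av
  wide <- profile_likelihood(d, th, free8, "r_av",
                             c(2e-4, 1e-3, 5e-3, 1e-2))
  expect_equal(wide$classification, "identifiable")
  # a sweep cut off on one side of the minimum is reported as one-sided
  half <- profile_likelihood(d, th, free8, "r_av",
                             c(2e-4, 5e-4, 1e-3, 2e-3))
  expect_equal(half$classification, "one_sided")
})
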