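# Data handling: CSV round trips, beat averaging, a priori parameter
# formulas, synthetic noise models, and the quadratic testbed.

test_that("CSV round trip is lossless", {
  d <- noiseless_mouse()
  path <- withr::local_tempfile(fileext = ".csv")
  write_pv_csv(d, path)
  d2 <- read_pv_csv(path)
  for (s in c("time", "v_lv", "p_lv", "p_ao"))
    expect_equal(d2[[s]], d[[s]], tolerance = 1e-12)
})

test_that("CSV reader reports missing columns and bad grids", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,V_LV,P_LV", "0,30,10", "0.002,31,11"), path)
  expect_error(read_pv_csv(path), "P_Ao")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,V_LV,P_LV,P_Ao", "0,30,10,60", "0.002,31,11,61",
               "0.005,32,12,62"), path2)
  expect_error(read_pv_csv(path2), "uniform")
  expect_error(read_pv_csv("no/such/file.csv"), "not found")
})

test_that("beat averaging folds multi-beat recordings correctly", {
  d <- noiseless_mouse()
  n <- length(d$time)
  rep50 <- function(x) rep(x, 50)
  avg <- average_beats(rep50(d$v_lv), rep50(d$p_lv), rep50(d$p_ao),
                       d$sampling_rate, d$t_cycle, n_beats = 50)
  expect_length(avg$v_lv, n)
  expect_equal(avg$v_lv, d$v_lv)
  expect_equal(avg$p_ao, d$p_ao)
  expect_error(average_beats(d$v_lv, d$p_lv, d$p_ao, d$sampling_rate,
                             d$t_cycle, n_beats = 2), "insufficient")
})

test_that("averaging 50 noisy beats shrinks the noise by about sqrt(50)", {
  d <- noiseless_mouse()
  n <- length(d$time)
  set.seed(21)
  sds <- replicate(100, {
    noisy <- rep(d$p_lv, 50) + rnorm(50 * n, 0, 2)
    avg <- average_beats(rep(d$v_lv, 50), noisy, rep(d$p_ao, 50),
                         d$sampling_rate, d$t_cycle, n_beats = 50)
    sd(avg$p_lv - d$p_lv)
  })
  expect_lt(abs(mean(sds) - 2 / sqrt(50)) / (2 / sqrt(50)), 0.2)
})

test_that("a priori parameters follow the extremum formulas", {
  d <- noiseless_mouse()
  ap <- apriori_parameters(d)
  expect_equal(ap[["e_es"]], max(d$p_lv) / min(d$v_lv))
  expect_equal(ap[["e_ed"]], min(d$p_lv) / max(d$v_lv))
  co <- (max(d$v_lv) - min(d$v_lv)) / d$t_cycle
  expect_equal(ap[["r_art"]], (mean(d$p_ao) - 20) / co)
  expect_equal(ap[["c_ao"]],
               (max(d$v_lv) - min(d$v_lv)) / (max(d$p_ao) - min(d$p_ao)))
  expect_equal(ap[["r_mv"]], 5e-3)
  expect_equal(ap[["r_av"]], 1e-3)
  expect_equal(ap[["v_lv_d"]], 5)
  flat <- pv_dataset(d$time, rep(30, 55), d$p_lv, rep(60, 55),
                     sampling_rate = 500, t_cycle = 0.11)
  expect_error(apriori_parameters(flat), "degenerate")
})

test_that("synthetic datasets honor the noise specification and the seed", {
  d0 <- synthesize_dataset(mouse_truth, noise = noise_spec(sigma = 0))
  expect_equal(d0$p_lv, attr(d0, "truth")$p_lv)
  d1 <- synthesize_dataset(mouse_truth, noise = noise_spec(sigma = 2, seed = 5))
  d2 <- synthesize_dataset(mouse_truth, noise = noise_spec(sigma = 2, seed = 5))
  expect_identical(d1$p_ao, d2$p_ao)
  resid <- unlist(lapply(c("v_lv", "p_lv", "p_ao"),
                         function(s) d1[[s]] - attr(d1, "truth")[[s]]))
  expect_lt(abs(sd(resid) - 2) / 2, 0.15)
})

test_that("noise spec validates its fields", {
  expect_error(noise_spec(sigma = -1), "sigma")
  expect_error(noise_spec(rho = 1), "rho")
  expect_error(noise_spec("white"), "arg")
})

test_that("quadratic testbed evaluates the printed polynomial", {
  tb <- noise_testbed(c(0, 5), noise_spec(sigma = 0))
  expect_equal(tb$y_true, c(2, 11.5))
  expect_equal(tb$y_noisy, tb$y_true)
})

test_that("heteroskedastic testbed noise grows along the abscissa", {
  x <- seq(0, 5, length.out = 200)
  set.seed(13)
  trends <- replicate(100, {
    tb <- noise_testbed(x, noise_spec("heteroskedastic", sigma = 0.5,
                                      gamma = 1.0))
    r <- tb$y_noisy - tb$y_true
    # rolling-window residual sd vs window position
    win <- split(abs(r), rep(1:10, each = 20))
    cor(1:10, vapply(win, sd, 0), method = "spearman")
  })
  expect_gt(mean(trends), 0.5)
  expect_gt(mean(trends > 0), 0.95)
})

test_that("correlated noise has the requested lag-1 autocorrelation", {
  x <- seq(0, 5, length.out = 4000)
  tb <- noise_testbed(x, noise_spec("correlated", sigma = 1, rho = 0.8,
                                    seed = 3))
  r <- tb$y_noisy - tb$y_true
  expect_equal(stats::acf(r, lag.max = 1, plot = FALSE)$acf[2], 0.8,
               tolerance = 0.1)
  expect_equal(sd(r), 1, tolerance = 0.1)
})
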