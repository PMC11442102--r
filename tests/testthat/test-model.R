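# Circuit model: elastance, pressures, valves, rhs, and the periodic-beat
# integrator.

test_that("elastance ramp hits its anchor points and is periodic", {
  p <- mouse_truth
  cst <- pv_constants()
  expect_equal(elastance(0, p), p[["e_ed"]])
  expect_equal(elastance(p[["t_s"]], p), p[["e_es"]])
  expect_equal(elastance(p[["t_e"]], p), p[["e_ed"]])
  # halfway up the cosine ramp the elastance is the midpoint of the range
  expect_equal(elastance(p[["t_s"]] / 2, p), (0.146 + 4.85) / 2,
               tolerance = 1e-2)
  # closed-form oracle for the full ramp, written independently in R
  tt <- seq(0, cst[["t_cycle"]], length.out = 201)
  ramp <- function(t) {
    es <- p[["e_es"]]; ed <- p[["e_ed"]]; ts <- p[["t_s"]]; te <- p[["t_e"]]
    ifelse(t < ts, ed + (es - ed) * (1 - cos(pi * t / ts)) / 2,
      ifelse(t < te, ed + (es - ed) * (1 + cos(pi * (t - ts) / (te - ts))) / 2,
             ed))
  }
  expect_equal(elastance(tt, p), ramp(tt), tolerance = 1e-12)
  expect_equal(elastance(tt + 3 * cst[["t_cycle"]], p), elastance(tt, p))
  expect_error(elastance(NaN, p), "finite")
})

test_that("LV pressure follows the linear elastance relation, sign included", {
  p <- mouse_truth
  expect_equal(lv_pressure(p[["v_lv_d"]], 0.03, p), 0)
  # E(t_s) = e_es = 4.85; 20 uL above dead volume
  expect_equal(lv_pressure(p[["v_lv_d"]] + 20, p[["t_s"]], p), 4.85 * 20)
  expect_lt(lv_pressure(p[["v_lv_d"]] - 1, p[["t_s"]], p), 0)
})

test_that("valve flow is a diode", {
  expect_equal(valve_flow(10, 5, 5e-3), 1000)
  expect_equal(valve_flow(5, 10, 5e-3), 0)
  expect_equal(valve_flow(7, 7, 1e-3), 0)
  expect_error(valve_flow(10, 5, 0), "positive")
})

test_that("rhs matches hand arithmetic and conserves the isovolumic phase", {
  cst <- pv_constants()
  # e_es = 4, V = 30, V_d = 5 at t = t_s gives P_lv = 100 exactly
  p <- pv_params(e_es = 4, v_lv_d = 5, r_av = 1e-3, r_art = 0.268,
                 c_ao = 0.968)
  st <- c(v_lv = 30, p_ao = 80)
  d <- pv_rhs(p[["t_s"]], st, p, cst)
  q_av <- (100 - 80) / 1e-3           # 20000
  q_sys <- (80 - 20) / 0.268          # 223.88...
  expect_equal(d[["dv_lv"]], -q_av)   # mitral closed (p_la < 100)
  expect_equal(d[["dp_ao"]], (q_av - q_sys) / 0.968, tolerance = 1e-12)
  # both valves closed: p_la < P_lv < p_ao -> isovolumic
  st2 <- c(v_lv = 7, p_ao = 80)       # P_lv = 4*2 = 8, between 5 and 80
  d2 <- pv_rhs(p[["t_s"]], st2, p, cst)
  expect_equal(d2[["dv_lv"]], 0)
})

test_that("steady-beat integration converges, respects diodes, and balances volume", {
  beat <- simulate_to_steady_beat(mouse_truth)
  expect_true(beat$converged)
  expect_lte(beat$n_beats_to_converge, 50)
  expect_lt(beat$convergence_metric, 1e-6)
  expect_gte(min(beat$q_mv), 0)
  expect_gte(min(beat$q_av), 0)
  # periodic flow balance: inflow equals outflow over the beat (quadrature
  # on a fine grid, wrapped around the cycle)
  fine <- simulate_to_steady_beat(mouse_truth, dt = 1 / 4000)
  trapz <- function(x, y) sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  tt <- c(fine$time, 0.11)
  in_flow <- trapz(tt, c(fine$q_mv, fine$q_mv[1]))
  out_flow <- trapz(tt, c(fine$q_av, fine$q_av[1]))
  expect_lt(abs(in_flow - out_flow) / out_flow, 1e-3)
  # net volume change over the converged beat: the start of the following
  # beat is V(t_cycle), so the consecutive-beat metric bounds |V(T) - V(0)|
  nxt <- suppressWarnings(simulate_to_steady_beat(
    mouse_truth, tol = 1e-12, max_beats = beat$n_beats_to_converge + 1))
  expect_lt(nxt$convergence_metric, 10 * 1e-6)
})

test_that("returned beat is insensitive to allowing more beats and finer output grids", {
  b1 <- simulate_to_steady_beat(mouse_truth, max_beats = 50)
  b2 <- simulate_to_steady_beat(mouse_truth, max_beats = 100)
  expect_lt(max(abs(b1$v_lv - b2$v_lv)) / max(b1$v_lv), 1e-5)
  expect_lt(max(abs(b1$p_ao - b2$p_ao)) / max(b1$p_ao), 1e-5)
  # halving dt: shared grid points agree to well within discretization error
  b3 <- simulate_to_steady_beat(mouse_truth, dt = 1 / 1000)
  shared <- seq(1, length(b3$time), by = 2)
  expect_lt(max(abs(b3$v_lv[shared] - b1$v_lv)) / max(b1$v_lv), 1e-4)
})

test_that("compiled integrator agrees with the deSolve reference route", {
  b_cpp <- simulate_to_steady_beat(mouse_truth)
  b_ref <- simulate_to_steady_beat(mouse_truth, engine = "desolve")
  expect_equal(b_cpp$v_lv, b_ref$v_lv, tolerance = 1e-4)
  expect_equal(b_cpp$p_ao, b_ref$p_ao, tolerance = 1e-4)
  expect_equal(b_cpp$p_lv, b_ref$p_lv, tolerance = 1e-3)
})

test_that("beat summary equals brute-force scans", {
  beat <- simulate_to_steady_beat(mouse_truth)
  s <- beat_summary(beat)
  mx <- -Inf; mn <- Inf
  for (v in beat$v_lv) { if (v > mx) mx <- v; if (v < mn) mn <- v }
  expect_equal(s[["v_lv_max"]], mx)
  expect_equal(s[["v_lv_min"]], mn)
  expect_equal(s[["stroke_volume"]], mx - mn)
  expect_equal(s[["cardiac_output"]], (mx - mn) / 0.11)
})

test_that("integrator rejects a dt that does not divide the cycle", {
  expect_error(simulate_to_steady_beat(mouse_truth, dt = 0.003), "divide")
})

test_that("parameter validation enforces physiological invariants", {
  expect_error(pv_params(e_es = 0.1, e_ed = 0.2), "e_es")
  expect_error(pv_params(t_s = 0.08, t_e = 0.05), "timing")
  expect_error(pv_params(r_mv = -1), "positive")
})
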