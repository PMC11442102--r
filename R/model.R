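#' Time-varying LV elastance
#'
#' Two-piece cosine ramp: the elastance rises from `e_ed` at the start of the
#' cycle to its peak `e_es` at `t_s`, relaxes back to `e_ed` at `t_e`, and
#' stays at `e_ed` for the remainder of the cycle. The curve is continuous
#' and periodic with period `t_cycle`.
#'
#' @param t Time (s); reduced modulo the cycle length. Vectorized.
#' @param params A [pv_params()] object.
#' @param constants A [pv_constants()] object.
#'
#' @return Elastance (mmHg/uL), same length as `t`.
#' @export
#'
#' @examples
#' p <- pv_params()
#' elastance(0, p)                 # e_ed
#' elastance(p[["t_s"]], p)        # e_es
elastance <- function(t, params, constants = pv_constants()) {
  if (any(!is.finite(t))) stop("time must be finite")
  .elastance_cpp(as.numeric(t), as.numeric(params), as.numeric(constants))
}

#' LV pressure from the linear elastance relation
#'
#' `P_LV = E(t) * (V_LV - V_LV,d)`. Negative values are possible when the
#' volume drops below the dead volume and are returned as-is.
#'
#' @param v_lv LV volume (uL).
#' @param t Time (s).
#' @inheritParams elastance
#'
#' @return Pressure (mmHg).
#' @export
lv_pressure <- function(v_lv, t, params, constants = pv_constants()) {
  elastance(t, params, constants) * (v_lv - params[["v_lv_d"]])
}

#' One-way (diode) valve flow
#'
#' Flow through a resistive valve that only opens forward:
#' `max((p_upstream - p_downstream) / r, 0)`.
#'
#' @param p_upstream,p_downstream Pressures (mmHg).
#' @param r Valve resistance (mmHg s/uL), strictly positive.
#'
#' @return Flow (uL/s), never negative.
#' @export
valve_flow <- function(p_upstream, p_downstream, r) {
  if (any(r <= 0)) stop("valve resistance must be strictly positive")
  pmax((p_upstream - p_downstream) / r, 0)
}

#' Right-hand side of the circuit ODE
#'
#' State is `(v_lv, p_ao)`. LV volume changes by the mitral inflow minus the
#' aortic outflow; aortic pressure by the net aortic volume flux over the
#' compliance, with `q_sys = (p_ao - p_cap) / r_art` (which may be negative).
#'
#' @param t Time (s).
#' @param state Named numeric vector `c(v_lv = , p_ao = )`.
#' @inheritParams elastance
#'
#' @return Named vector `c(dv_lv, dp_ao)` (uL/s, mmHg/s).
#' @export
pv_rhs <- function(t, state, params, constants = pv_constants()) {
  p_lv <- lv_pressure(state[["v_lv"]], t, params, constants)
  q_mv <- valve_flow(constants[["p_la"]], p_lv, params[["r_mv"]])
  q_av <- valve_flow(p_lv, state[["p_ao"]], params[["r_av"]])
  q_sys <- (state[["p_ao"]] - constants[["p_cap"]]) / params[["r_art"]]
  c(dv_lv = q_mv - q_av,
    dp_ao = (q_av - q_sys) / params[["c_ao"]])
}

#' Simulate the model to a converged periodic beat
#'
#' Integrates the circuit beat-by-beat from a fixed initial state
#' (`V_LV = 40` uL, `P_Ao = 70` mmHg) until the beat sampled on the output
#' grid is periodic: the sup-norm relative change of `(v_lv, p_ao)` between
#' consecutive beats falls below `tol`. The converged beat is returned on the
#' uniform grid `t_k = k * dt`, `k = 0, ..., n-1` (endpoint excluded).
#'
#' @inheritParams elastance
#' @param dt Output sampling interval (s); must divide the cycle length.
#'   Default `1/500` (500 Hz).
#' @param max_beats Maximum number of beats to integrate (default 50).
#' @param tol Periodic-convergence tolerance (default 1e-6).
#' @param rtol,atol Relative and absolute tolerance of the adaptive
#'   Runge-Kutta integrator.
#' @param engine `"cpp"` (default, compiled Dormand-Prince 5(4)) or
#'   `"desolve"` (reference integration of [pv_rhs()] with [deSolve::ode()],
#'   used for cross-checking).
#'
#' @return An object of class `pv_beat`: a list with vectors `time`, `v_lv`,
#'   `p_lv`, `p_ao`, `q_mv`, `q_av`, `q_sys`, plus `n_beats_to_converge`,
#'   `convergence_metric`, and `converged`.
#' @export
#'
#' @examples
#' beat <- simulate_to_steady_beat(pv_params())
#' beat_summary(beat)
simulate_to_steady_beat <- function(params, constants = pv_constants(),
                                    dt = 1 / 500, max_beats = 50, tol = 1e-6,
                                    rtol = 1e-8, atol = 1e-10,
                                    engine = c("cpp", "desolve")) {
  engine <- match.arg(engine)
  tc <- constants[["t_cycle"]]
  n_grid <- round(tc / dt)
  if (abs(n_grid * dt - tc) > 1e-9 * tc)
    stop("dt must divide the cycle length t_cycle")
  params <- as_pv_params(params, constants = constants)

  if (engine == "cpp") {
    res <- .simulate_beats_cpp(as.numeric(params), as.numeric(constants),
                               as.integer(n_grid), tol, as.integer(max_beats),
                               rtol, atol, 40, 70)
    if (!res$finite)
      stop("solver produced a non-finite state for parameters: ",
           paste(sprintf("%s=%.4g", .param_names, as.numeric(params)),
                 collapse = ", "))
  } else {
    res <- .simulate_beats_desolve(params, constants, n_grid, tol, max_beats,
                                   rtol, atol)
  }
  if (!res$converged)
    warning(sprintf(
      "beat not periodic after %d beats (metric %.3g > tol %.3g)",
      max_beats, res$metric, tol))
  structure(list(
    time = res$time, v_lv = res$v_lv, p_lv = res$p_lv, p_ao = res$p_ao,
    q_mv = res$q_mv, q_av = res$q_av, q_sys = res$q_sys,
    n_beats_to_converge = res$n_beats, convergence_metric = res$metric,
    converged = res$converged, dt = dt, constants = constants,
    params = params), class = "pv_beat")
}

# Reference route: same beat loop, but each beat integrated with deSolve on
# the R-level rhs. Slow; kept as an independent verification path.
.simulate_beats_desolve <- function(params, constants, n_grid, tol, max_beats,
                                    rtol, atol) {
  dt <- constants[["t_cycle"]] / n_grid
  grid <- seq(0, constants[["t_cycle"]], by = dt)  # includes endpoint
  deriv <- function(t, y, parms) {
    list(pv_rhs(t, c(v_lv = y[[1]], p_ao = y[[2]]), params, constants))
  }
  y <- c(40, 70)
  prev <- NULL; metric <- Inf; converged <- FALSE; beat <- 0
  while (beat < max_beats) {
    beat <- beat + 1
    sol <- deSolve::ode(y, grid, deriv, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    cur <- sol[seq_len(n_grid), 2:3, drop = FALSE]
    y <- as.numeric(sol[nrow(sol), 2:3])
    if (!all(is.finite(y))) stop("solver produced a non-finite state")
    if (!is.null(prev)) {
      metric <- max(max(abs(cur[, 1] - prev[, 1])) / max(abs(cur[, 1])),
                    max(abs(cur[, 2] - prev[, 2])) / max(abs(cur[, 2])))
      if (metric < tol) { converged <- TRUE; break }
    }
    prev <- cur
  }
  time <- grid[seq_len(n_grid)]
  p_lv <- lv_pressure(cur[, 1], time, params, constants)
  list(time = time, v_lv = cur[, 1], p_lv = p_lv, p_ao = cur[, 2],
       q_mv = valve_flow(constants[["p_la"]], p_lv, params[["r_mv"]]),
       q_av = valve_flow(p_lv, cur[, 2], params[["r_av"]]),
       q_sys = (cur[, 2] - constants[["p_cap"]]) / params[["r_art"]],
       n_beats = beat, metric = metric, converged = converged)
}

#' Summary hemodynamics of a converged beat
#'
#' @param beat A `pv_beat` from [simulate_to_steady_beat()].
#'
#' @return Named vector: extrema of LV pressure/volume and aortic pressure,
#'   stroke volume (uL), mean aortic pressure (mmHg), and cardiac output
#'   (uL/s, stroke volume over cycle length).
#' @export
beat_summary <- function(beat) {
  stopifnot(inherits(beat, "pv_beat"), length(beat$time) > 0)
  sv <- max(beat$v_lv) - min(beat$v_lv)
  c(p_lv_max = max(beat$p_lv), p_lv_min = min(beat$p_lv),
    v_lv_max = max(beat$v_lv), v_lv_min = min(beat$v_lv),
    p_ao_max = max(beat$p_ao), p_ao_min = min(beat$p_ao),
    p_ao_mean = mean(beat$p_ao),
    stroke_volume = sv,
    cardiac_output = sv / beat$constants[["t_cycle"]])
}

#' @export
print.pv_beat <- function(x, ...) {
  cat(sprintf(
    "Periodic beat: %d grid points over %.4g s (%s in %d beats, metric %.2g)\n",
    length(x$time), x$constants[["t_cycle"]],
    if (x$converged) "converged" else "NOT converged",
    x$n_beats_to_converge, x$convergence_metric))
  print(round(beat_summary(x), 3))
  invisible(x)
}

#' @export
as.data.frame.pv_beat <- function(x, ...) {
  data.frame(time = x$time, P_LV = x$p_lv, V_LV = x$v_lv, P_Ao = x$p_ao,
             Q_mv = x$q_mv, Q_av = x$q_av, Q_sys = x$q_sys)
}

#' Write a simulated beat to CSV
#'
#' Columns `time,P_LV,V_LV,P_Ao,Q_mv,Q_av,Q_sys`.
#'
#' @param beat A `pv_beat`.
#' @param path Output file path.
#' @export
write_beat_csv <- function(beat, path) {
  write.csv(as.data.frame(beat), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.pv_beat <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$time, cbind(x$p_lv, x$p_ao), type = "l", lty = 1,
                    xlab = "time (s)", ylab = "pressure (mmHg)",
                    main = "Pressures", col = c("firebrick", "steelblue"))
  graphics::legend("topright", c("P_LV", "P_Ao"), lty = 1, bty = "n",
                   col = c("firebrick", "steelblue"))
  graphics::plot(x$v_lv, x$p_lv, type = "l", xlab = "V_LV (uL)",
                 ylab = "P_LV (mmHg)", main = "PV loop")
  invisible(x)
}
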