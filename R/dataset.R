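#' A single-beat pressure-volume dataset
#'
#' Container for one cardiac cycle of aligned LV volume, LV pressure, and
#' aortic pressure measurements on a uniform time grid.
#'
#' @param time Time grid (s), uniform, starting at 0.
#' @param v_lv LV volume (uL).
#' @param p_lv LV pressure (mmHg).
#' @param p_ao Aortic pressure (mmHg).
#' @param sampling_rate Sampling rate (Hz). Inferred from the grid if omitted.
#' @param t_cycle Cycle length (s). Defaults to `n / sampling_rate`.
#'
#' @return An object of class `pv_dataset`.
#' @export
pv_dataset <- function(time, v_lv, p_lv, p_ao, sampling_rate = NULL,
                       t_cycle = NULL) {
  n <- length(time)
  if (n < 2 || length(v_lv) != n || length(p_lv) != n || length(p_ao) != n)
    stop("time, v_lv, p_lv, p_ao must have equal length >= 2")
  dt <- diff(time)
  if (any(abs(dt - dt[1]) > 1e-9))
    stop("time grid is not uniform (tolerance 1e-9 s)")
  if (is.null(sampling_rate)) sampling_rate <- 1 / dt[1]
  if (is.null(t_cycle)) t_cycle <- n / sampling_rate
  if (n != round(sampling_rate * t_cycle))
    stop("length must equal round(sampling_rate * t_cycle)")
  structure(list(time = as.numeric(time), v_lv = as.numeric(v_lv),
                 p_lv = as.numeric(p_lv), p_ao = as.numeric(p_ao),
                 sampling_rate = sampling_rate, t_cycle = t_cycle),
            class = "pv_dataset")
}

#' @export
print.pv_dataset <- function(x, ...) {
  cat(sprintf("PV dataset: %d samples at %g Hz over %.4g s\n",
              length(x$time), x$sampling_rate, x$t_cycle))
  cat(sprintf("  V_LV [%.3g, %.3g] uL, P_LV [%.3g, %.3g] mmHg, P_Ao [%.3g, %.3g] mmHg\n",
              min(x$v_lv), max(x$v_lv), min(x$p_lv), max(x$p_lv),
              min(x$p_ao), max(x$p_ao)))
  invisible(x)
}

#' @export
as.data.frame.pv_dataset <- function(x, ...) {
  data.frame(time = x$time, V_LV = x$v_lv, P_LV = x$p_lv, P_Ao = x$p_ao)
}

#' Read / write a PV dataset as CSV
#'
#' The CSV carries the header `time,V_LV,P_LV,P_Ao`. The round trip is
#' lossless to machine precision (values written with 15 significant digits).
#'
#' @param path File path.
#' @return [read_pv_csv()] returns a [pv_dataset()].
#' @export
read_pv_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  need <- c("time", "V_LV", "P_LV", "P_Ao")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (any(!stats::complete.cases(df[need])))
    stop("ragged or non-numeric rows in ", path)
  pv_dataset(df$time, df$V_LV, df$P_LV, df$P_Ao)
}

#' @rdname read_pv_csv
#' @param dataset A [pv_dataset()].
#' @export
write_pv_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df[] <- lapply(df, function(v) sprintf("%.15g", v))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average a multi-beat recording into one representative beat
#'
#' Splits each signal into consecutive beats of `round(sampling_rate *
#' t_cycle)` samples and takes the pointwise mean over the first `n_beats`.
#'
#' @param v_lv,p_lv,p_ao Multi-beat signal vectors (concatenated beats).
#' @param sampling_rate Sampling rate (Hz).
#' @param t_cycle Cycle length (s).
#' @param n_beats Number of beats to average (default: all complete beats).
#'
#' @return A [pv_dataset()] holding the averaged beat.
#' @export
average_beats <- function(v_lv, p_lv, p_ao, sampling_rate, t_cycle,
                          n_beats = NULL) {
  n_per <- round(sampling_rate * t_cycle)
  if (is.null(n_beats)) n_beats <- length(v_lv) %/% n_per
  if (n_beats < 1 || length(v_lv) < n_beats * n_per)
    stop("insufficient samples: need at least ", n_beats * n_per)
  fold <- function(x) {
    rowMeans(matrix(x[seq_len(n_beats * n_per)], nrow = n_per))
  }
  pv_dataset(time = (seq_len(n_per) - 1) / sampling_rate,
             v_lv = fold(v_lv), p_lv = fold(p_lv), p_ao = fold(p_ao),
             sampling_rate = sampling_rate, t_cycle = t_cycle)
}

#' A priori parameter values from data
#'
#' Initializes the model parameters from measured extrema and physiological
#' relationships: `e_es = max(P_LV)/min(V_LV)`, `e_ed = min(P_LV)/max(V_LV)`,
#' `r_art = (mean(P_Ao) - p_cap)/CO`, and `c_ao` as stroke volume over aortic
#' pulse pressure. Valve resistances and the dead volume take fixed defaults
#' (5e-3, 1e-3 mmHg s/uL; 5 uL). Timing is estimated from the extrema of
#' `dP_LV/dt` (maximal pressure rise for `t_s`, fastest relaxation for
#' `t_e`), falling back to 0.044/0.077 s if the estimates are implausible.
#'
#' @param dataset A [pv_dataset()].
#' @param constants A [pv_constants()].
#' @param cardiac_output Cardiac output (uL/s); defaults to stroke volume
#'   divided by the cycle length.
#'
#' @return A [pv_params()] object.
#' @export
apriori_parameters <- function(dataset, constants = pv_constants(),
                               cardiac_output = NULL) {
  d <- dataset
  sv <- max(d$v_lv) - min(d$v_lv)
  pp <- max(d$p_ao) - min(d$p_ao)
  if (sv <= 0 || pp <= 0) stop("degenerate dataset: zero stroke volume or pulse pressure")
  if (is.null(cardiac_output)) cardiac_output <- sv / d$t_cycle
  if (cardiac_output <= 0) stop("cardiac output must be positive")

  dp <- diff(d$p_lv) * d$sampling_rate
  t_s <- d$time[which.max(dp)]
  t_e <- d$time[which.min(dp)]
  tc <- constants[["t_cycle"]]
  b0 <- pv_bounds(constants)
  t_s <- min(max(t_s, b0["lower", "t_s"]), b0["upper", "t_s"])
  t_e <- min(max(t_e, b0["lower", "t_e"]), b0["upper", "t_e"])
  if (!(t_s < t_e)) {
    t_s <- 4.40e-2 * tc / 0.11
    t_e <- 7.70e-2 * tc / 0.11
  }
  # noise can push an extremum-derived value outside its physiological
  # range; clip into the default bounds rather than fail
  clip <- function(nm, v) min(max(v, b0["lower", nm]), b0["upper", nm])
  pv_params(r_mv = 5e-3, r_av = 1e-3,
            r_art = clip("r_art",
                         (mean(d$p_ao) - constants[["p_cap"]]) / cardiac_output),
            e_es = clip("e_es", max(d$p_lv) / min(d$v_lv)),
            e_ed = clip("e_ed", min(d$p_lv) / max(d$v_lv)),
            t_s = t_s, t_e = t_e,
            v_lv_d = 5, c_ao = clip("c_ao", sv / pp),
            constants = constants)
}

#' Measurement-error specification
#'
#' Three error models for synthetic data: `iid` Gaussian with standard
#' deviation `sigma`; `heteroskedastic` Gaussian with standard deviation
#' `sigma * (1 + gamma * t)` growing along the abscissa; and `correlated`,
#' a stationary lag-1 autoregressive process with coefficient `rho` and
#' marginal standard deviation `sigma`.
#'
#' @param kind One of `"iid"`, `"heteroskedastic"`, `"correlated"`.
#' @param sigma Noise scale in signal units (default 2).
#' @param gamma Heteroskedastic growth rate per abscissa unit (default 5/s,
#'   a 55% standard-deviation increase over a 0.11 s beat).
#' @param rho Lag-1 autocorrelation, `|rho| < 1` (default 0.8).
#' @param seed Optional integer seed for reproducible draws.
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("iid", "heteroskedastic", "correlated"),
                       sigma = 2, gamma = 5, rho = 0.8, seed = NULL) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be nonnegative")
  if (gamma < 0) stop("gamma must be nonnegative")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  structure(list(kind = kind, sigma = sigma, gamma = gamma, rho = rho,
                 seed = seed), class = "noise_spec")
}

# One noise stream over abscissa x under the given spec. Caller manages RNG.
.draw_noise <- function(x, noise) {
  n <- length(x)
  switch(noise$kind,
    iid = rnorm(n, 0, noise$sigma),
    heteroskedastic = rnorm(n, 0, noise$sigma * (1 + noise$gamma * x)),
    correlated = {
      e <- numeric(n)
      e[1] <- rnorm(1, 0, noise$sigma)
      innov_sd <- noise$sigma * sqrt(1 - noise$rho^2)
      for (k in seq_len(n)[-1]) e[k] <- noise$rho * e[k - 1] + rnorm(1, 0, innov_sd)
      e
    })
}

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic PV dataset
#'
#' Simulates the model to its periodic beat, samples it on the measurement
#' grid, and adds measurement noise independently to each of the three
#' signals according to `noise`. The noiseless truth is attached as the
#' `"truth"` attribute (itself a [pv_dataset()]).
#'
#' @inheritParams simulate_to_steady_beat
#' @param noise A [noise_spec()].
#' @param sampling_rate Sampling rate (Hz), default 500.
#'
#' @return A [pv_dataset()] with attributes `truth` (noiseless dataset) and
#'   `params` (generating parameters).
#' @export
#'
#' @examples
#' d <- synthesize_dataset(pv_params(), noise = noise_spec("iid", sigma = 2, seed = 1))
#' range(d$p_lv - attr(d, "truth")$p_lv)
synthesize_dataset <- function(params, constants = pv_constants(),
                               noise = noise_spec(), sampling_rate = 500,
                               ...) {
  beat <- simulate_to_steady_beat(params, constants, dt = 1 / sampling_rate, ...)
  truth <- pv_dataset(beat$time, beat$v_lv, beat$p_lv, beat$p_ao,
                      sampling_rate = sampling_rate,
                      t_cycle = constants[["t_cycle"]])
  noisy <- with_seed(noise$seed, {
    lapply(truth[c("v_lv", "p_lv", "p_ao")],
           function(y) y + .draw_noise(truth$time, noise))
  })
  out <- pv_dataset(truth$time, noisy$v_lv, noisy$p_lv, noisy$p_ao,
                    sampling_rate = sampling_rate,
                    t_cycle = constants[["t_cycle"]])
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  out
}

#' Quadratic test function with configurable measurement error
#'
#' A simple known-truth testbed for illustrating and validating the error
#' models and residual diagnostics: `M(x) = 0.4 x^2 - 0.1 x + 2`, observed
#' under the same three noise models as [synthesize_dataset()].
#'
#' @param x Abscissa vector.
#' @param noise A [noise_spec()].
#'
#' @return A list with `x`, `y_true`, and `y_noisy`.
#' @export
#'
#' @examples
#' tb <- noise_testbed(seq(0, 5, length.out = 100),
#'                     noise_spec("heteroskedastic", sigma = 0.5, gamma = 0.3, seed = 1))
noise_testbed <- function(x, noise = noise_spec()) {
  y_true <- 0.4 * x^2 - 0.1 * x + 2
  y_noisy <- with_seed(noise$seed, y_true + .draw_noise(x, noise))
  list(x = x, y_true = y_true, y_noisy = y_noisy)
}
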