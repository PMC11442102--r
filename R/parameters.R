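#' Fixed physiological constants of the circuit
#'
#' The left atrium and the systemic capillaries are modeled as constant
#' pressure sources; the cardiac cycle length is fixed.
#'
#' @param p_la Left atrial pressure (mmHg), default 5.
#' @param p_cap Systemic capillary pressure (mmHg), default 20.
#' @param t_cycle Cardiac cycle length (s), default 0.11 (adult mouse).
#'
#' @return An object of class `pv_constants` (named numeric vector).
#' @export
#'
#' @examples
#' pv_constants()
pv_constants <- function(p_la = 5, p_cap = 20, t_cycle = 0.11) {
  x <- c(p_la = p_la, p_cap = p_cap, t_cycle = t_cycle)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all constants must be finite and strictly positive")
  structure(x, class = "pv_constants")
}

#' Model parameters of the LV-aorta circuit
#'
#' The nine inferable quantities: valve and arterial resistances
#' (mmHg s/uL), end-systolic and end-diastolic elastance (mmHg/uL), times of
#' maximum and minimum elastance (s), LV dead volume (uL), and aortic
#' compliance (uL/mmHg).
#'
#' @param r_mv,r_av,r_art Mitral valve, aortic valve, and arterial resistance
#'   (mmHg s/uL).
#' @param e_es,e_ed End-systolic and end-diastolic elastance (mmHg/uL);
#'   `e_es > e_ed` is required.
#' @param t_s,t_e Time of maximum and of minimum elastance (s);
#'   `0 < t_s < t_e < t_cycle` is required.
#' @param v_lv_d LV dead (unstressed) volume (uL).
#' @param c_ao Aortic compliance (uL/mmHg).
#' @param constants A [pv_constants()] object used to validate the timing
#'   parameters.
#'
#' @return An object of class `pv_params` (named numeric vector).
#' @export
#'
#' @examples
#' pv_params()  # a priori mouse values
pv_params <- function(r_mv = 5e-3, r_av = 1e-3, r_art = 2.68e-1,
                      e_es = 4.85, e_ed = 1.46e-1,
                      t_s = 4.40e-2, t_e = 7.70e-2,
                      v_lv_d = 5, c_ao = 9.68e-1,
                      constants = pv_constants()) {
  x <- c(r_mv = r_mv, r_av = r_av, r_art = r_art, e_es = e_es, e_ed = e_ed,
         t_s = t_s, t_e = t_e, v_lv_d = v_lv_d, c_ao = c_ao)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all parameters must be finite and strictly positive")
  if (e_es <= e_ed) stop("e_es must exceed e_ed")
  if (!(t_s < t_e && t_e < constants[["t_cycle"]]))
    stop("timing must satisfy 0 < t_s < t_e < t_cycle")
  structure(x, class = "pv_params")
}

#' @export
print.pv_params <- function(x, ...) {
  cat("LV-aorta model parameters:\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.pv_constants <- function(x, ...) {
  cat("Fixed circuit constants (mmHg, mmHg, s):\n")
  print(unclass(x), ...)
  invisible(x)
}

# Coerce a named vector (full or partial) into a valid pv_params, filling
# unmentioned entries from `base`.
as_pv_params <- function(theta, base = pv_params(), constants = pv_constants()) {
  if (inherits(theta, "pv_params") && length(theta) == 9L) return(theta)
  full <- unclass(base)
  if (length(theta)) {
    nm <- names(theta)
    if (is.null(nm) || !all(nm %in% .param_names))
      stop("parameter names must be among: ", paste(.param_names, collapse = ", "))
    full[nm] <- theta
  }
  do.call(pv_params, c(as.list(full), list(constants = constants)))
}

#' Default parameter bounds for calibration and priors
#'
#' Physiologically plausible ranges for the mouse LV-aorta model, used as
#' optimization bounds and as the support of the uniform priors. Timing
#' bounds are expressed as fractions of the cycle length.
#'
#' @param constants A [pv_constants()] object (sets the cycle length that
#'   scales the timing bounds).
#'
#' @return A matrix with rows `lower` and `upper`, one column per parameter.
#' @export
pv_bounds <- function(constants = pv_constants()) {
  tc <- constants[["t_cycle"]]
  lower <- c(r_mv = 1e-4, r_av = 1e-4, r_art = 0.1, e_es = 0.5, e_ed = 1e-2,
             t_s = 0.33 * tc, t_e = 0.66 * tc, v_lv_d = 1, c_ao = 0.4)
  upper <- c(r_mv = 1e-2, r_av = 1e-2, r_art = 1.0, e_es = 6.0, e_ed = 1.0,
             t_s = 0.66 * tc, t_e = 0.88 * tc, v_lv_d = 10, c_ao = 1.5)
  rbind(lower = lower, upper = upper)
}
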