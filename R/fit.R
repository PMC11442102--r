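# Frequentist calibration: stacked OLS residuals, multistart bounded
# Levenberg-Marquardt, coefficient-of-variation identifiability check, and
# AIC/BIC subset comparison.

# Stacked residuals (data - model) over v_lv, p_lv, p_ao. On simulation
# failure returns a large-residual sentinel so optimizers can continue.
.residuals_at <- function(theta_full, dataset, constants, ...) {
  y <- try(suppressWarnings(.model_output(theta_full, dataset, constants, ...)),
           silent = TRUE)
  n <- 3 * length(dataset$time)
  if (inherits(y, "try-error") || any(!is.finite(y))) {
    warning("simulation failed inside the cost; sentinel residuals used")
    return(rep(sqrt(1e12 / n), n))
  }
  c(dataset$v_lv, dataset$p_lv, dataset$p_ao) - y
}

#' Stacked residual vector and ordinary least-squares cost
#'
#' The cost sums squared differences between the measured and simulated LV
#' volume, LV pressure, and aortic pressure over the beat; the three data
#' sources are neither scaled nor weighted (they are of comparable
#' magnitude in this preparation).
#'
#' @param theta Named numeric vector of parameter values (any subset of the
#'   nine; the rest come from `params`).
#' @param dataset A [pv_dataset()].
#' @param params Full parameter vector supplying fixed entries.
#' @param constants A [pv_constants()].
#' @param ... Passed to the simulator.
#'
#' @return `pv_residuals()`: numeric vector of length `3 * n`;
#'   `pv_cost()`: a single nonnegative number.
#' @export
pv_residuals <- function(theta, dataset, params = pv_params(),
                         constants = pv_constants(), ...) {
  full <- unclass(as_pv_params(params, constants = constants))
  full[names(theta)] <- theta
  .residuals_at(full, dataset, constants, ...)
}

#' @rdname pv_residuals
#' @export
pv_cost <- function(theta, dataset, params = pv_params(),
                    constants = pv_constants(), ...) {
  sum(pv_residuals(theta, dataset, params, constants, ...)^2)
}

# One bounded Levenberg-Marquardt start. Returns theta (named), cost, and
# convergence info; never errors on solver failure (sentinel cost instead).
.lm_fit_once <- function(start, free, fixed_full, dataset, constants, bounds,
                         maxfev = 2000, ...) {
  resid_fn <- function(x) {
    th <- fixed_full
    th[free] <- x
    .residuals_at(th, dataset, constants, ...)
  }
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = bounds["lower", free], upper = bounds["upper", free],
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-10, maxfev = maxfev, maxiter = 500))),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    return(list(theta = start, cost = 1e12, ok = FALSE, message = as.character(fit)))
  theta <- pmin(pmax(coef(fit), bounds["lower", free]), bounds["upper", free])
  list(theta = setNames(as.numeric(theta), free),
       cost = sum(suppressWarnings(resid_fn(theta))^2), ok = TRUE,
       message = fit$message)
}

#' Multistart calibration of the LV-aorta model
#'
#' Minimizes the unweighted least-squares cost over the free parameters from
#' `n_starts` initial points drawn uniformly within the bounds, each refined
#' by bounded Levenberg-Marquardt. The best local optimum is taken as the
#' estimate; the spread of the top-ranked optima (see [top_k_cov()]) probes
#' whether the minimum is global and the parameters practically
#' identifiable.
#'
#' @param dataset A [pv_dataset()].
#' @param free Names of free parameters (default: the seven-parameter mouse
#'   subset, i.e. all but `r_av` and `v_lv_d`).
#' @param params Full parameter vector supplying values for fixed entries
#'   (default: a priori values).
#' @param constants A [pv_constants()].
#' @param bounds Bounds matrix as from [pv_bounds()].
#' @param n_starts Number of random starts (default 100).
#' @param seed Integer seed making the start sample reproducible.
#' @param include_apriori Also start one optimization from `params` itself
#'   (default TRUE; counts toward `n_starts`).
#' @param ... Passed to the simulator (e.g. `tol`, `max_beats`).
#'
#' @return An object of class `pv_fit`: the best estimate and the full
#'   multistart table, with methods `print`, `summary`, `coef`,
#'   `residuals`, `fitted`, `predict`, `confint`, `simulate`, `plot`,
#'   `logLik`, `AIC`.
#' @export
#'
#' @examples
#' \donttest{
#' d <- synthesize_dataset(pv_params(), noise = noise_spec(sigma = 0, seed = 1))
#' fit <- pv_fit(d, n_starts = 5, seed = 1)
#' coef(fit)
#' }
pv_fit <- function(dataset, free = setdiff(.param_names, c("r_av", "v_lv_d")),
                   params = NULL, constants = pv_constants(),
                   bounds = pv_bounds(constants), n_starts = 100, seed = NULL,
                   include_apriori = TRUE, ...) {
  stopifnot(all(free %in% .param_names), n_starts >= 1)
  if (any(bounds["lower", ] >= bounds["upper", ]))
    stop("bounds must satisfy lower < upper")
  if (is.null(params)) params <- apriori_parameters(dataset, constants)
  fixed_full <- unclass(as_pv_params(params, constants = constants))

  lo <- bounds["lower", free]; hi <- bounds["upper", free]
  starts <- with_seed(seed, {
    m <- matrix(runif(n_starts * length(free), lo, hi),
                nrow = n_starts, byrow = TRUE)
    colnames(m) <- free
    m
  })
  if (include_apriori)
    starts[1, ] <- pmin(pmax(fixed_full[free], lo), hi)

  runs <- vector("list", n_starts)
  for (s in seq_len(n_starts))
    runs[[s]] <- .lm_fit_once(starts[s, ], free, fixed_full, dataset,
                              constants, bounds, ...)
  if (!any(vapply(runs, `[[`, TRUE, "ok")))
    stop("all optimization starts failed; messages: ",
         paste(unique(vapply(runs, `[[`, "", "message")), collapse = "; "))

  ord <- order(vapply(runs, `[[`, 0, "cost"))
  runs <- runs[ord]
  est_mat <- do.call(rbind, lapply(runs, `[[`, "theta"))
  costs <- vapply(runs, `[[`, 0, "cost")
  theta_hat <- fixed_full
  theta_hat[free] <- runs[[1]]$theta

  structure(list(
    coefficients = runs[[1]]$theta,
    theta_full = theta_hat,
    free = free, fixed = setdiff(.param_names, free),
    cost = costs[1], costs = costs, estimates = est_mat,
    n_starts = n_starts, seed = seed,
    dataset = dataset, constants = constants, bounds = bounds,
    n_residuals = 3 * length(dataset$time),
    sim_args = list(...)), class = "pv_fit")
}

#' @export
coef.pv_fit <- function(object, ...) object$coefficients

#' @export
residuals.pv_fit <- function(object, ...) {
  do.call(.residuals_at, c(list(object$theta_full, object$dataset,
                                object$constants), object$sim_args))
}

#' @export
fitted.pv_fit <- function(object, ...) {
  do.call(.model_output, c(list(object$theta_full, object$dataset,
                                object$constants), object$sim_args))
}

#' @export
logLik.pv_fit <- function(object, ...) {
  n <- object$n_residuals
  # concentrated Gaussian log-likelihood at sigma2 = J/n
  ll <- -n / 2 * (log(2 * pi * object$cost / n) + 1)
  structure(ll, df = length(object$free) + 1, nobs = n, class = "logLik")
}

#' @export
print.pv_fit <- function(x, ...) {
  cat(sprintf("Multistart LV-aorta calibration (%d starts, %d free parameters)\n",
              x$n_starts, length(x$free)))
  cat(sprintf("  best cost J = %.6g over n = %d residuals\n", x$cost,
              x$n_residuals))
  cat("  estimates:\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' @export
summary.pv_fit <- function(object, alpha = 0.05, k = 20, ...) {
  ci <- confint(object, level = 1 - alpha)
  cov <- top_k_cov(object, k = min(k, object$n_starts))
  ic <- information_criteria(object$cost, object$n_residuals,
                             length(object$free))
  structure(list(fit = object, ci = ci, cov = cov, ic = ic), class = "summary.pv_fit")
}

#' @export
print.summary.pv_fit <- function(x, ...) {
  print(x$fit)
  cat("\n  asymptotic confidence intervals:\n")
  print(signif(x$ci, 4))
  cat(sprintf("\n  top-%d multistart CoV (%%):\n", length(x$cov)))
  print(round(x$cov, 2))
  cat(sprintf("\n  AIC %.1f, BIC %.1f\n", x$ic[["AIC"]], x$ic[["BIC"]]))
  invisible(x)
}

#' Coefficient of variation over the best multistart optima
#'
#' Computes `100 * sd / mean` per free parameter over the `k` lowest-cost
#' local optima. Small values (a few percent) indicate that independent
#' starts land on one minimum; large values flag practical
#' non-identifiability.
#'
#' @param fit A `pv_fit`.
#' @param k Number of top-ranked optima to use (default 20).
#'
#' @return Named vector of CoV percentages.
#' @export
top_k_cov <- function(fit, k = 20) {
  stopifnot(inherits(fit, "pv_fit"), k >= 1, k <= fit$n_starts)
  top <- fit$estimates[seq_len(k), , drop = FALSE]
  m <- colMeans(top)
  if (any(m == 0)) stop("zero mean estimate; CoV undefined")
  100 * apply(top, 2, sd) / abs(m)
}

#' Information criteria for a least-squares fit
#'
#' Gaussian-likelihood forms with constant terms dropped and the noise
#' variance counted as an estimated parameter:
#' `AIC = n log(J/n) + 2 (p + 1)`, `BIC = n log(J/n) + log(n) (p + 1)`.
#'
#' @param j_min Minimized cost (sum of squared residuals), strictly positive.
#' @param n_residuals Number of residuals.
#' @param p_free Number of free model parameters.
#'
#' @return Named vector `c(AIC = , BIC = )`.
#' @export
information_criteria <- function(j_min, n_residuals, p_free) {
  if (j_min <= 0) stop("degenerate likelihood: J must be strictly positive")
  if (n_residuals <= p_free) stop("need more residuals than parameters")
  base <- n_residuals * log(j_min / n_residuals)
  c(AIC = base + 2 * (p_free + 1),
    BIC = base + log(n_residuals) * (p_free + 1))
}

#' Compare calibration subsets by information criteria
#'
#' Runs one multistart per candidate free-parameter subset (fixed parameters
#' held at their values in `params`) and tabulates cost, AIC, and BIC; the
#' table is sorted by AIC (smaller is better).
#'
#' @inheritParams pv_fit
#' @param subsets List of character vectors of free-parameter names.
#'
#' @return An object of class `pv_subsets`: a data frame with one row per
#'   subset plus the fitted objects in the `"fits"` attribute.
#' @export
compare_subsets <- function(dataset, subsets, params = NULL,
                            constants = pv_constants(), n_starts = 20,
                            seed = NULL, ...) {
  stopifnot(length(subsets) >= 1, all(lengths(subsets) >= 1))
  fits <- lapply(seq_along(subsets), function(i)
    pv_fit(dataset, free = subsets[[i]], params = params,
           constants = constants, n_starts = n_starts,
           seed = if (is.null(seed)) NULL else seed + i - 1, ...))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    ic <- information_criteria(f$cost, f$n_residuals, length(f$free))
    data.frame(subset = paste(subsets[[i]], collapse = "+"),
               p_free = length(f$free), cost = f$cost,
               n_residuals = f$n_residuals,
               AIC = ic[["AIC"]], BIC = ic[["BIC"]])
  }))
  ord <- order(tab$AIC)
  tab <- tab[ord, ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[ord]
  class(tab) <- c("pv_subsets", "data.frame")
  tab
}
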