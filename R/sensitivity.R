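# Local sensitivity, influence ranking, correlation analysis, subset
# selection, and profile-likelihood identifiability.

# Central-difference Jacobian of f: R^p -> R^m with per-coordinate relative
# step. Shared by the sensitivity matrix and the UQ module.
fd_jacobian <- function(f, x, rel_step = 1e-4) {
  x <- as.numeric(x)
  p <- length(x)
  f0 <- f(x)
  J <- matrix(NA_real_, length(f0), p)
  for (i in seq_len(p)) {
    h <- rel_step * max(abs(x[i]), rel_step)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (f(xp) - f(xm)) / (2 * h)
  }
  if (any(!is.finite(J))) {
    bad <- which(colSums(!is.finite(J)) > 0)
    stop("non-finite derivative for parameter(s): ",
         paste(bad, collapse = ", "))
  }
  J
}

# Stacked model output (v_lv, p_lv, p_ao) on the dataset grid for a full
# parameter vector; used everywhere residuals or derivatives are needed.
.model_output <- function(theta_full, dataset, constants, ...) {
  beat <- simulate_to_steady_beat(as_pv_params(theta_full, constants = constants),
                                  constants, dt = 1 / dataset$sampling_rate, ...)
  c(beat$v_lv, beat$p_lv, beat$p_ao)
}

#' Tornado screening of parameter influence
#'
#' Perturbs each parameter up and down by a fraction `delta` (one at a time)
#' and reports the percent change in each summary output (extrema of LV
#' pressure, LV volume, and aortic pressure).
#'
#' @inheritParams simulate_to_steady_beat
#' @param delta Relative perturbation (default 0.10).
#'
#' @return A data frame with columns `parameter`, `output`, `up_pct`,
#'   `down_pct`, and a logical `failed` marking perturbations whose
#'   simulation did not complete.
#' @export
tornado_analysis <- function(params, constants = pv_constants(), delta = 0.10,
                             ...) {
  params <- as_pv_params(params, constants = constants)
  base <- beat_summary(simulate_to_steady_beat(params, constants, ...))
  outs <- c("p_lv_max", "p_lv_min", "v_lv_max", "v_lv_min",
            "p_ao_max", "p_ao_min")
  one_side <- function(i, sign) {
    th <- unclass(params)
    th[i] <- th[i] * (1 + sign * delta)
    out <- try(suppressWarnings(
      beat_summary(simulate_to_steady_beat(
        as_pv_params(th, constants = constants), constants, ...))),
      silent = TRUE)
    if (inherits(out, "try-error")) rep(NA_real_, length(outs))
    else 100 * (out[outs] - base[outs]) / base[outs]
  }
  rows <- lapply(seq_along(params), function(i) {
    up <- one_side(i, +1); dn <- one_side(i, -1)
    data.frame(parameter = .param_names[i], output = outs,
               up_pct = as.numeric(up), down_pct = as.numeric(dn),
               failed = !is.finite(up) | !is.finite(dn))
  })
  do.call(rbind, rows)
}

#' Local derivative-based sensitivity matrix
#'
#' Central-difference derivatives of the three model signals with respect to
#' each parameter, evaluated on the dataset grid. Entries are doubly scaled:
#' each output row is divided by the mean of the corresponding data signal
#' and each column multiplied by its parameter value, making the matrix
#' dimensionless. The unscaled derivative matrix `F` is retained for the
#' asymptotic covariance downstream.
#'
#' @inheritParams simulate_to_steady_beat
#' @param dataset A [pv_dataset()] supplying the grid and the signal means.
#' @param free Names of parameters to differentiate (default: all nine).
#' @param h Relative finite-difference step (default 1e-4).
#'
#' @return An object of class `pv_sensitivity`: list with the scaled matrix
#'   `S` (3n x p), the unscaled `F`, `signal` (block labels), `parameters`,
#'   and the evaluation point `theta`.
#' @export
local_sensitivity <- function(params, dataset, constants = pv_constants(),
                              free = .param_names, h = 1e-4, ...) {
  params <- as_pv_params(params, constants = constants)
  theta <- unclass(params)[free]
  fixed <- unclass(params)
  f <- function(x) {
    fx <- fixed; fx[free] <- x
    suppressWarnings(.model_output(fx, dataset, constants, ...))
  }
  F <- fd_jacobian(f, theta, rel_step = h)
  n <- length(dataset$time)
  ybar <- rep(c(mean(dataset$v_lv), mean(dataset$p_lv), mean(dataset$p_ao)),
              each = n)
  S <- sweep(F, 1, ybar, "/")
  S <- sweep(S, 2, theta, "*")
  colnames(S) <- colnames(F) <- free
  structure(list(S = S, F = F,
                 signal = rep(.signal_names, each = n),
                 parameters = free, theta = theta),
            class = "pv_sensitivity")
}

#' @export
print.pv_sensitivity <- function(x, ...) {
  cat(sprintf("Scaled sensitivity matrix: %d samples x %d parameters\n",
              nrow(x$S), ncol(x$S)))
  print(round(influence_ranking(x), 4))
  invisible(x)
}

#' Influence ranking by summed squared sensitivities
#'
#' Collapses the scaled sensitivity matrix to one score per parameter,
#' `sum over time and signals of S^2`, reported in descending order.
#'
#' @param sens A `pv_sensitivity` from [local_sensitivity()].
#' @return Named numeric vector of nonnegative scores, descending.
#' @export
influence_ranking <- function(sens) {
  sort(colSums(sens$S^2), decreasing = TRUE)
}

# Moore-Penrose pseudo-inverse via SVD (tolerance relative to largest
# singular value).
.pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

#' Parameter correlation matrix from local sensitivities
#'
#' Approximates the parameter covariance (up to the noise variance) by the
#' pseudo-inverse of `S'S` and converts it to a correlation matrix. Pairs
#' with |correlation| near 1 indicate locally interdependent parameters.
#'
#' @param sens A `pv_sensitivity`.
#' @return Symmetric correlation matrix with unit diagonal. A near-singular
#'   `S'S` (condition number > 1e12) is reported via the
#'   `"ill_conditioned"` attribute.
#' @export
parameter_correlation <- function(sens) {
  S <- sens$S
  if (nrow(S) < ncol(S)) stop("fewer rows than parameters in S")
  sts <- crossprod(S)
  ev <- eigen(sts, symmetric = TRUE, only.values = TRUE)$values
  C <- .pinv(sts)
  d <- sqrt(diag(C))
  corr <- C / tcrossprod(d)
  corr <- (corr + t(corr)) / 2
  diag(corr) <- 1
  dimnames(corr) <- list(sens$parameters, sens$parameters)
  attr(corr, "ill_conditioned") <- ev[1] / max(ev[length(ev)], 0) > 1e12
  corr
}

#' Select a calibration subset by influence and correlation
#'
#' Fixes (i) parameters whose influence score falls below `rank_floor` times
#' the maximum score and (ii) for each pair with |correlation| above
#' `corr_cut`, the lower-ranked member. Ties break deterministically by
#' parameter order.
#'
#' @param ranking Named scores from [influence_ranking()].
#' @param correlations Matrix from [parameter_correlation()].
#' @param rank_floor Fraction of the top score below which a parameter is
#'   deemed noninfluential (default 1e-3).
#' @param corr_cut Absolute correlation above which a pair is deemed
#'   interdependent (default 0.95).
#'
#' @return List with `free` (names kept for calibration) and `fixed`
#'   (named character vector of reasons).
#' @export
select_subset <- function(ranking, correlations, rank_floor = 1e-3,
                          corr_cut = 0.95) {
  pars <- rownames(correlations)
  stopifnot(all(names(ranking) %in% pars))
  score <- ranking[pars]
  fixed <- character(0)
  low <- pars[score < rank_floor * max(score)]
  for (p in low) fixed[p] <- "noninfluential"
  pr <- which(abs(correlations) > corr_cut & upper.tri(correlations),
              arr.ind = TRUE)
  if (nrow(pr)) {
    for (r in seq_len(nrow(pr))) {
      a <- pars[pr[r, 1]]; b <- pars[pr[r, 2]]
      drop <- if (score[a] < score[b]) a else if (score[b] < score[a]) b
              else pars[max(pr[r, ])]
      if (!drop %in% names(fixed))
        fixed[drop] <- sprintf("correlated (|r| > %.2f) with %s", corr_cut,
                               setdiff(c(a, b), drop))
    }
  }
  free <- setdiff(pars, names(fixed))
  if (!length(free)) stop("subset selection fixed every parameter")
  list(free = free, fixed = fixed)
}

#' Profile likelihood for one parameter
#'
#' Sweeps `target` over `grid`, re-optimizing all other free parameters at
#' each grid value, and classifies practical identifiability from where the
#' profiled cost crosses the threshold
#' `J_min * (1 + qchisq(1 - alpha, 1) / (n - p))` (Gaussian errors):
#' `"identifiable"` if crossed on both sides of the minimum, `"one_sided"`
#' if on one side only, `"flat"` if never.
#'
#' @param dataset A [pv_dataset()].
#' @param params Full parameter vector (e.g. the calibrated estimate).
#' @param free Free-parameter names (must include `target`).
#' @param target Name of the profiled parameter.
#' @param grid Increasing vector of values for `target`.
#' @param alpha Significance level (default 0.05).
#' @param constants A [pv_constants()].
#' @param bounds Bounds matrix as from [pv_bounds()].
#' @param ... Passed to the simulator.
#'
#' @return An object of class `pv_profile`: list with `grid`, `cost`,
#'   `threshold`, `classification`, `target`, and the reference cost
#'   `j_min`.
#' @export
profile_likelihood <- function(dataset, params, free, target, grid,
                               alpha = 0.05, constants = pv_constants(),
                               bounds = pv_bounds(constants), ...) {
  stopifnot(target %in% free)
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  others <- setdiff(free, target)
  params <- as_pv_params(params, constants = constants)
  n <- 3 * length(dataset$time)
  p <- length(free)

  start <- unclass(params)[others]
  cost <- numeric(length(grid))
  for (g in seq_along(grid)) {
    fixed <- unclass(params)
    fixed[target] <- grid[g]
    if (length(others)) {
      fit <- .lm_fit_once(start, others, fixed, dataset, constants, bounds, ...)
      cost[g] <- fit$cost
      start <- fit$theta  # warm start for the next grid point
    } else {
      cost[g] <- sum(.residuals_at(fixed, dataset, constants, ...)^2)
    }
  }
  j_min <- min(cost)
  threshold <- j_min * (1 + qchisq(1 - alpha, 1) / (n - p))
  i_min <- which.min(cost)
  crosses_left <- any(cost[seq_len(i_min)] > threshold)
  crosses_right <- any(cost[i_min:length(cost)] > threshold)
  cls <- if (crosses_left && crosses_right) "identifiable"
         else if (crosses_left || crosses_right) "one_sided" else "flat"
  est <- unclass(params)[target]
  if (est < min(grid) || est > max(grid))
    warning("profile grid does not bracket the estimate for ", target)
  structure(list(grid = grid, cost = cost, threshold = threshold,
                 classification = cls, target = target, j_min = j_min),
            class = "pv_profile")
}

#' @export
print.pv_profile <- function(x, ...) {
  cat(sprintf("Profile likelihood for %s over [%g, %g]: %s\n",
              x$target, min(x$grid), max(x$grid), x$classification))
  cat(sprintf("  min cost %.6g, threshold %.6g\n", x$j_min, x$threshold))
  invisible(x)
}

#' @export
plot.pv_profile <- function(x, ...) {
  graphics::plot(x$grid, x$cost, type = "b", xlab = x$target,
                 ylab = "profiled cost", ...)
  graphics::abline(h = x$threshold, lty = 2, col = "firebrick")
  invisible(x)
}
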