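# Uncertainty quantification: asymptotic parameter confidence intervals,
# frequentist confidence/prediction bands, Bayesian credible/prediction
# bands, and residual diagnostics.

#' Asymptotic confidence intervals from residuals and a Jacobian
#'
#' The nonlinear-regression normal approximation: with residual variance
#' `sigma2 = J / (n - p)` and covariance `sigma2 (F'F)^{-1}`, each interval
#' is `estimate +/- t_{1-alpha/2, n-p} * SE`. For a model linear in its
#' parameters this reduces exactly to the classical regression formulas.
#'
#' @param estimate Named parameter estimates (length p).
#' @param residuals Residual vector at the estimate (length n).
#' @param jacobian `n x p` derivative matrix of the model output with
#'   respect to the parameters, evaluated at the estimate.
#' @param alpha Significance level (default 0.05).
#'
#' @return Data frame with `estimate`, `se`, `lower`, `upper` per parameter;
#'   the residual variance is attached as the `"sigma2"` attribute.
#' @export
asymptotic_ci <- function(estimate, residuals, jacobian, alpha = 0.05) {
  n <- length(residuals); p <- length(estimate)
  stopifnot(nrow(jacobian) == n, ncol(jacobian) == p, n > p)
  ftf <- crossprod(jacobian)
  cv <- try(solve(ftf), silent = TRUE)
  if (inherits(cv, "try-error")) {
    corr <- abs(stats::cov2cor(.pinv(ftf)))
    diag(corr) <- 0
    worst <- which(corr == max(corr), arr.ind = TRUE)[1, ]
    stop("singular F'F: parameters ", names(estimate)[worst[1]], " and ",
         names(estimate)[worst[2]], " are not jointly identifiable")
  }
  sigma2 <- sum(residuals^2) / (n - p)
  se <- sqrt(sigma2 * diag(cv))
  tq <- qt(1 - alpha / 2, df = n - p)
  out <- data.frame(estimate = as.numeric(estimate), se = se,
                    lower = as.numeric(estimate) - tq * se,
                    upper = as.numeric(estimate) + tq * se,
                    row.names = names(estimate))
  attr(out, "sigma2") <- sigma2
  attr(out, "cov") <- sigma2 * cv
  out
}

#' Pointwise confidence and prediction bands from output gradients
#'
#' At each output point with gradient `g`, the confidence half-width is
#' `t sqrt(sigma2 g' (F'F)^{-1} g)` and the prediction half-width
#' `t sqrt(sigma2 (1 + g' (F'F)^{-1} g))`; the prediction band therefore
#' encloses the confidence band wherever the residual variance is positive.
#'
#' @param center Fitted output values (length m).
#' @param grad `m x p` gradient matrix of the outputs at the estimate.
#' @inheritParams asymptotic_ci
#'
#' @return Data frame with `center`, `ci_lo`, `ci_hi`, `pi_lo`, `pi_hi`.
#' @export
regression_bands <- function(center, residuals, jacobian, grad, alpha = 0.05) {
  n <- length(residuals); p <- ncol(jacobian)
  stopifnot(ncol(grad) == p, n > p)
  sigma2 <- sum(residuals^2) / (n - p)
  cv <- solve(crossprod(jacobian))
  q <- rowSums((grad %*% cv) * grad)   # g' (F'F)^-1 g per output point
  tq <- qt(1 - alpha / 2, df = n - p)
  hw_ci <- tq * sqrt(sigma2 * q)
  hw_pi <- tq * sqrt(sigma2 * (1 + q))
  data.frame(center = center,
             ci_lo = center - hw_ci, ci_hi = center + hw_ci,
             pi_lo = center - hw_pi, pi_hi = center + hw_pi)
}

# Jacobian of the stacked model output with respect to the free parameters
# of a fit, at its estimate (unscaled; central differences).
.fit_jacobian <- function(fit, h = 1e-4) {
  fixed <- fit$theta_full
  f <- function(x) {
    th <- fixed
    th[fit$free] <- x
    suppressWarnings(do.call(.model_output,
                             c(list(th, fit$dataset, fit$constants),
                               fit$sim_args)))
  }
  fd_jacobian(f, fit$theta_full[fit$free], rel_step = h)
}

#' @export
confint.pv_fit <- function(object, parm = object$free, level = 0.95, ...) {
  ci <- asymptotic_ci(object$coefficients, residuals(object),
                      .fit_jacobian(object), alpha = 1 - level)
  ci[parm, , drop = FALSE]
}

#' Model predictions with frequentist uncertainty bands
#'
#' @param object A `pv_fit`.
#' @param interval `"none"`, `"confidence"`, or `"prediction"`
#'   (`"prediction"` also returns the confidence band).
#' @param level Coverage level (default 0.95).
#' @param ... Unused.
#'
#' @return With `interval = "none"`, a data frame of the fitted signals on
#'   the data grid; otherwise a list of `pv_bands` objects (one per signal)
#'   with columns `time`, `center`, `ci_lo`, `ci_hi`, `pi_lo`, `pi_hi`.
#' @export
predict.pv_fit <- function(object, interval = c("none", "confidence",
                                                "prediction"),
                           level = 0.95, ...) {
  interval <- match.arg(interval)
  yhat <- fitted(object)
  n <- length(object$dataset$time)
  sig <- rep(.signal_names, each = n)
  if (interval == "none")
    return(data.frame(time = rep(object$dataset$time, 3), signal = sig,
                      fit = yhat))
  F <- .fit_jacobian(object)
  r <- residuals(object)
  bands <- regression_bands(yhat, r, F, F, alpha = 1 - level)
  out <- lapply(.signal_names, function(s) {
    b <- bands[sig == s, ]
    b <- cbind(time = object$dataset$time, b)
    rownames(b) <- NULL
    structure(b, level = level, framework = "frequentist",
              class = c("pv_bands", "data.frame"))
  })
  names(out) <- .signal_names
  out
}

#' Simulate new noisy datasets from a fitted model
#'
#' Draws `nsim` replicate datasets: the fitted signals plus iid Gaussian
#' noise with the residual variance `J / (n - p)`.
#'
#' @param object A `pv_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param ... Unused.
#'
#' @return List of [pv_dataset()] objects.
#' @export
simulate.pv_fit <- function(object, nsim = 1, seed = NULL, ...) {
  yhat <- fitted(object)
  n <- length(object$dataset$time)
  sigma <- sqrt(object$cost / (object$n_residuals - length(object$free)))
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      y <- yhat + rnorm(length(yhat), 0, sigma)
      pv_dataset(object$dataset$time, y[seq_len(n)], y[n + seq_len(n)],
                 y[2 * n + seq_len(n)],
                 sampling_rate = object$dataset$sampling_rate,
                 t_cycle = object$dataset$t_cycle)
    })
  })
}

#' @export
plot.pv_fit <- function(x, level = 0.95, ...) {
  bands <- predict(x, interval = "prediction", level = level)
  d <- x$dataset
  obs <- list(v_lv = d$v_lv, p_lv = d$p_lv, p_ao = d$p_ao)
  ylabs <- c(v_lv = "V_LV (uL)", p_lv = "P_LV (mmHg)", p_ao = "P_Ao (mmHg)")
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (s in .signal_names) {
    b <- bands[[s]]
    ylim <- range(b$pi_lo, b$pi_hi, obs[[s]])
    graphics::plot(d$time, obs[[s]], pch = 16, cex = 0.5, ylim = ylim,
                   xlab = "time (s)", ylab = ylabs[[s]], main = s)
    graphics::polygon(c(b$time, rev(b$time)), c(b$pi_lo, rev(b$pi_hi)),
                      col = grDevices::adjustcolor("steelblue", 0.2),
                      border = NA)
    graphics::polygon(c(b$time, rev(b$time)), c(b$ci_lo, rev(b$ci_hi)),
                      col = grDevices::adjustcolor("steelblue", 0.4),
                      border = NA)
    graphics::lines(b$time, b$center, col = "firebrick")
  }
  invisible(x)
}

#' Bayesian credible and prediction bands for the model outputs
#'
#' Thins the post-burn-in chain uniformly to `n_draws` joint draws of
#' (parameters, noise variance), simulates each, and takes pointwise
#' percentiles: the credible band from the simulations, the prediction band
#' after adding Gaussian noise with each draw's variance. The center curve
#' is the simulation at the highest-posterior sample.
#'
#' @param chain A `pv_mcmc`.
#' @param n_draws Number of posterior draws (default 2000).
#' @param level Coverage level (default 0.95).
#' @param seed Optional seed for the prediction-noise draws.
#'
#' @return Named list of `pv_bands` data frames (one per signal), with the
#'   number of failed simulations in the `"n_failed"` attribute.
#' @export
bayesian_output_bands <- function(chain, n_draws = 2000, level = 0.95,
                                  seed = NULL) {
  stopifnot(inherits(chain, "pv_mcmc"))
  keep <- seq.int(chain$burn_in + 1L, nrow(chain$samples))
  if (length(keep) < 2) stop("chain shorter than burn-in")
  n_draws <- min(n_draws, length(keep))
  idx <- keep[unique(round(seq(1, length(keep), length.out = n_draws)))]
  n <- length(chain$dataset$time)

  sims <- matrix(NA_real_, length(idx), 3 * n)
  for (j in seq_along(idx)) {
    th <- chain$theta_full
    th[chain$free] <- chain$samples[idx[j], ]
    y <- try(suppressWarnings(do.call(
      .model_output, c(list(th, chain$dataset, chain$constants),
                       chain$sim_args))), silent = TRUE)
    if (!inherits(y, "try-error")) sims[j, ] <- y
  }
  ok <- stats::complete.cases(sims)
  n_failed <- sum(!ok)
  sims <- sims[ok, , drop = FALSE]
  sig2 <- chain$sigma2[idx][ok]

  # center: simulation at the sample with highest (stored) log posterior,
  # approximated by the lowest-cost draw among those simulated
  rss <- vapply(seq_len(nrow(sims)), function(j) {
    sum((c(chain$dataset$v_lv, chain$dataset$p_lv, chain$dataset$p_ao)
         - sims[j, ])^2)
  }, 0)
  center <- sims[which.min(rss), ]

  pred <- with_seed(seed,
    sims + matrix(rnorm(length(sims), 0, sqrt(sig2)), nrow(sims)))
  a <- (1 - level) / 2
  qs <- function(m) apply(m, 2, quantile, probs = c(a, 1 - a))
  cr <- qs(sims); pr <- qs(pred)

  out <- lapply(seq_along(.signal_names), function(k) {
    cols <- (k - 1) * n + seq_len(n)
    b <- data.frame(time = chain$dataset$time, center = center[cols],
                    ci_lo = pmin(cr[1, cols], center[cols]),
                    ci_hi = pmax(cr[2, cols], center[cols]),
                    pi_lo = pr[1, cols], pi_hi = pr[2, cols])
    b$pi_lo <- pmin(b$pi_lo, b$ci_lo)
    b$pi_hi <- pmax(b$pi_hi, b$ci_hi)
    structure(b, level = level, framework = "bayesian",
              n_failed = n_failed, class = c("pv_bands", "data.frame"))
  })
  names(out) <- .signal_names
  out
}

#' Residual diagnostics against the iid assumption
#'
#' Per signal: lag-1 autocorrelation of the residuals, the slope of squared
#' residuals regressed on time (variance trend), and normal-quantile pairs
#' for QQ plotting. The verdict flags the residuals as non-iid when the
#' lag-1 autocorrelation exceeds `2 / sqrt(n)` in magnitude (correlated
#' errors) or the variance-trend slope is significantly nonzero at the 5%
#' level (heteroskedastic errors).
#'
#' @param theta Named parameter values at which residuals are computed.
#' @inheritParams pv_residuals
#'
#' @return An object of class `pv_diagnostics`: per-signal list with
#'   `residuals`, `lag1`, `trend_slope`, `trend_p`, `qq` (data frame), and
#'   flags, plus an overall `verdict` (`"iid"` or `"non-iid"`).
#' @export
residual_diagnostics <- function(theta, dataset, params = pv_params(),
                                 constants = pv_constants(), ...) {
  r_all <- pv_residuals(theta, dataset, params, constants, ...)
  n <- length(dataset$time)
  per <- lapply(seq_along(.signal_names), function(k) {
    r <- r_all[(k - 1) * n + seq_len(n)]
    .diagnose_residuals(r, dataset$time)
  })
  names(per) <- .signal_names
  noniid <- any(vapply(per, function(d) d$correlated || d$heteroskedastic,
                       TRUE))
  structure(list(signals = per,
                 verdict = if (noniid) "non-iid" else "iid"),
            class = "pv_diagnostics")
}

# Core diagnostic on one residual series over abscissa x; exported through
# residual_diagnostics() and reused by the noise-testbed checks.
.diagnose_residuals <- function(r, x) {
  n <- length(r)
  lag1 <- if (var(r) == 0) 0 else acf(r, lag.max = 1, plot = FALSE)$acf[2]
  tr <- lm(I(r^2) ~ x)
  sm <- summary(tr)$coefficients
  slope <- sm["x", "Estimate"]
  p_val <- sm["x", "Pr(>|t|)"]
  qq <- stats::qqnorm(r, plot.it = FALSE)
  list(residuals = r, lag1 = lag1, trend_slope = slope, trend_p = p_val,
       qq = data.frame(theoretical = qq$x, sample = qq$y),
       correlated = abs(lag1) > 2 / sqrt(n),
       heteroskedastic = p_val < 0.05)
}

#' Classify a residual series as iid, heteroskedastic, or correlated
#'
#' Convenience wrapper around the diagnostic rules for a single residual
#' series (e.g. from the quadratic [noise_testbed()]): `"correlated"` if the
#' lag-1 autocorrelation exceeds `2/sqrt(n)`, else `"heteroskedastic"` if
#' the variance-trend slope is significant at 5%, else `"iid"`.
#'
#' @param residuals Residual vector.
#' @param x Abscissa (time or location) of each residual.
#'
#' @return Character verdict.
#' @export
classify_residuals <- function(residuals, x) {
  d <- .diagnose_residuals(residuals, x)
  if (d$correlated) "correlated"
  else if (d$heteroskedastic) "heteroskedastic"
  else "iid"
}

#' @export
print.pv_diagnostics <- function(x, ...) {
  cat("Residual diagnostics (verdict:", x$verdict, ")\n")
  for (s in names(x$signals)) {
    d <- x$signals[[s]]
    cat(sprintf("  %s: lag1 = %+.3f%s, var-trend p = %.3g%s\n", s, d$lag1,
                if (d$correlated) " [correlated]" else "",
                d$trend_p,
                if (d$heteroskedastic) " [heteroskedastic]" else ""))
  }
  invisible(x)
}
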