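# Bayesian calibration: Gaussian likelihood, box-uniform priors, adaptive
# Metropolis with conjugate inverse-gamma refresh of the noise variance,
# posterior summaries, and chain diagnostics.

#' Gaussian log-likelihood of the PV data
#'
#' Single shared noise variance across the three stacked signals:
#' `-(n/2) log(2 pi sigma2) - J(theta) / (2 sigma2)`.
#'
#' @inheritParams pv_residuals
#' @param sigma2 Noise variance (signal units squared), strictly positive.
#'
#' @return Log-likelihood; `-Inf` if the simulation fails.
#' @export
pv_log_likelihood <- function(theta, sigma2, dataset, params = pv_params(),
                              constants = pv_constants(), ...) {
  if (sigma2 <= 0) stop("sigma2 must be strictly positive")
  r <- try(suppressWarnings(
    pv_residuals(theta, dataset, params, constants, ...)), silent = TRUE)
  if (inherits(r, "try-error")) return(-Inf)
  n <- length(r)
  -n / 2 * log(2 * pi * sigma2) - sum(r^2) / (2 * sigma2)
}

#' Box-uniform log-prior
#'
#' Constant `-sum(log(width))` inside the box (boundary included), `-Inf`
#' outside.
#'
#' @param theta Named parameter vector.
#' @param priors Bounds matrix (rows `lower`, `upper`) over the free
#'   parameters, as from [pv_bounds()].
#'
#' @return Log-prior density.
#' @export
pv_log_prior <- function(theta, priors) {
  nm <- names(theta)
  lo <- priors["lower", nm]; hi <- priors["upper", nm]
  if (any(theta < lo | theta > hi)) return(-Inf)
  -sum(log(hi - lo))
}

# Recursive sample covariance (unbiased, Welford) used by both samplers.
.running_cov <- function() {
  env <- new.env(parent = emptyenv())
  env$n <- 0L; env$mean <- NULL; env$M2 <- NULL
  list(
    push = function(x) {
      if (env$n == 0L) {
        env$mean <- x
        env$M2 <- matrix(0, length(x), length(x))
      } else {
        d <- x - env$mean
        env$mean <- env$mean + d / (env$n + 1L)
        env$M2 <- env$M2 + tcrossprod(d, x - env$mean)
      }
      env$n <- env$n + 1L
    },
    cov = function() if (env$n > 1L) env$M2 / (env$n - 1L) else NULL,
    n = function() env$n)
}

# Shared adaptive-Metropolis proposal machinery: returns a sampler closure
# over a generic log-target. Proposal covariance after adapt_start is
# s_d * (empirical covariance + epsilon I), s_d = 2.4^2 / p (Haario-style).
.am_chol <- function(cov, epsilon, p) {
  s_d <- 2.4^2 / p
  chol(s_d * (cov + diag(epsilon, p)))
}

#' Adaptive Metropolis sampler for a generic log-target
#'
#' Gaussian random-walk Metropolis whose proposal covariance is adapted from
#' the chain history: after `adapt_start` iterations the proposal is
#' `N(theta, s_d (Cov + epsilon I))` with `s_d = 2.4^2 / p`, refreshed every
#' `adapt_interval` iterations. Used directly for validation against
#' analytic targets; [pv_mcmc()] embeds the same scheme with a conjugate
#' noise-variance update.
#'
#' @param log_target Function `theta -> log density` (up to a constant).
#' @param init Named numeric starting point.
#' @param n_iter Number of iterations.
#' @param seed Integer seed.
#' @param adapt_start Iteration at which adaptation begins (default 1000).
#' @param adapt_interval Iterations between covariance refreshes (default 1).
#' @param epsilon Covariance regularization (default 1e-10).
#' @param init_sd Initial proposal standard deviations (default: 10% of
#'   `abs(init)`, floored at 1e-3).
#'
#' @return List with `samples` (n_iter x p), `log_post`, `accepted`
#'   (logical), and `acceptance_rate`.
#' @export
am_sampler <- function(log_target, init, n_iter, seed = NULL,
                       adapt_start = 1000, adapt_interval = 1,
                       epsilon = 1e-10, init_sd = NULL) {
  p <- length(init)
  if (is.null(init_sd)) init_sd <- pmax(0.1 * abs(init), 1e-3)
  with_seed(seed, {
    samples <- matrix(NA_real_, n_iter, p,
                      dimnames = list(NULL, names(init)))
    lp <- numeric(n_iter)
    accepted <- logical(n_iter)
    theta <- as.numeric(init)
    lp_cur <- log_target(theta)
    if (!is.finite(lp_cur)) stop("log_target not finite at init")
    run <- .running_cov()
    run$push(theta)
    R <- diag(init_sd, p)   # upper-triangular proposal factor
    for (i in seq_len(n_iter)) {
      if (i > adapt_start && (i %% adapt_interval == 0)) {
        cv <- run$cov()
        if (!is.null(cv)) {
          Rn <- try(.am_chol(cv, epsilon, p), silent = TRUE)
          if (!inherits(Rn, "try-error")) R <- Rn
        }
      }
      prop <- theta + drop(rnorm(p) %*% R)
      lp_prop <- log_target(prop)
      if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
        theta <- prop; lp_cur <- lp_prop; accepted[i] <- TRUE
      }
      samples[i, ] <- theta
      lp[i] <- lp_cur
      run$push(theta)
    }
    list(samples = samples, log_post = lp, accepted = accepted,
         acceptance_rate = mean(accepted))
  })
}

#' Adaptive Metropolis calibration of the LV-aorta model
#'
#' Samples the posterior of the free parameters under box-uniform priors and
#' a Gaussian likelihood with one shared noise variance. The variance is
#' refreshed each iteration from its conditional inverse-gamma distribution
#' given the current residual sum of squares (conjugate update with a weak
#' hyperprior anchored at the initial fit's mean squared residual); the
#' parameters move by adaptive Gaussian random-walk Metropolis.
#'
#' @param dataset A [pv_dataset()].
#' @param free Free-parameter names (default: the seven-parameter subset).
#' @param params Full parameter vector for fixed entries and as the chain
#'   start (clipped to the prior box); default: a priori values from the
#'   data.
#' @param constants A [pv_constants()].
#' @param priors Bounds matrix over the free parameters ([pv_bounds()]).
#' @param n_iter Number of iterations (default 100000; reduce for tests).
#' @param seed Integer seed.
#' @param adapt_start,adapt_interval,epsilon Adaptation settings as in
#'   [am_sampler()].
#' @param burn_in Fraction of the chain discarded by downstream summaries
#'   (stored, default 0.2).
#' @param n0 Prior weight (pseudo-observations) of the variance hyperprior.
#' @param s2_anchor Scale anchor of the variance hyperprior. By default it
#'   is the mean squared residual of a single bounded least-squares
#'   refinement from the starting point, so the prior is centered on a
#'   realistic noise level rather than on the misfit of the raw start.
#' @param ... Passed to the simulator.
#'
#' @return An object of class `pv_mcmc`: `samples` (n_iter x p), `sigma2`,
#'   `accepted`, `acceptance_rate`, `burn_in` (index), plus bookkeeping.
#' @export
pv_mcmc <- function(dataset, free = setdiff(.param_names, c("r_av", "v_lv_d")),
                    params = NULL, constants = pv_constants(),
                    priors = pv_bounds(constants), n_iter = 100000,
                    seed = NULL, adapt_start = 1000, adapt_interval = 1,
                    epsilon = 1e-10, burn_in = 0.2, n0 = 1,
                    s2_anchor = NULL, ...) {
  if (is.null(params)) params <- apriori_parameters(dataset, constants)
  fixed_full <- unclass(as_pv_params(params, constants = constants))
  lo <- priors["lower", free]; hi <- priors["upper", free]
  theta <- pmin(pmax(fixed_full[free], lo), hi)
  n <- 3 * length(dataset$time)

  cost_of <- function(th) {
    full <- fixed_full
    full[free] <- th
    sum(.residuals_at(full, dataset, constants, ...)^2)
  }

  j_cur <- suppressWarnings(cost_of(theta))
  if (is.null(s2_anchor)) {
    warm <- .lm_fit_once(theta, free, fixed_full, dataset, constants,
                         priors, ...)
    s2_anchor <- min(warm$cost, j_cur) / n
  }
  a0 <- 0.5 * n0
  b0 <- 0.5 * n0 * s2_anchor
  log_post <- function(j, s2) {
    -n / 2 * log(2 * pi * s2) - j / (2 * s2) - sum(log(hi - lo))
  }

  with_seed(seed, {
    p <- length(free)
    samples <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, free))
    sigma2 <- numeric(n_iter)
    accepted <- logical(n_iter)
    run <- .running_cov()
    run$push(theta)
    R <- diag(0.01 * (hi - lo), p)  # initial proposal sd: 1% of prior width
    s2 <- s2_anchor
    for (i in seq_len(n_iter)) {
      # conjugate refresh of the noise variance given current residuals
      s2 <- 1 / rgamma(1, shape = a0 + n / 2, rate = b0 + j_cur / 2)
      lp_cur <- log_post(j_cur, s2)
      if (i > adapt_start && (i %% adapt_interval == 0)) {
        cv <- run$cov()
        if (!is.null(cv)) {
          Rn <- try(.am_chol(cv, epsilon, p), silent = TRUE)
          if (!inherits(Rn, "try-error")) R <- Rn
        }
      }
      prop <- theta + drop(rnorm(p) %*% R)
      if (all(prop >= lo & prop <= hi)) {
        j_prop <- suppressWarnings(cost_of(prop))
        lp_prop <- log_post(j_prop, s2)
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
          theta <- prop; j_cur <- j_prop; accepted[i] <- TRUE
        }
      }
      samples[i, ] <- theta
      sigma2[i] <- s2
      run$push(theta)
    }
    acc <- mean(accepted[-seq_len(min(adapt_start, n_iter))])
    if (!is.na(acc) && acc == 0)
      warning("zero acceptance after adaptation; proposal scale ",
              signif(max(diag(R)), 3))
    structure(list(samples = samples, sigma2 = sigma2, accepted = accepted,
                   acceptance_rate = mean(accepted),
                   burn_in = floor(burn_in * n_iter),
                   free = free, theta_full = fixed_full,
                   dataset = dataset, constants = constants,
                   priors = priors[, free, drop = FALSE], seed = seed,
                   n_residuals = n,
                   adaptation = list(adapt_start = adapt_start,
                                     adapt_interval = adapt_interval,
                                     epsilon = epsilon),
                   sim_args = list(...)), class = "pv_mcmc")
  })
}

#' @export
print.pv_mcmc <- function(x, ...) {
  cat(sprintf("Adaptive Metropolis chain: %d iterations, %d parameters\n",
              nrow(x$samples), length(x$free)))
  cat(sprintf("  acceptance rate %.2f, burn-in %d\n", x$acceptance_rate,
              x$burn_in))
  invisible(x)
}

#' @export
summary.pv_mcmc <- function(object, ...) posterior_summary(object, ...)

# Kernel-density mode of a sample (Silverman bandwidth).
.kde_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1])
  d <- density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Posterior summaries of an MCMC chain
#'
#' Per-parameter (and noise variance) mean, median, kernel-density mode,
#' standard deviation, and central credible interval after burn-in removal.
#'
#' @param chain A `pv_mcmc`.
#' @param burn_in Fraction discarded (default: as stored in the chain).
#' @param level Credible level (default 0.95).
#'
#' @return Data frame with one row per parameter plus `sigma2`.
#' @export
posterior_summary <- function(chain, burn_in = NULL, level = 0.95) {
  stopifnot(inherits(chain, "pv_mcmc"))
  nb <- if (is.null(burn_in)) chain$burn_in
        else floor(burn_in * nrow(chain$samples))
  if (nb >= nrow(chain$samples)) stop("burn-in longer than the chain")
  keep <- seq.int(nb + 1L, nrow(chain$samples))
  draws <- cbind(chain$samples[keep, , drop = FALSE],
                 sigma2 = chain$sigma2[keep])
  a <- (1 - level) / 2
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    median = apply(draws, 2, median),
    mode = apply(draws, 2, .kde_mode),
    sd = apply(draws, 2, sd),
    lower = apply(draws, 2, quantile, probs = a),
    upper = apply(draws, 2, quantile, probs = 1 - a),
    row.names = NULL)
  attr(out, "level") <- level
  out
}

# Effective sample size via the autocorrelation sum, truncated at the first
# nonpositive estimate (initial positive sequence).
.ess <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 10 * floor(sqrt(n))), plot = FALSE,
             demean = TRUE)$acf[-1]
  s <- 0
  for (r in rho) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Chain diagnostics
#'
#' Acceptance rate, per-parameter lag-1 autocorrelation, and effective
#' sample size (autocorrelation-sum estimator) after burn-in removal.
#'
#' @param chain A `pv_mcmc`, or a numeric matrix of samples.
#' @param burn_in Fraction discarded (chains only).
#'
#' @return List with `acceptance_rate`, `lag1`, `ess`.
#' @export
chain_diagnostics <- function(chain, burn_in = NULL) {
  if (inherits(chain, "pv_mcmc")) {
    nb <- if (is.null(burn_in)) chain$burn_in
          else floor(burn_in * nrow(chain$samples))
    m <- chain$samples[seq.int(nb + 1L, nrow(chain$samples)), , drop = FALSE]
    acc <- chain$acceptance_rate
  } else {
    m <- as.matrix(chain)
    acc <- NA_real_
  }
  lag1 <- apply(m, 2, function(x) {
    if (var(x) == 0) return(0)
    acf(x, lag.max = 1, plot = FALSE)$acf[2]
  })
  list(acceptance_rate = acc, lag1 = lag1, ess = apply(m, 2, .ess))
}

#' @export
plot.pv_mcmc <- function(x, ...) {
  keep <- seq.int(x$burn_in + 1L, nrow(x$samples))
  p <- length(x$free)
  op <- graphics::par(mfrow = c(ceiling(p / 3), 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in x$free) {
    d <- density(x$samples[keep, nm])
    graphics::plot(d, main = nm, xlab = nm)
  }
  invisible(x)
}
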