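# Configuration-driven workflow driver: simulate -> sensitivity -> subset ->
# fit -> mcmc -> uq, with seed control, per-stage artifacts, and a run log.

.default_config <- function() {
  list(
    data = NULL,                 # path to a PV CSV; NULL => synthetic
    synthetic = list(noise = "iid", sigma = 2, gamma = 5, rho = 0.8),
    constants = list(p_la = 5, p_cap = 20, t_cycle = 0.11),
    sampling_rate = 500,
    parameters = list(),         # a priori overrides by name
    ranges = list(),             # bound overrides: name -> c(lower, upper)
    stages = list(simulate = TRUE, sensitivity = TRUE, subset = TRUE,
                  fit = TRUE, mcmc = TRUE, uq = TRUE),
    profile = "test",            # "test" (10 starts, 5000 iters) or "paper"
    n_starts = NULL, n_iter = NULL,
    seed = 1,
    out_dir = "cardiofit_run")
}

#' Load and validate a workflow configuration
#'
#' JSON configuration with defaults filled in: circuit constants (5/20 mmHg,
#' 0.11 s), 500 Hz sampling, default parameter ranges, all stages enabled,
#' and the reduced `"test"` profile (10 optimization starts, 5000 MCMC
#' iterations; the `"paper"` profile uses 100 and 100000).
#'
#' @param path Path to a JSON file, or `NULL` for pure defaults.
#'
#' @return A validated config list of class `pv_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  if (!is.null(cfg$data) && !file.exists(cfg$data))
    stop("data file not found: ", cfg$data)
  if (!cfg$profile %in% c("test", "paper"))
    stop("profile must be 'test' or 'paper'")
  if (is.null(cfg$n_starts))
    cfg$n_starts <- if (cfg$profile == "paper") 100 else 10
  if (is.null(cfg$n_iter))
    cfg$n_iter <- if (cfg$profile == "paper") 100000 else 5000
  cfg$seed <- as.integer(cfg$seed)
  for (nm in names(cfg$ranges)) {
    rg <- as.numeric(cfg$ranges[[nm]])
    if (!nm %in% .param_names)
      stop("range given for unknown parameter: ", nm)
    if (length(rg) != 2 || !(rg[1] < rg[2]))
      stop("range for ", nm, " must satisfy lower < upper")
  }
  structure(cfg, class = "pv_config")
}

#' Save a workflow configuration
#'
#' @param config A `pv_config`.
#' @param path Output JSON path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full analysis workflow
#'
#' Executes the enabled stages in order — data (load or synthesize),
#' simulate, sensitivity (+ correlation), subset selection, multistart fit
#' (+ AIC), adaptive Metropolis, and uncertainty quantification — writing
#' each stage's artifact (CSV/JSON) to the configured output directory
#' together with a provenance record (seed, package version, timestamps,
#' config). A stage failure stops the run with the stage named; artifacts
#' of completed stages are preserved.
#'
#' @param config A `pv_config` from [load_config()].
#'
#' @return Invisibly, a list of stage results (`data`, `beat`, `sensitivity`,
#'   `subset`, `fit`, `mcmc`, `uq`, `provenance`).
#' @export
run_workflow <- function(config = load_config()) {
  stopifnot(inherits(config, "pv_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$out_dir, "run.log"), open = "at")
  on.exit(close(log_con))
  results <- list()
  stage <- function(name, enabled, expr) {
    if (!enabled) return(NULL)
    .log_line(log_con, "stage ", name, " start")
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    .log_line(log_con, "stage ", name, " done")
    out
  }

  constants <- do.call(pv_constants, config$constants)
  apriori <- as_pv_params(unlist(config$parameters), constants = constants)
  bounds <- pv_bounds(constants)
  for (nm in names(config$ranges))
    bounds[, nm] <- as.numeric(config$ranges[[nm]])

  results$data <- stage("data", TRUE, {
    if (!is.null(config$data)) {
      read_pv_csv(config$data)
    } else {
      ns <- noise_spec(config$synthetic$noise, sigma = config$synthetic$sigma,
                       gamma = config$synthetic$gamma,
                       rho = config$synthetic$rho, seed = config$seed)
      d <- synthesize_dataset(apriori, constants, noise = ns,
                              sampling_rate = config$sampling_rate)
      write_pv_csv(d, file.path(config$out_dir, "dataset.csv"))
      d
    }
  })
  dataset <- results$data
  apriori <- apriori_parameters(dataset, constants)

  results$beat <- stage("simulate", isTRUE(config$stages$simulate), {
    beat <- simulate_to_steady_beat(apriori, constants,
                                    dt = 1 / config$sampling_rate)
    write_beat_csv(beat, file.path(config$out_dir, "beat.csv"))
    beat
  })

  results$sensitivity <- stage("sensitivity", isTRUE(config$stages$sensitivity), {
    sens <- local_sensitivity(apriori, dataset, constants)
    rk <- influence_ranking(sens)
    corr <- parameter_correlation(sens)
    write.csv(data.frame(parameter = names(rk), score = as.numeric(rk)),
              file.path(config$out_dir, "ranking.csv"), row.names = FALSE)
    write.csv(corr, file.path(config$out_dir, "correlation.csv"))
    list(sens = sens, ranking = rk, correlation = corr)
  })

  results$subset <- stage("subset", isTRUE(config$stages$subset), {
    sel <- if (!is.null(results$sensitivity))
      select_subset(results$sensitivity$ranking,
                    results$sensitivity$correlation)
    else list(free = setdiff(.param_names, c("r_av", "v_lv_d")),
              fixed = c(r_av = "default", v_lv_d = "default"))
    jsonlite::write_json(sel, file.path(config$out_dir, "subset.json"),
                         auto_unbox = TRUE)
    sel
  })
  free <- results$subset$free %||% setdiff(.param_names, c("r_av", "v_lv_d"))

  results$fit <- stage("fit", isTRUE(config$stages$fit), {
    fit <- pv_fit(dataset, free = free, params = apriori,
                  constants = constants, bounds = bounds,
                  n_starts = config$n_starts, seed = config$seed)
    ci <- confint(fit)
    ic <- information_criteria(fit$cost, fit$n_residuals, length(fit$free))
    jsonlite::write_json(list(
      estimates = as.list(coef(fit)), cost = fit$cost,
      cov_top_k = as.list(top_k_cov(fit, k = min(20, fit$n_starts))),
      ci = cbind(parameter = rownames(ci), ci),
      AIC = ic[["AIC"]], BIC = ic[["BIC"]]),
      file.path(config$out_dir, "fit.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    fit
  })

  results$mcmc <- stage("mcmc", isTRUE(config$stages$mcmc), {
    start <- if (!is.null(results$fit)) {
      th <- apriori; th[results$fit$free] <- coef(results$fit)
      as_pv_params(th, constants = constants)
    } else apriori
    chain <- pv_mcmc(dataset, free = free, params = start,
                     constants = constants, priors = bounds,
                     n_iter = config$n_iter, seed = config$seed)
    write.csv(cbind(as.data.frame(chain$samples), sigma2 = chain$sigma2,
                    accepted = chain$accepted),
              file.path(config$out_dir, "chain.csv"), row.names = FALSE)
    write.csv(posterior_summary(chain),
              file.path(config$out_dir, "posterior.csv"), row.names = FALSE)
    chain
  })

  results$uq <- stage("uq", isTRUE(config$stages$uq), {
    out <- list()
    if (!is.null(results$fit)) {
      out$frequentist <- predict(results$fit, interval = "prediction")
      for (s in names(out$frequentist))
        write.csv(out$frequentist[[s]],
                  file.path(config$out_dir, paste0("bands_freq_", s, ".csv")),
                  row.names = FALSE)
      diag <- residual_diagnostics(coef(results$fit), dataset,
                                   params = apriori, constants = constants)
      jsonlite::write_json(
        list(verdict = diag$verdict,
             lag1 = lapply(diag$signals, `[[`, "lag1"),
             trend_p = lapply(diag$signals, `[[`, "trend_p")),
        file.path(config$out_dir, "diagnostics.json"), auto_unbox = TRUE,
        digits = NA)
      out$diagnostics <- diag
    }
    if (!is.null(results$mcmc)) {
      out$bayesian <- bayesian_output_bands(
        results$mcmc, n_draws = min(2000, config$n_iter %/% 2),
        seed = config$seed)
      for (s in names(out$bayesian))
        write.csv(out$bayesian[[s]],
                  file.path(config$out_dir, paste0("bands_bayes_", s, ".csv")),
                  row.names = FALSE)
    }
    out
  })

  results$provenance <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cardiofit")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = unclass(config))
  jsonlite::write_json(results$provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .log_line(log_con, "workflow complete")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
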