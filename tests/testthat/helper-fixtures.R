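# Shared fixtures: the mouse-like truth, cached noiseless/noisy datasets, and
# a cached quick calibration. Built once per test run.

mouse_truth <- pv_params()
mouse_free7 <- setdiff(names(mouse_truth), c("r_av", "v_lv_d"))

noiseless_mouse <- function() {
  if (is.null(.fixture_env$noiseless))
    .fixture_env$noiseless <- synthesize_dataset(
      mouse_truth, noise = noise_spec("iid", sigma = 0, seed = 1))
  .fixture_env$noiseless
}

noisy_mouse <- function() {
  if (is.null(.fixture_env$noisy))
    .fixture_env$noisy <- synthesize_dataset(
      mouse_truth, noise = noise_spec("iid", sigma = 2, seed = 7))
  .fixture_env$noisy
}

# Single-start calibration of the noisy fixture, started from the truth:
# enough for CI / band / diagnostic tests that need a converged estimate.
quick_fit <- function() {
  if (is.null(.fixture_env$fit))
    .fixture_env$fit <- pv_fit(noisy_mouse(), free = mouse_free7,
                               params = mouse_truth, n_starts = 1, seed = 1)
  .fixture_env$fit
}

.fixture_env <- new.env()
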