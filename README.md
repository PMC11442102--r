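# cardiofit

Calibration and uncertainty quantification for a lumped-parameter model of
the left ventricle and aorta.

## The problem

Dynamic pressure–volume (PV) measurements — left-ventricular (LV) volume,
LV pressure, and aortic pressure sampled over a cardiac cycle — are the
standard readout of systolic and diastolic function in small-animal
hemodynamics. A mechanistic circuit model can turn these signals into
interpretable physiological parameters (valve resistances, chamber
elastances, arterial compliance), but doing that credibly requires an
analysis pipeline, not just an ODE solver: which parameters does the data
actually inform, how do we calibrate them, and how uncertain are the
estimates and the predictions?

`cardiofit` implements that full pipeline for a compact LV–aorta model and
lets every step be exercised end-to-end on synthetic data with known ground
truth. It is aimed at cardiovascular modelers and at anyone who wants a
worked, testable example of sensitivity analysis, identifiability
assessment, frequentist and Bayesian calibration, and uncertainty
quantification for a nonlinear ODE model.

## The model

The LV is a time-varying elastance chamber,

    P_LV(t) = E(t) (V_LV(t) − V_LV,d),

where E(t) rises from the diastolic elastance E_ed to its systolic peak
E_es at time T_s along a cosine ramp, relaxes back to E_ed at T_e, and
stays diastolic for the rest of the fixed 0.11 s cycle. The mitral and
aortic valves are resistive diodes, Q = max(ΔP/R, 0); the aorta is a single
compliant compartment C_ao drained through the arterial resistance R_art
into a constant capillary pressure, and filling is driven by a constant
left-atrial pressure. The state (V_LV, P_Ao) evolves by

    dV_LV/dt = Q_mv − Q_av,
    dP_Ao/dt = (Q_av − Q_sys) / C_ao,

integrated with an adaptive Runge–Kutta scheme beat-by-beat until the beat
is periodic. The nine inferable parameters are

    θ = {R_mv, R_av, R_art, E_es, E_ed, T_s, T_e, V_LV,d, C_ao}.

Calibration minimizes the unweighted least-squares cost stacking the three
signals, J(θ) = Σ (data − model)², from many random starts; Bayesian
calibration samples the posterior under box-uniform priors with an adaptive
Metropolis sampler and a conjugate update for the noise variance.

## Worked example

```r
library(cardiofit)

# simulate the mouse-like a priori parameter set to its periodic beat
beat <- simulate_to_steady_beat(pv_params())
beat
#> Periodic beat: 55 grid points over 0.11 s (converged in 26 beats, metric 7.2e-07)
#>       p_lv_max       p_lv_min       v_lv_max       v_lv_min       p_ao_max
#>         61.048          2.172         32.057         17.488         60.880
#>       p_ao_min      p_ao_mean  stroke_volume cardiac_output
#>         49.384         55.494         14.569        132.449

# a synthetic single-beat dataset: truth + iid Gaussian noise (sd 2)
d <- synthesize_dataset(pv_params(),
                        noise = noise_spec("iid", sigma = 2, seed = 42))

# multistart calibration of the seven-parameter subset
fit <- pv_fit(d, n_starts = 20, seed = 1)
fit
#> Multistart LV-aorta calibration (20 starts, 7 free parameters)
#>   best cost J = 607.633 over n = 165 residuals
#>   estimates:
#>     r_mv    r_art     e_es     e_ed      t_s      t_e     c_ao
#> 0.005222 0.244200 4.903000 0.130900 0.044190 0.077720 1.050000

confint(fit)
#>       estimate       se   lower   upper
#> r_mv   0.00522 0.000738 0.00376 0.00668
#> r_art  0.24418 0.009071 0.22626 0.26209
#> e_es   4.90278 0.124518 4.65684 5.14871
#> e_ed   0.13086 0.014079 0.10305 0.15867
#> t_s    0.04419 0.000641 0.04292 0.04545
#> t_e    0.07772 0.000643 0.07645 0.07899
#> c_ao   1.04991 0.079363 0.89317 1.20666
```

Every generating value (R_mv = 5e-3, R_art = 0.268, E_es = 4.85,
E_ed = 0.146, T_s = 0.044, T_e = 0.077, C_ao = 0.968) is recovered to
within a couple of standard errors; the timing parameters are resolved to
1–3% of their values while R_mv, with its weak leverage on the signals, is
an order of magnitude less certain — the asymmetry the uncertainty analysis
is designed to expose.

```r
# Bayesian calibration from the frequentist optimum
chain <- pv_mcmc(d, params = fit$theta_full, n_iter = 5000, seed = 1)
posterior_summary(chain)   # means, modes, 95% credible intervals
predict(fit, interval = "prediction")   # frequentist CI/PI bands per signal
bayesian_output_bands(chain)            # credible/prediction bands
```

The marginal posterior modes fall inside the frequentist confidence
intervals (e.g. E_es mode 4.92 vs CI [4.66, 5.15]), the sampler accepts
about 30% of proposals after adaptation, and the noise variance posterior
(mean 3.9) brackets the generating σ² = 4.

Sensitivity screening, subset selection, and identifiability live in
`tornado_analysis()`, `local_sensitivity()`, `influence_ranking()`,
`parameter_correlation()`, `select_subset()`, and `profile_likelihood()`;
`run_workflow()` chains all stages from a JSON configuration, and
`inst/cli/cardiofit` exposes the same pipeline from a shell.

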