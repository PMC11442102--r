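---
title: "Methods: simulation, calibration, and uncertainty quantification of the LV–aorta model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, calibration, and uncertainty quantification of the LV-aorta model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiofit)
```

`cardiofit` packages a complete analysis pipeline for dynamic
pressure–volume (PV) data around a deliberately compact mechanistic model.
This vignette is the package's own account of the science: the model and
its assumptions, the statistical machinery, the numerical choices, and what
the synthetic-data tests do and do not demonstrate.

## The circuit model

The left ventricle (LV) is a time-varying elastance chamber: pressure is
proportional to the volume above the unstressed ("dead") volume,

$$P_\mathrm{LV}(t) = E(t)\,\bigl(V_\mathrm{LV}(t) - V_{\mathrm{LV},d}\bigr).$$

The elastance follows a two-piece cosine ramp over the cycle of length
$T_c$: it starts at the diastolic value $E_{ed}$, rises to the systolic
peak $E_{es}$ at $T_s$ (the time of maximum elastance), falls back to
$E_{ed}$ at $T_e$ (the time of minimum elastance), and stays there for the
remainder of the cycle. The ramp is continuous, periodic, and attains its
extrema exactly at $t = T_s$ and $t \in \{0, T_e\}$. A smooth
trigonometric activation is the standard choice for elastance drivers in
lumped cardiovascular models; any smooth unimodal ramp with the same
anchor points would serve, and the two-piece cosine is the simplest one
with interpretable timing parameters.

Both heart valves are resistive diodes, $Q = \max(\Delta P / R,\, 0)$: flow
is Ohmic when the pressure gradient is forward and exactly zero otherwise —
no inertia, no regurgitation. The aorta is a single compliant compartment
whose pressure absorbs the aortic volume state ($P_\mathrm{Ao} =
V_\mathrm{Ao}/C_\mathrm{ao}$), drained through the arterial resistance
$R_\mathrm{art}$ into a constant capillary pressure $P_\mathrm{cap}$;
filling comes from a constant left-atrial pressure $P_\mathrm{la}$. The
two-dimensional state $(V_\mathrm{LV}, P_\mathrm{Ao})$ evolves as

$$\frac{dV_\mathrm{LV}}{dt} = Q_\mathrm{mv} - Q_\mathrm{av}, \qquad
\frac{dP_\mathrm{Ao}}{dt} = \frac{Q_\mathrm{av} - Q_\mathrm{sys}}{C_\mathrm{ao}},$$

with $Q_\mathrm{sys} = (P_\mathrm{Ao} - P_\mathrm{cap})/R_\mathrm{art}$
allowed to be negative (diastolic run-off reversal is not physical here,
but the sign is determined by the data-driven pressures and in practice
stays positive).

### Parameters

| Parameter | Meaning | Units | Default (a priori) | Bounds |
|---|---|---|---|---|
| $R_\mathrm{mv}$ | mitral valve resistance | mmHg·s/µL | 5e-3 | [1e-4, 1e-2] |
| $R_\mathrm{av}$ | aortic valve resistance | mmHg·s/µL | 1e-3 | [1e-4, 1e-2] |
| $R_\mathrm{art}$ | arterial resistance | mmHg·s/µL | 0.268 | [0.1, 1.0] |
| $E_{es}$ | end-systolic elastance | mmHg/µL | 4.85 | [0.5, 6.0] |
| $E_{ed}$ | end-diastolic elastance | mmHg/µL | 0.146 | [0.01, 1.0] |
| $T_s$ | time of maximum elastance | s | 0.044 | [0.33, 0.66]·$T_c$ |
| $T_e$ | time of minimum elastance | s | 0.077 | [0.66, 0.88]·$T_c$ |
| $V_{\mathrm{LV},d}$ | LV dead volume | µL | 5 | [1, 10] |
| $C_\mathrm{ao}$ | aortic compliance | µL/mmHg | 0.968 | [0.4, 1.5] |

The constants are $P_\mathrm{la} = 5$ mmHg, $P_\mathrm{cap} = 20$ mmHg and
$T_c = 0.11$ s — an adult-mouse heart rate of about 545 beats/min. The
timing bounds are expressed as fractions of the cycle so that they scale
with $T_c$; on the default cycle they bracket the a priori values. The a
priori defaults themselves are data-driven formulas
(`apriori_parameters()`): $E_{es} = \max(P_\mathrm{LV})/\min(V_\mathrm{LV})$,
$E_{ed} = \min(P_\mathrm{LV})/\max(V_\mathrm{LV})$, $R_\mathrm{art} =
(\bar P_\mathrm{Ao} - P_\mathrm{cap})/\mathrm{CO}$, $C_\mathrm{ao} =$
stroke volume over aortic pulse pressure, with the valve resistances and
dead volume fixed at nominal healthy values. Timing is read off the
extrema of $dP_\mathrm{LV}/dt$ (fastest pressure rise for $T_s$, fastest
relaxation for $T_e$); when noise makes those estimates cross or leave
their bounds, the nominal 0.044/0.077 s values are used. Extremum-derived
values are clipped into the bounds above, since a single noisy sample can
otherwise push a ratio of extrema outside any physiological range.

### Numerical solution

The integrator is an adaptive Dormand–Prince 5(4) Runge–Kutta scheme
(compiled, relative tolerance 1e-8, absolute 1e-10). The diode
$\max(\cdot, 0)$ makes the right-hand side continuous but not smooth at
valve transitions; the kink is in the derivative only and is handled by
the tight step control rather than event location. A beat is integrated
from the fixed initial state $(V_\mathrm{LV}, P_\mathrm{Ao}) = (40, 70)$
and repeated until the sampled beat is periodic: the sup-norm relative
change of both state signals between consecutive beats must fall below
`tol = 1e-6`, with at most 50 beats (a warning, not an error, if the
budget is exhausted — the best beat is still returned). The converged beat
is reported on the measurement grid $t_k = k/f_s$, $k = 0, \dots, n-1$
with the endpoint excluded, so a 500 Hz recording of a 0.11 s cycle has
exactly 55 samples per beat; including both endpoints would duplicate the
periodic point. An independent reference route integrates the same R-level
right-hand side with `deSolve::ode()` and is compared against the compiled
path in the test suite.

## Synthetic data

`synthesize_dataset()` simulates the periodic beat and adds measurement
noise independently to each of the three signals. Three error models are
provided:

* **iid**: Gaussian, constant standard deviation σ (default 2, in signal
  units — a few percent of the pressure signals and ≈10% of the volume
  excursion, a realistic catheter noise floor);
* **heteroskedastic**: Gaussian with standard deviation
  $\sigma (1 + \gamma t)$. The generating law is linear in the abscissa
  because only the qualitative feature — variance growing along the
  record — is being emulated; γ defaults to 5/s (a 55% growth across one
  beat);
* **correlated**: a stationary lag-1 autoregressive process with
  coefficient ρ (default 0.8) and marginal standard deviation σ. An AR(1)
  process is the simplest one-parameter model of serial dependence; real
  correlated residuals usually reflect model discrepancy rather than a
  literal AR error, but produce the same smooth residual shapes.

All generators are reproducible under an integer seed, and the noiseless
truth is attached to the returned dataset. The quadratic testbed
`noise_testbed()` applies the same three noise models to the fixed
polynomial $M(x) = 0.4x^2 - 0.1x + 2$, giving a known-truth platform for
the residual diagnostics that is independent of the ODE model.

What the generator deliberately does **not** emulate: beat-to-beat
variability (heart-rate or contractility fluctuation), baseline drift,
catheter artifacts, or model discrepancy (data generated by a richer model
than the one being fitted). Passing the synthetic tests therefore
demonstrates that the estimation machinery is correct and calibrated under
its own assumptions — not that the circuit model is adequate for any
particular animal. On real data the residual diagnostics
(`residual_diagnostics()`) are the guard: systematic lag-1 correlation
there signals missing physics, and the package flags it rather than
modeling it.

## Sensitivity, correlation, and subset selection

`tornado_analysis()` perturbs each parameter ±10% one at a time and
reports percent changes of the systolic/diastolic summaries — a coarse
screening. `local_sensitivity()` computes central finite differences of
all three signal trajectories (relative step 1e-4, balancing truncation
error against the 1e-8 solver noise), scaled twice: each output row by the
mean of its data signal (so mmHg and µL outputs are comparable) and each
column by its parameter value (so mmHg·s/µL and s parameters are
comparable). The parameter scaling is a design choice the output scaling
does not imply; the relative (log-style) form makes the ranking metric
$\sum_t S_i(t)^2$ unit-free.

Correlation between parameters is read from the normalized pseudo-inverse
of $S^\top S$ — the Gaussian approximation of the parameter covariance up
to the noise variance. The pseudo-inverse (SVD, relative tolerance 1e-12)
keeps the computation defined when the matrix is numerically singular, and
a condition number above 1e12 is reported as an attribute.

`select_subset()` fixes parameters that are noninfluential (score below
1e-3 of the maximum — parameters three orders of magnitude down contribute
nothing to the fit but still cost degrees of freedom) and, for each pair
with |correlation| above 0.95, the lower-ranked member, with ties broken
by parameter order so the result is deterministic. On mouse-like synthetic
data this reproduces the expected structure: the aortic valve resistance
is noninfluential and the end-systolic elastance/dead-volume pair is
nearly collinear, leaving seven free parameters.

`profile_likelihood()` sweeps one parameter over a grid, re-optimizing the
remaining free parameters at each grid point (warm-started from the
neighboring solution), and classifies the curve against the cost threshold

$$J^\ast \left(1 + \frac{\chi^2_{1-\alpha,1}}{n-p}\right),$$

the residual-variance-corrected likelihood-ratio level for one degree of
freedom under Gaussian errors: crossing on both sides of the minimum is
`identifiable`, on one side `one_sided`, never `flat`. The classification
is relative to the sweep, which is the scientifically meaningful reading:
a parameter can be flat within ±20% of its value yet constrained over a
decade.

## Frequentist calibration

The cost stacks the three residual vectors without weights or scaling —
defensible here because the three signals are of comparable numeric
magnitude (tens of mmHg and tens of µL); for preparations where they are
not, weighted least squares would replace it. Each multistart run draws
`n_starts` initial points uniformly within the bounds (independent draws
under the seed; one start is optionally replaced by the a priori point)
and refines each with bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`, cost tolerance 1e-10, at most 2000 residual
evaluations per start). A simulation failure inside the cost returns a
large-residual sentinel (cost 1e12) so the optimizer can back away instead
of crashing. Results are sorted by cost; the spread of the top-20 optima
(`top_k_cov()`, coefficient of variation per parameter) is the practical
identifiability readout — near-identical top optima indicate a global
minimum, a large CoV (as when the dead volume is freed alongside the
elastances) indicates basins of attraction or a ridge.

Model comparison uses the concentrated Gaussian information criteria

$$\mathrm{AIC} = n \ln(J/n) + 2(p+1), \qquad
\mathrm{BIC} = n \ln(J/n) + \ln(n)\,(p+1),$$

with the noise variance counted as an estimated parameter and constant
terms dropped. Additive constants cancel in every comparison on the same
dataset, which is the only use the package makes of these numbers; a freed
parameter that cannot lower the cost raises AIC by exactly 2.

## Bayesian calibration

The likelihood is Gaussian with one shared variance σ² across all stacked
residuals — the exact Bayesian counterpart of the unweighted cost.
Priors are uniform boxes on the calibration bounds (boundary included).
Sampling is adaptive Metropolis: Gaussian random-walk proposals whose
covariance is $s_d(\mathrm{Cov} + \epsilon I)$ with $s_d = 2.4^2/p$,
adapted from the full chain history every iteration after the first 1,000
(ε = 1e-10 guards positive-definiteness; the initial proposal is diagonal
with standard deviations of 1% of each prior width). σ² is refreshed every
iteration from its conditional inverse-gamma distribution given the
current residual sum of squares — a conjugate update with a weak
hyperprior (one pseudo-observation). The hyperprior's scale is anchored at
the mean squared residual of a single bounded least-squares refinement
from the chain's starting point: anchoring at the raw start instead would
center the prior on the misfit of an uncalibrated parameter set and bias
σ² upward by the lack-of-fit, which the warm refinement removes at the
cost of one extra optimization. In the staged workflow the chain starts at
the frequentist optimum (calibrate first, then sample), which also gives
the sampler its shortest burn-in; started from the raw a priori point the
adaptation needs a few thousand iterations longer to mature, visible as a
depressed early acceptance rate.

Summaries (`posterior_summary()`) report mean, median, kernel-density mode
(Silverman bandwidth), standard deviation, and central quantile credible
intervals after discarding 20% burn-in. `chain_diagnostics()` reports the
acceptance rate, lag-1 autocorrelation, and effective sample size via the
truncated autocorrelation-sum estimator.

## Uncertainty quantification

Frequentist parameter intervals use the nonlinear-regression normal
approximation: $\hat\sigma^2 = J(\hat\theta)/(n-p)$, covariance
$\hat\sigma^2 (F^\top F)^{-1}$ with $F$ the unscaled output Jacobian at
the estimate (same central-difference machinery as the sensitivity module,
step 1e-4), and $t_{n-p}$ quantiles. Output bands use the pointwise
gradient $g$: confidence half-width
$t\sqrt{\hat\sigma^2\, g^\top (F^\top F)^{-1} g}$ and prediction
half-width $t\sqrt{\hat\sigma^2 (1 + g^\top (F^\top F)^{-1} g)}$, so the
prediction band encloses the confidence band wherever residuals are
nonzero. For a model linear in its parameters both reduce exactly to the
classical regression formulas, which the test suite verifies against
`lm()` to 1e-8.

Bayesian bands thin the post-burn-in chain uniformly to `n_draws`
(default 2,000) joint draws of (θ, σ²), simulate each draw, and take
pointwise 2.5/97.5 percentiles — of the simulations for the credible band,
and after adding Gaussian noise with each draw's σ² for the prediction
band. The center curve is the simulation at the best-fitting retained draw
(the draw minimizing the residual sum of squares, a joint-mode surrogate
that avoids a separate multivariate density estimate); failed simulations
are skipped and counted.

Residual diagnostics test the iid assumption per signal with two simple
rules: lag-1 autocorrelation beyond $2/\sqrt{n}$ flags serial correlation,
and a two-sided 5% slope test of squared residuals regressed on the
abscissa flags heteroskedasticity. Squared-residual regression was chosen
over visual inspection to make the verdict reproducible; it is the
plainest parametric version of such tests, and with two 5%-level rules the
false-alarm rate on truly iid residuals is about 10% by construction.

## Problem sizes and reproducibility

All randomized procedures accept integer seeds and are bit-reproducible
under them. The test suite runs entirely on synthetic data at reduced but
statistically meaningful sizes chosen to keep a full run within a couple
of minutes: 20-start multistarts for recovery, 200 replicates for the
coverage studies, 5,000-iteration chains for sampler checks (the
paper-faithful workflow profile uses 100 starts and 100,000 iterations and
is selected with `profile = "paper"` in the workflow configuration). The
acceptance script (`scripts/acceptance.R`) recomputes the pipeline's
headline quantities from scratch at the same scales.

## Known limitations

* The circuit has no atrium, baroreflex, pericardium, valve inertia, or
  multi-compartment vasculature; on real data its residuals are expected
  to show structure (model discrepancy), which the diagnostics flag but
  the statistical model does not correct.
* Local sensitivity and the asymptotic covariance are derivative-based and
  valid near the evaluation point only; no global (variance-based)
  sensitivity measures are provided.
* The correlated-error generator is AR(1); smooth discrepancy-like
  residual shapes are emulated only in their lag-1 signature.
* Profile-likelihood classification depends on the chosen sweep range, by
  construction.
* The adaptive Metropolis sampler is single-chain; between-chain
  convergence diagnostics are out of scope.
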