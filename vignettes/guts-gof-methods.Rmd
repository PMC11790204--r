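---
title: "Quantitative goodness of fit and visual assessment of GUTS survival models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative goodness of fit and visual assessment of GUTS survival models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gutsgof` implements, as one tested pipeline, the comparison of quantitative
goodness-of-fit (GoF) metrics against visual assessment of survival-model
fits used in the environmental risk assessment (ERA) of plant protection
products. This vignette is the package's account of the underlying models,
the numerical choices, and what the synthetic-data machinery does and does
not emulate.

## The survival model

Mortality under time-variable toxicant exposure is modelled with the reduced
General Unified Threshold model of Survival (GUTS-RED), which drives a
scaled damage state directly from the external concentration `Cw(t)`:

    dD/dt = kd (Cw(t) - D),   D(0) = 0,

with `kd` (1/day) the dominant rate constant lumping toxicokinetics and
damage recovery. Two death mechanisms are provided.

* **Stochastic death (SD)**: all organisms share a damage threshold `z`; the
  instantaneous hazard is `hb + b max(0, D(t) - z)` with background hazard
  `hb` (1/day) and killing rate `b` (1/(concentration unit x day)), so

      S(t) = exp(-hb t - b \int_0^t max(0, D - z) d tau).

* **Individual tolerance (IT)**: thresholds vary between organisms with a
  log-logistic distribution `F` (median `mw`, shape `beta`); an organism
  dies when its running-maximum damage first exceeds its own threshold:

      S(t) = (1 - F(max_{tau <= t} D(tau))) exp(-hb t).

Time is in days throughout; concentration units are whatever the exposure
profile uses.

### Numerical treatment

Exposure profiles are piecewise (linear segments by default, constant
segments for media-renewal designs; the last concentration is held beyond
the final time point). On each segment the concentration is affine, so the
damage is exponential-affine and is propagated **in closed form** — there
is no ODE solver and no step-size tolerance in the production path. The
test suite still cross-checks the closed forms against adaptive numerical
integration (`deSolve`) at `1e-8` relative tolerance.

The SD hazard integral is likewise evaluated exactly per segment. Damage is
unimodal on a segment (its derivative has at most one zero, available in
closed form), so each segment splits into monotone pieces; threshold
crossings are solved in closed form on constant-concentration pieces and by
bracketed root-finding (tolerance `1e-12`) on linear pieces, where the
crossing equation has no elementary solution. The exceedance antiderivative
is then evaluated between crossings. The IT running maximum uses the same
unimodal decomposition.

Survivor counts are sampled by chaining conditional binomial deaths between
observation times, which gives the exact `Binomial(n0, S(t))` marginal at
every time.

## Calibration

The likelihood is the standard conditional-binomial (equivalently,
multinomial-deaths) form: survivors at `t_j` are binomial out of the
survivors at `t_{j-1}` with probability `S(t_j)/S(t_{j-1})`, clamped to
`[1e-12, 1]` before the log. Priors are log-uniform on `kd`, on `b` (or
`beta`) and on the threshold (`z` or `mw`, default range `1e-2 x` the
smallest positive tested concentration to `10 x` the largest), and uniform
on `hb` in `[0, 0.1]/day`. Sampling uses an adaptive random-walk Metropolis
on log parameters — 4 chains, 50% burn-in, 2,000 retained draws by default —
with split-Rhat and effective sample size recorded per parameter; Rhat above
1.05 flags, but does not abort, a fit. Posterior-predictive summaries
(median and central 95% interval of predicted survivor counts) include
binomial sampling error by default, because the observable is an integer
count; the layer can be switched off to isolate parameter uncertainty.

The package's parameter-recovery study uses five treatments of 50 organisms
observed at 0, 0.5, 1, 2, 4, 7 and 14 days: a control, constant exposures at
1.5x, 3x and 6x the threshold, and a 1.5-day depuration pulse at 5x. The mix
was chosen for joint identifiability — early observations and the pulse
decay pin `kd`, the concentration dependence of mortality onset pins `z`,
and sustained kill rates at two exceedance levels pin `b` — and mirrors the
variety of acute/chronic, constant/pulsed designs in real dataset
collections. At this sample size the posterior medians of `kd`, `z` and `b`
carry roughly 10-20% sampling scatter, which is what the recovery tests
assert (25% per parameter in at least 8 of 10 seeds, with 95% credible
intervals covering the truth at their nominal rate).

## The GoF metric suite

Five metrics summarize one fit against one dataset; observations at `t = 0`
are excluded (the prediction there is exactly `n0`, so such rows would
inflate the PPC and deflate the NRMSE without carrying information — the
convention is configurable via `drop_t0`).

* **NRMSE** (%): root-mean-square error of predicted vs observed survivor
  counts over all time points and treatments, normalized by the mean
  observed count.
* **SPPE** (%): per treatment, `100 (y_obs_end - y_pred_end) / n0` at the
  last count. `sppe_min` is the most negative value (largest
  underestimation of effects) clipped at 0 from above; `sppe_max` the most
  positive (largest overestimation) clipped at 0 from below, so an error
  direction that never occurs reports 0%.
* **PPC** (%): the share of observations inside their 95% predictive
  interval, closed at the bounds.
* **Nagelkerke pseudo-R2**: likelihood ratio of the fitted model against a
  null model with one average survival probability (total survivors over
  total tested), both binomial at the end-of-test counts.

For combination, metrics are rescaled linearly to `[0, 1]` with 1 best:
`ppc/100`, `1 - nrmse/100`, `1 - |sppe|/100` (clamped at 0), and the
pseudo-R2 clamped to `[0, 1]`. The **average GoF** is the mean and the
**minimum GoF** the minimum of the scaled NRMSE, PPC, SPPE_min and SPPE_max.
The linear scaling on `[0, 100%]` makes a minimum-GoF cut of 0.54 correspond
to NRMSE below ~46%, PPC above ~54% and |SPPE| below ~46% — the same regime
as the regulatory suggestion that NRMSE <= 50% and PPC >= 50%.

Fit selection mirrors survey practice: a fit is kept only if some treatment
shows at least 70% end-of-test mortality (inclusive) and the experiment has
more than one treatment; retained fits are then subsampled to approximately
equal counts across five equal-width average-GoF bins (seeded).

## Representations

A fit is shown either as a **time series** (one panel per treatment:
observed survival proportions with Wilson score intervals, posterior-median
curve, 95% band) or as a **dose-response curve** (one panel per experiment:
end-of-test survival against each treatment's maximum concentration). The
DRC prediction curve is built by multiplicatively scaling the experiment's
reference profile — the highest-exposure treatment normalized to unit
peak — across a concentration grid and evaluating posterior end-of-test
survival. This is the minimal-assumption construction consistent with both
representations deriving from the same calibrated model; it is a package
design choice, as is plotting controls at a pseudo-position on the log
concentration axis. Panels carry equal-size metadata so a renderer cannot
bias visibility of detail between images.

Score comparison between representations is per fit: median score (midpoint
of the central pair for even counts) and acceptance fraction (scores 1-3)
per representation, classified as DRC better / equal / TS better by the
median.

## The synthetic survey

Real visual evaluations of model fits are rarely shareable, so the survey
stage is generated from an explicit latent model, which makes the inference
chain testable end to end against known ground truth.

* **Fit library**: synthetic SD datasets from randomized true parameters,
  paired with predictions from log-scale-perturbed parameters whose
  perturbation SD is drawn per fit up to 1.6 — this spreads the library
  over the whole GoF range, emulating the roughly equal coverage of fit
  quality levels in the rated image pool. Predictive intervals come from a
  tight pseudo-posterior around the perturbed parameters; a full MCMC per
  library fit would only slow the survey stage without changing its
  statistical structure.
* **Evaluators**: affiliation sampled with weights 15/5/13/24/6/1
  (academia, authority, CRO, industry, other, not specified) and experience
  levels 5..1 with weights 14/16/12/14/8 (most experienced modeler to
  nonmodeler), the composition of the actual 64-participant pool.
* **Design**: every evaluator sees 20 images in the fixed order five
  calibration time series, five calibration DRCs, five validation time
  series, five validation DRCs, drawn randomly and independently per
  category.
* **Scores**: a cumulative ordinal draw on a latent scale (probit link by
  default, i.e. latent normal): linear predictor on the combined GoF, image
  type, affiliation contrasts, centred experience, GoF x type and
  GoF x experience interactions, plus a normal evaluator random intercept
  shared across an evaluator's 20 images. The default geometry makes better
  GoF give better (lower) scores, lets experience steepen the GoF slope
  (more extreme scores from experienced evaluators), and places 50%
  acceptance near average GoF 0.74 and minimum GoF 0.54 — used as a
  recovery target, not claimed as ground truth.
* **Rejection reasons**: only scores 4-6 get a reason. For time-series
  images the end-of-test vs time-course group is Bernoulli with a logit
  linear in the four scaled metrics (default coefficients carry the
  expected sign pattern: SPPE negative, NRMSE/PPC positive); the one- vs
  multiple-panel letter and the DRC reason letters use fixed proportions.

Deliberately not simulated: learning over the 20-image sequence, free-text
reasons, and any dependence of scores on image rendering details. Passing
recovery tests therefore show that the inference chain is correct for data
with this structure — not that real evaluators behave this way.

## Inference

* **Cumulative ordinal regression** (`fit_cumulative`): probit (default) or
  logit link, five free cutpoints (ordered transform), Normal(0, 2.5)
  priors on coefficients, Normal(0, 5) on cutpoints, half-Normal(0, 2) on
  the evaluator random-intercept SD. The random intercept is integrated out
  of the likelihood with 15-node Gauss-Hermite quadrature, so the sampler
  works on the marginal posterior of ~15 fixed parameters. Two estimation
  modes: adaptive-Metropolis MCMC (initialized at the penalized-likelihood
  mode with the Laplace covariance as proposal shape) and a fast Laplace
  approximation; the test suite checks their agreement on synthetic data
  and uses the fast mode where many fits are needed.
* **ELPD-LOO** (`elpd_loo`): Pareto-smoothed importance sampling from the
  pointwise log-likelihood matrix, with the generalized-Pareto tail fit of
  Zhang & Stephens and per-observation k diagnostics; validated against
  exact leave-one-out refitting on small data. For random-effect fits the
  pointwise likelihood is the per-observation marginal (intercept
  integrated against its prior), which ignores within-evaluator posterior
  dependence; LOO-based decisions in the pipeline therefore use
  fixed-effect-only models, where the pointwise likelihood is exact.
* **Predictor screen** (`rank_predictors`): one single-predictor cumulative
  model per non-empty subset of the five scaled metrics — 31 candidates,
  singletons entering directly and larger subsets combined by average or
  minimum — ranked by ELPD-LOO with the paired SE of each difference to the
  top model. Raw ELPD is reported without multiplicity correction: this is
  a comparison, not a test.
* **Acceptance thresholds** (`fit_acceptance_logit`,
  `acceptance_threshold`): acceptance (score <= 3) is Bernoulli-logit in one
  metric; the 50% threshold is the analytic root `-a/b`, with its interval
  from normal-approximation draws of the coefficients. Non-positive slopes
  or thresholds outside the metric range are flagged, never silently
  returned.
* **Rejection-reason model** (`fit_rejection_reason_model`): among rejected
  time-series records with a grouped reason, response 1 = end-of-test
  related, logit-linear in the four scaled metrics. A negative coefficient
  means that metric, like the evaluators, judges a fit bad because of the
  end of the test; positive, because of the time course.

### Scales used by the tests

The acceptance-style checks run at desk scale on one CPU: 100 random
profiles for the damage oracle; 1,000 random fixtures for the metric
oracles; 10 seeds of the 5 x 50-organism calibration recovery; 20
replicates of the 64-evaluator survey-chain recovery (Laplace mode); a
40-observation exact-LOO comparison; 10 replicates each of the screen and
reason-model recoveries. These sizes are the package's chosen compromise
between statistical resolution and a test suite that runs in minutes.

## Known limitations

* The exact priors and sampler settings behind published GUTS fits vary by
  implementation; recovery on synthetic data, not numerical identity with
  any one tool, is the correctness claim here.
* Laplace-mode credible intervals are approximate; on the survey-model
  posteriors examined they agree with MCMC to well within a posterior SD,
  but skewed posteriors (tiny samples, near-boundary SDs) will degrade
  them.
* The screen refits 31 models independently; with very small surveys some
  candidates can fail to converge and are excluded from the ranking with a
  notice rather than imputed.
* Real survey data would add structure the generator omits (ordering
  effects, evaluator-image interactions); conclusions about real evaluators
  require real evaluations.
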