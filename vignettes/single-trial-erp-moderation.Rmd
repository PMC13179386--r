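---
title: "Single-trial ERP regression and trait-moderated brain-brain analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial ERP regression and trait-moderated brain-brain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterp)
```

## The analysis problem

`sterp` implements a two-level mass-univariate analysis of single-trial
event-related potentials (ERPs). The scientific question it serves is a
*brain-brain* one: does the between-subject relationship between neural
feedback sensitivity (a larger P3b to loss than to gain feedback) and neural
motor inhibition (a larger P3 to successfully withheld or cancelled responses
than to executed ones) depend on a trait such as compulsivity (OCI-R sum
score) or negative urgency (UPPS subscale sum)?

The pipeline has three statistical stages.

**First level (within subject).** At every electrode and time point of the
epoch grid, single-trial voltages are regressed on trial-wise task
predictors by robust regression:

* go/nogo: `EEG = b0 + b1*trial_type + b2*ITI`, trial type coded go = -1,
  nogo = +1, the preceding inter-trial interval (seconds, centered) as a
  nuisance regressor;
* stop-signal: `EEG = b0 + b1*trial_type + b2*arrow + b3*ITI`, go = -1,
  *successful* stop = +1 (failed stops excluded), arrow direction -1/+1;
* feedback tasks: `EEG = b0 + b1*valence`, with valence coded -1 for gain
  and +1 for loss. In the incentivized flanker task valence is coded at the
  *context* level (potential-gain context -1, loss-avoidance context +1; all
  feedback trials retained). In the two-step task, feedback worth zero points
  is excluded and negative points code +1 (loss), positive points -1 (gain).

The per-subject output is a b-value map per regressor over the
electrode-by-time grid.

**Group main effects.** Per cell, subjects' b-values are tested against zero
with a two-tailed one-sample t-test (`df = n - 1`); multiplicity over all
cells (channels x times, e.g. 63 x 401 at full scale) is handled by
Benjamini-Hochberg FDR at alpha = 0.025. Peaks of a component are the
maximal-|t| FDR-significant cells inside an a-priori region (e.g. central
electrodes beyond 300 ms for the nogo P3), reported with the critical p (the
largest rejected p-value), a confidence interval at the
`100*(1 - critical p)` percent level, and one-sample Hedges' g
(`g = J*t/sqrt(n)`, `J = 1 - 3/(4(n-1)-1)`).

**Second level (moderated brain-brain regression).** Each subject's feedback
effect is summarized as a scalar window score: the mean feedback-valence b
over a component window (flanker P3b: Pz, 500-520 ms; two-step P3: CP1,
440-460 ms). The inhibition-task b-maps are then regressed, cell-wise across
subjects, on the centered window score and its product with the centered
trait moderator:

```
first-level b = B0 + B1 * x_c + B2 * (x_c * m_c) + error
```

Two points deserve emphasis. First, following the reported model, the
moderator has *no* main-effect column; `include_moderator_main = TRUE`
restores the conventional moderated-regression form because the omission is
unusual (it forces the moderator's main effect into the error term). Second,
with both variables demeaned, `B1` is the simple slope at the average
moderator value. Interaction maps are masked at uncorrected p = 0.010, as in
the reported figures; no second-level FDR is invented.

Significant interactions are probed with Johnson-Neyman (JN) analysis. The
simple slope at moderator value `m` (centered `m_c`) is `s = B1 + B2*m_c`
with `SE^2 = V11 + 2*m_c*V12 + m_c^2*V22` from the coefficient covariance;
JN boundaries solve `s^2 = t_crit^2 * SE^2` (two-sided p = 0.01 at the
residual df) as a quadratic in `m_c`, are mapped back to raw trait units,
and are clipped to the observed moderator range. Interval significance is
labelled by evaluating the simple-slope p at interval midpoints. The
residualized-trait variant replaces the moderator inside the product term by
the raw residuals of regressing one trait on the other, isolating each
construct's unique variance; the main-effect predictor is unchanged.

### A note on degrees of freedom

Second-level coefficient tests use residual `df = n - 3` (intercept, main
effect, interaction). Published analyses of this design sometimes print
`t(n - 1)`; with n in the hundreds the difference is immaterial, but the
package reports the df its model actually has.

## Preprocessing operators

Applied in this order by the pipeline (each operator is exported and
composable):

1. **Baseline correction** -- per trial and channel, the mean over the 200 ms
   pre-stimulus window (`[-200, 0)` ms) is subtracted.
2. **Improbable-epoch rejection** -- per (channel, time) cell a Gaussian is
   fitted across trials; an epoch's improbability score is the mean negative
   log-density of its values under those Gaussians, and epochs scoring more
   than 5 SDs above the mean score are removed in a single pass. This is a
   concrete, configurable stand-in for joint-probability artifact rejection;
   the estimator (Gaussian surprise, mean aggregation, mean+5SD cut) is a
   package choice.
3. **Temporal smoothing** -- 5-point centered moving average (each sample
   averaged with the two preceding and two succeeding samples). At the grid
   edges the window truncates to the available samples, which keeps the
   operator average-preserving; edge handling is a package choice.
4. **Analysis-window selection** -- the regression grid is restricted to
   -100..700 ms, endpoints inclusive on both sides, so a 500 Hz recording
   yields 401 samples (an 100 Hz desk-scale grid yields 81).

Rejection runs *before* smoothing (so a gross artifact cannot leak into its
neighbours before being scored) and smoothing before window selection (so
the analysis window contains no truncated-kernel edges).

## Robust first-level estimator

`irls_fit()` is iteratively reweighted least squares with Tukey bisquare
weights, tuning constant 4.685, robust scale `median(|r|)/0.6745`
re-estimated each iteration, convergence when the largest coefficient change
drops below 1e-6, at most 50 iterations, OLS start. These are the standard
robust-regression defaults; the tuning constant gives 95% efficiency under
Gaussian noise. Two consequences matter for testing: on clean data the
bisquare estimate is *statistically* equivalent to OLS (differences are a
small fraction of the OLS sampling SE) but not numerically identical --
bisquare downweights every nonzero residual slightly -- and under gross
outliers (which the synthetic generator plants deliberately) it dominates
OLS in recovery error. Rank-deficient designs abort with the offending
columns named; per-cell failures inside a map fit are recorded as flagged
cells rather than aborting the subject.

## The synthetic cohort generator

The generator exists so that every stage has a ground truth to recover. It
emulates:

* **Task event streams**: go/nogo with exactly 25% nogo trials; a
  stop-signal task with exactly 25% stop trials whose stop-signal delay is
  staircase-tracked (initial 200 ms, step 50 ms -- conventional tracking
  values) around an independent-race respondent (defaults: go finishing
  times N(450, 80) ms, stop process N(200, 40) ms), converging to ~50% stop
  success; an incentivized flanker task with balanced potential-gain /
  loss-avoidance contexts and outcomes driven by sampled error/too-slow
  rates; and a two-step task with 80/20 common/rare transitions and feedback
  points following a Gaussian-step random walk reflected at +5 and -4.
  Outcome points are the rounded walk value (the task shows integer points),
  which makes the bounds attainable; zero-point feedback occurs and is
  excluded only at design construction. Inter-trial intervals are jittered
  uniformly on 0.8-1.2 s (the ITI enters the designs only as a nuisance
  covariate; its distribution is a package choice).
* **Epochs**: each epoch is a condition-dependent ERP component (Gaussian
  spatial falloff around a peak channel times a half-cosine temporal kernel
  times `base + effect*code`), a per-trial DC baseline offset, and noise
  that is AR(1) in time (coefficient 0.9), spatially mixed through a random
  orthonormal matrix, with 5% of epochs scaled 8-fold -- outliers planted
  specifically to exercise the robust estimator and the epoch rejection.
  There is no head-model forward simulation and no ocular/cardiac artifact
  structure; passing recovery tests therefore demonstrates statistical
  correctness of the pipeline, not robustness to everything real EEG
  contains.
* **Between-subject structure**: per-subject feedback-effect amplitudes are
  drawn around 4 uV (SD 1.5); inhibition-effect amplitudes follow
  `inh_base + (coupling + moderation*(trait - mean trait)) * (feedback amp -
  mean) + residual`, so the second-level model's true coefficients are known
  by construction. Defaults (`coupling = 0.5` uV/uV, `moderation = -0.03`
  per OCI-R unit) mirror the magnitudes reported for this design at full
  scale. Trait scores are bivariate normal (OCI-R 12.6 +/- 9.5, urgency
  26.3 +/- 5.9, r = 0.18), rounded and clipped to the theoretical ranges
  0-72 and 12-48 -- clipping shifts the OCI-R moments slightly upward, which
  the tests allow for.

## Problem sizes, power, and the recovery condition

Tests and examples run at desk scale: 100 Hz grids (81 analysis samples),
6-19 channels, 40-60 subjects, 80-300 trials per task; the full-scale
profile (205 subjects, 500 Hz, 63 channels) is configuration, not a
requirement. Two consequences of desk scale are handled explicitly rather
than hidden:

* **Power.** At the reported full-scale interaction magnitude
  (`moderation = -0.03`) a 60-subject cohort yields an interaction t near
  -1.9 -- the real design needed a few hundred subjects. Recovery and power
  suites therefore plant `moderation = -0.06`, a deliberately well-powered
  recovery condition chosen from a prospective power calculation; package
  defaults remain at the reported scale.
* **Attenuation.** The windowed feedback score is the true amplitude times a
  known kernel factor plus first-level estimation noise, so the second-level
  slopes are attenuated by the score's reliability
  `lambda = var(true part)/var(score)` -- classical errors-in-variables,
  intrinsic to two-level designs including the original. Recovery tests
  compare estimates against `coupling*lambda` and `moderation*lambda`, with
  `lambda` computed per cohort from the stored ground truth, rather than
  pretending the attenuation away.
* **Two-step trial counts.** Short reward walks have a non-trivial chance of
  producing single-signed outcomes (about 6% of 100-trial runs), which makes
  the valence design degenerate; the default two-step count is therefore
  300 trials, as in typical uses of the task.

## Numerical and degenerate-input choices

* `fdr_bh()` implements the step-up rule directly and returns the critical p
  (largest rejected p; 0 when nothing is rejected). Tests check it against
  both `stats::p.adjust("BH")` and a literal brute-force step-up oracle.
* Peak search restricts to FDR-significant cells of matching sign and breaks
  |t| ties by earlier time, then channel order, for determinism; an empty
  significant set returns an explicit no-peak result.
* Zero-variance cells in the group t-map (all subjects identical) are
  assigned p = 0 when the mean is nonzero (degenerate certainty) and p = 1
  when it is zero.
* JN boundaries with a negative discriminant yield an empty boundary set and
  a whole-range significance label; boundaries are clipped to the observed
  moderator range.
* `reject_improbable()` on an all-identical epoch set warns and rejects
  nothing; a rejection threshold of infinity is the identity.
* Epoch bundles store float32 voltages (little-endian raw array + JSON
  manifest + TSV trial table); round trips are lossless at float32
  precision, and shape mismatches name the offending dimension.

## Limitations

Filtering, re-referencing and ICA cleaning are out of scope -- input epochs
are assumed cleaned. The BH procedure's FDR control under the strong spatial
and temporal dependence of EEG rests on the positive-regression-dependence
argument; the null-simulation test uses independent cells. Two-step choice
behaviour is random (no reinforcement-learning agent), and reward-prediction
-error regressors are not implemented. The improbability estimator is one
reasonable member of the family of joint-probability rejection rules, not a
reimplementation of any particular toolbox's.
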