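---
title: "Models and methods in ethogaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ethogaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethogaze)
```

ethogaze analyses "channel-surfing" information-foraging experiments:
subjects repeatedly choose among viewing options (a blank screen, a new
random clip, a continuation, or a repeat of the last clip), then freely
view 5 s of naturalistic video that has been annotated frame-by-frame with
an ethogram of species-typical behaviours. The package covers the whole
analysis chain — ethogram data model, gaze statistics, task simulation,
penalized regression, choice and neural encoding models — plus a
synthetic-data generator with known ground truth, so every stage can be
validated end to end without any recordings.

## The ethogram data model

Scoring and analysis use two different shapes of the same ethogram.
*Scoring* treats six observations as leveled states (camera movement,
monkey count, face visibility, ano-genital-area visibility, foraging,
aggression intensity), each holding exactly one level per frame, alongside
some thirty binary event behaviours. *Analysis* needs every variable
binary, so `deriveAnalysisEthogram()` expands the leveled states through
cumulative membership rules (e.g. *count ≥ 2* is true for levels 2, 3–5,
6–10 and >10) and pools rare agonistic events into broader classes
(*attack*, *threaten*, *submit*). Because the level rules are cumulative,
the nesting implications — eye contact ⇒ direct face ⇒ prominent face ⇒
visible face, and the analogous count, aggression and genital-visibility
chains — hold by construction, and the test suite checks them on
randomized timelines.

Two decisions here were genuinely open:

* **Pass-through events.** By default the pooled agonistic classes
  *replace* their constituent raw events — the pooling exists precisely
  because those constituents are too rare to analyse individually — which
  yields 27 derived variables plus 16 remaining events (plus 4 gaze
  regressors in the encoding model). The pass-through list is an argument,
  so a different regressor composition is one call away.
* **Annotation intervals** are half-open `[start_frame, end_frame)` in
  0-based frames, which avoids off-by-one ambiguity at bout boundaries;
  unannotated frames take the baseline level (leveled observations) or 0
  (events), matching the "complete timeseries" semantics of scored video.

Window averaging (`windowAverageRegressors()`) attributes each frame to
the window containing its draw-time midpoint; at 30 fps and 200 ms windows
each of the 25 windows of a 5 s presentation holds exactly 6 frames.

## Gaze focus and the consistency/typicality statistics

Raw 1000 Hz eye positions are boxcar-averaged to one *gaze focus* per
video frame, with windows centred on the frame draw times to minimize
phase delay, and rescaled so the video height is 1 unit with the origin at
the video centre (y points down, the screen convention; both statistics
below are rotation-invariant so orientation does not affect results). A
focus is *in frame* inside the closed rectangle ±0.716 × ±0.550 — the
610 × 458 video footprint plus a 0.05 buffer on each side. Closed bounds
are the measure-zero-safe reading of an inclusive "within".

For the n gaze foci observed on one video frame across repeated viewings,
gaze consistency is

$$g = \frac{2 d_0}{n(n-1)} \sum_i \sum_{j<i}
      \frac{1}{\max(\lVert x_i - x_j\rVert,\, d_0)},$$

the mean pairwise capped inverse distance, analogous to the potential
energy of a cloud of mutually repulsive particles with the interaction
capped below $d_0$ (default 0.01 ≈ 4.58 video pixels, the smallest
distance treated as a meaningfully different gaze target). It is 1 exactly
when all foci fall within a disc of diameter $d_0$ and decays as foci
disperse; unlike covariance-based spread measures it ranks one tight
cluster above two tight clusters above a diffuse cloud. Gaze typicality is
the per-observation analogue
$\tau_i = \frac{d_0}{n-1}\sum_{j\neq i} \max(\lVert x_i - x_j\rVert, d_0)^{-1}$.
Both are computed only for frames with at least 5 in-frame observations
(`minObservations`), and typicality only for in-frame foci; offscreen and
missing samples are excluded rather than imputed, since the statistics are
defined on observations. Neither statistic is scale-invariant: scaling all
inter-point distances (above $d_0$) by $c$ divides $g$ by exactly $c$, a
property the tests assert. The implementation is vectorized over the
pairwise distance matrix and is required by the tests to agree with a
literal double-loop oracle to 1e-12.

## The task engine

Menus (all 6 unordered pairs plus 4 forced singletons of Blank / Switch /
Continue / Repeat) carry target weights $b_k$: singletons share 10% of the
mass, pairs share the rest uniformly. Menu validity follows the task
rules: Continue/Repeat are never offered after a Blank choice (or at
session start), and Continue requires at least 5 s remaining in the source
file. To keep constrained menus near their targets, sampling uses the
adaptive weight

$$a_k = b_k\, 2^{(1 - n_k/(N b_k))/0.2},$$

where $n_k$ counts presentations of menu $k$ out of $N$ trials so far
($a_k = b_k$ at $N = 0$). Among the algebraic readings of this reweighting
rule, this is the one with a fixed point $a_k = b_k$ at the target
presentation rate that up-weights under-presented menus — the behaviour
the procedure exists to provide. `adaptiveWeight(b, N*b, N)` equals `b`
exactly.

One consequence worth understanding: the adaptive correction is partial,
not exact. Whenever the previous choice was Blank, only three menus are
valid, so those menus accumulate extra presentations that the finite
reweighting rate (0.2) never fully claws back. If choices are uniformly
random, Blank is chosen on ~28% of trials and the Continue/Repeat menus'
combined target (80%) exceeds the 72% of trials on which they are valid at
all — convergence to targets is then *infeasible* and the forced-choice
fraction settles near 12%. Under the package's default choice model
(utilities 0 / 0.5 / 1 / 2 for Blank / Repeat / Continue / Switch,
mirroring the strong empirical preference ordering in which a blank screen
is least attractive), Blank is chosen on ~14% of trials and the long-run
forced-choice fraction settles near 10.7% — close to, but measurably
above, the 10% design mass. Simulation studies in this package therefore
always use the preference-ordered policy as the study condition.

## Penalized GLMs

All regression stages share one engine: elastic-net GLMs fitted by
coordinate descent (glmnet) behind a surface that adds per-coefficient
penalty factors (0 = unpenalized, used for the choice model's utilities),
explicit internal standardization (predictors centred when an intercept is
fitted, scaled to unit variance; coefficients reported on the original
scale), 20-fold cross-validation with the one-standard-error rule
($\lambda_{1SE}$ = the largest $\lambda$ whose CV deviance is within one
SE of the minimum, i.e. the sparser end of statistically indistinguishable
fits), a grid search over the mixing parameter $\alpha$ (default grid
0.1–1.0 in 6 points; ties go to the larger, sparser $\alpha$), and a
permutation null. Folds are drawn from the session RNG and stratified by
class for binomial responses. Every fit can be audited with `kktCheck()`,
which verifies the subgradient optimality conditions on the standardized
scale to 1e-6; at $\lambda = 0$ fits agree with unpenalized IRLS
(`stats::glm`) to the same tolerance.

Because p-values on individual elastic-net coefficients are not
meaningful, false discoveries are assessed by `permutationNullFit()`: the
rows of the penalized design columns are randomly permuted (unpenalized
columns and any offset stay aligned with the response) and the full
CV-plus-1SE procedure is re-run; discoveries under permutation estimate
the false-discovery behaviour of the whole pipeline. On the synthetic
encoding data this procedure discovers nothing in any unit.

The larger simulation studies in the test suite use a reduced
$\alpha$ grid of {0.5, 1} and sessions of 50–200 presentations per unit —
sizes chosen so the full suite runs in minutes while leaving the CV and
1SE machinery untouched; the default 6-point grid is exercised by the unit
tests.

## The ranked 2AFC choice model

Options carry an arbitrary ranking (Blank 0 < Repeat 1 < Continue 2 <
Switch 3). For each two-option trial the response is 1 if the
higher-ranked option was chosen, and each non-Blank option gets a
regressor $m_i$ ∈ {+1 higher-ranked offered, −1 lower-ranked offered, 0
absent}; Blank is the zero-utility baseline. The log-odds of choosing the
higher-ranked option are

$$\ln\frac{p_d}{1-p_d} = \sum_i v_i m_{d,i}
  + \sum_i \sum_k \beta_{i,k}\, m_{d,i} x_{d,k},$$

with $x_{d,k}$ the binary occurrence of ethogram variable $k$ in the
*previous* trial's video (all zero after a Blank). The utilities $v_i$ are
unpenalized; the interactions $\beta_{i,k}$ carry the elastic-net penalty.
The model has no intercept (the ±1 coding absorbs the comparison
structure). Forced trials and the first trial of a session are excluded.
Parameter-recovery tests plant $v$ = (0.5, 1, 2) and recover each utility
within ±0.15 at ~10⁴ two-option trials, with the null interaction set
surviving in ≥90% of replicates.

Gaze-behaviour models reuse the same engine: gaze-onscreen is a binomial
(logit) GLM of the per-frame-presentation in-frame indicator on the
ethogram variables, and gaze consistency — z-scored across frames, this package's
reading of "normalized", for which no exact definition is established —
is a gaussian (identity link) GLM. Because ethogram variables are
nested, a frame's total prediction is the sum of all active variables'
coefficients.

## The free-viewing encoding model

Spike counts in 200 ms windows ($t$ = 0…24 within presentation $n$) are
modelled as Poisson with

$$\ln \varphi_{n,t} = \ln(\varphi_0\, \pi_t\, \delta_n)
  + \sum_k \beta_k\, x_{k,n,t-\tau},$$

where $\varphi_0$ is the unit's baseline rate, $\pi_t$ its characteristic
within-presentation timecourse (the PSTH across presentations, scaled to
mean 1), $\delta_n$ a slow per-presentation drift (mean 1), and the
regressors are window-averaged ethogram and gaze variables lagged by
$\tau$ = 100 ms, the latency for visual information to reach prefrontal
cortex. The three offset components are estimated first
(`estimateTimecourseAndDrift()`) and enter as a fixed log-offset, so the
penalized fit explains only departures from the unit's stimulus-locked and
slow-drift structure; $\beta_k$ are all penalized and reported as
multiplicative gains $e^{\beta_k}$. The 200 ms window is twice the ~100 ms
lag at which spike-count autocorrelation falls below 0.1 without stimuli
(`autocorrelationWindowCheck()` reproduces this calculation), balancing
window independence against stationarity. Variables present in fewer than
5 distinct presentations are excluded: with fewer exemplars, a rate change
cannot be attributed to the behaviour rather than to whatever co-occurred
with it.

Numerical choices: $\pi_t$ and $\delta_n$ are floored at 1e-3 so
log-offsets stay finite; the drift estimator is a centred 21-presentation
running mean of the per-presentation mean rate (the estimator itself is a
design choice of this package). The drift estimator deserves one caution, which
the tests encode: it assumes the stimulus content of nearby presentations
is roughly exchangeable. When consecutive presentations are segments of
the same video in order, smoothed stimulus effects leak into
$\hat\delta_n$ and inflate false discoveries; with presentation order
randomized across videos — which the Switch-dominated task approximates —
recovery is clean (sign agreement of recovered gains ≥95%, median false
positives ≤1 per unit at 200 presentations). The family is Poisson with a
log link throughout, the natural model for window spike counts.

Choice-phase responses are modelled separately (`fitChoicePhaseModel()`):
quasi-Poisson GLMs compare counts 0.1–0.6 s after target onset with a
0.0–0.5 s pre-trial baseline, with epoch-by-option terms contrasting
Switch and Continue against Blank, using either the chosen or the offered
options; significance is Bonferroni-corrected at 0.05 and "modulation" is
reported as the fold-change $e^{|\hat\beta|}$, the natural effect size for
a log-link model. Overdispersion is handled by the quasi-Poisson scale estimate.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions for every recovery test:

* **Behaviour timelines**: each leveled observation alternates baseline
  and active bouts with exponential dwell times (defaults: 3 s baseline,
  1.5 s active, uniform choice among non-baseline levels); events get
  Poisson bout onsets (1/300 per frame) with exponential durations (mean
  20 frames). Dwell distributions are configurable per observation; exponential is the
  maximum-entropy default in the absence of characterized bout-duration
  statistics.
* **Gaze**: per block of 150 frames, a small set of attractors is placed
  in the frame; each viewing of each frame is offscreen with probability
  logistic in the ethogram variables, otherwise Gaussian around an
  attractor whose spread can depend log-linearly on the ethogram. This
  reproduces the qualitative structure the gaze statistics respond to
  (multimodality, behaviour-dependent tightness and onscreen occupancy),
  not saccade kinematics or smooth pursuit.
* **Choices**: Bernoulli draws from the ranked-choice model at true
  utilities (default 0.5 / 1 / 2) and optional true interactions.
* **Spikes**: Poisson counts at
  $\varphi_0 \pi_t \delta_n e^{\sum\beta x}$ with timestamps uniform in
  their window; default units have a sinusoidal timecourse, smooth
  exponential drift within ±35%, 5–10 active regressors and gains in
  [1/3, 3].

Everything is a pure function of the configuration and the session RNG
(`set.seed()`), and generated data pass every upstream validator. A full
synthetic session (default 500 trials, 100 videos of 30–120 s) composes
all of these coherently, with choices reading occurrence from the actually
viewed segments.

What passing these tests shows — and does not show: recovery holds under
the generator's semi-Markov, exchangeable-presentation, log-linear-gain
assumptions. Real recordings add slow non-exponential behavioural bouts,
non-boxcar neural response profiles (the model's boxcar-with-lag
assumption under-detects brief behaviours), and regressor collinearity
beyond what the generator produces — and correlated regressors can always
masquerade for one another in a penalized fit.

## Known limitations

* Degrees-of-visual-arc conversion is out of scope (viewing geometry is
  not specified); all gaze quantities are in video-height units.
* The gaze-consistency GLM treats frames as observations; whether the
  original analysis used frames or frame-presentations for that model is
  not stated.
* The adaptive menu procedure's forced-choice fraction is exactly 10%
  only in the zero-blocking limit (see the task-engine section); the
  package reports what the procedure actually produces.
* Utilities from `fitChoiceModel()` are on the logit scale relative to
  Blank; they are comparable across options within a session, not across
  sessions with different menu compositions.
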