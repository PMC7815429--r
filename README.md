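# ethogaze

Analysis toolkit for **channel-surfing information-foraging experiments**:
tasks in which a subject repeatedly chooses what to watch next — a blank
screen, a brand-new video clip ("Switch"), the continuation of the last
clip ("Continue"), or the same clip again ("Repeat") — and then freely
views 5 s of naturalistic video that has been annotated frame-by-frame
with an ethogram of species-typical behaviours. The package is aimed at
researchers in neuroethology and decision neuroscience who need to relate
annotated video content to viewing choices, gaze behaviour, and
single-unit activity.

## What it implements

**Ethogram data model.** Frame-wise scoring timelines (leveled states such
as camera movement, monkey count, face/ano-genital visibility, foraging
and aggression intensity, plus binary events) are parsed from interval
tables and expanded into binary *analysis* variables through cumulative
membership rules, so nesting implications (eye contact ⇒ direct face ⇒
prominent face ⇒ visible face, count ≥ 11 ⇒ … ⇒ count ≥ 1, …) hold by
construction. Variables are window-averaged into regressors (25 windows of
200 ms per 5 s presentation) and filtered by a ≥5-distinct-presentations
rule.

**Gaze statistics.** Raw 1000 Hz eye traces are boxcar-downsampled to one
*gaze focus* per video frame in normalized video coordinates (height = 1,
origin at centre; in-frame = the closed rectangle ±0.716 × ±0.550). For
the *n* foci observed on a frame across viewings, gaze **consistency** is
the capped mean pairwise inverse distance

    g = 2 d0 / (n(n-1)) * sum_{i<j} 1 / max(||x_i - x_j||, d0),  d0 = 0.01

(1 when all foci fall within a disc of diameter d0; one tight cluster >
two clusters > diffuse cloud), and gaze **typicality** is its
per-observation analogue. Both require ≥5 in-frame observations.

**Task engine.** Menu sampling with adaptive weights
`a_k = b_k * 2^((1 - n_k/(N b_k))/0.2)` over valid menus (Continue/Repeat
never follow a Blank choice; Continue needs ≥5 s of file left), forced
singleton menus at 10% target mass, duration-weighted Switch outcomes, and
pluggable choice policies.

**Penalized GLMs.** Elastic-net regression (gaussian / binomial / Poisson,
optional offsets) with per-coefficient penalty factors, 20-fold CV with
the one-standard-error rule, an alpha grid search, KKT verification of
every returned solution, and permutation-null refits for false-discovery
assessment.

**Choice and neural models.** The ranked two-alternative choice model
(option utilities unpenalized, option × previous-video-ethogram
interactions penalized), binomial gaze-onscreen and gaussian
gaze-consistency models, the free-viewing Poisson encoding model
`ln φ(n,t) = ln(φ0 π_t δ_n) + Σ_k β_k x_{k,n,t−τ}` with estimated
timecourse/drift offsets and τ = 100 ms lagged regressors, quasi-Poisson
choice-phase models with Bonferroni-corrected option contrasts, an
autocorrelation-based analysis-window check, and population summaries of
nonzero coefficients by region.

**Synthetic data.** A generator producing semi-Markov behaviour timelines,
attractor-based gaze with behaviour-dependent offscreen probability and
spread, ranked-utility choices, and Poisson spike trains from the
generative encoding model — all with recorded ground truth, so every
recovery property is testable offline.

## Worked example

```r
library(ethogaze)
set.seed(1)

# simulate 4000 choice trials at known utilities, then recover them
cd  <- generateChoiceData(4000, v = c(Repeat = 0.5, Continue = 1, Switch = 2))
des <- buildChoiceDesign(cd$trials, cd$occurrence)
fitChoiceModel(des, penaltyConfig("binomial", alphaGrid = c(0.5, 1)))
#> Ranked 2AFC utility model (utilities relative to Blank = 0)
#>   Repeat Continue   Switch
#>   0.4779   0.9795   2.1042
#> 0 nonzero option-by-ethogram interaction(s)
```

The printed utilities are log-odds of choosing each option over Blank in a
head-to-head menu: the planted ordering Switch > Continue > Repeat > Blank
is recovered within ±0.11, and since no option-by-behaviour interaction
was planted, the elastic net correctly returns an empty interaction set.

```r
# gaze metrics on 8 synthetic viewings of one annotated video
ae  <- deriveAnalysisEthogram(generateEthogramTimeline(900, videoId = "demo"))
gz  <- generateGazeTraces(ae, nViews = 8)
agg <- aggregateFrameGaze(gz$views)
summary(agg$frames$consistency)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.    NA's
#> 0.03863 0.07710 0.10168 0.11028 0.13732 0.33052      25
mean(agg$frames$proportion_onscreen)
#> [1] 0.8483333
```

Consistency is defined only on frames with at least five in-frame
observations (the 25 `NA` frames fail that rule); higher values mean gaze
landed in tighter agreement across viewings of the same frame.

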