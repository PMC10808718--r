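---
title: "Simulating and analysing closed-loop emotional-face neurofeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing closed-loop emotional-face neurofeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The paradigm

`faceloop` models a real-time fMRI neurofeedback experiment in which the
feedback display is a human face whose emotional intensity is yoked to the
participant's own amygdala BOLD signal. A face morphs in 31 discrete steps
(indices 0–30) between a neutral (0%) and a fully emotional (100%)
expression — happy for half the cohort, fearful for the other half — and
each participant is instructed to push the expression toward or away from
the emotional endpoint by regulating their amygdala. Crossing emotion
(happy/fear) with instructed direction (up/down) yields four groups. Two
of them are *task-congruent* — happy-up and fear-down, where the instructed
change is also the hedonically preferred one — and these have loop polarity
+1 (more amygdala signal, more intense expression); the incongruent groups
(happy-down, fear-up) have polarity −1.

Each training run consists of four 20-s baseline blocks alternating with
four 40-s regulation blocks (240 s of task at TR = 1 s), preceded by five
dummy volumes that are discarded. Each participant completes four runs.

Because no public dataset exists for this paradigm, the package is built
around a generative simulator: every analysis stage can be exercised, and
its statistical behaviour studied, on data whose ground truth is known.

# The generative model

## Neural dynamics

Four regions are modelled in fixed order V1, FFA (fusiform face area),
bilateral amygdala (pooled, as in the single feedback ROI), and medial OFC.
Their latent states follow the bilinear form used in effective-connectivity
modelling:

$$\dot z = \Big(A + u_\text{face} B^{face} + u_\text{int} B^{int}\Big) z
  + C\,[u_\text{face}, u_\text{int}]^\top$$

where `u_face` is the regulation-block indicator, `u_int` the displayed
emotional intensity (morph index / 30), `A` the intrinsic coupling, and the
two `B` matrices its modulation by the face condition and the stimulus
intensity. Directed edges are restricted to V1→FFA, V1→Amy, V1→mOFC,
FFA↔Amy and mOFC↔Amy; driving inputs enter V1 only; self-connections are
strictly negative.

The default participant (`default_neural_params()`) keeps the intrinsic
couplings weak and routes the task effect through the modulatory terms —
faces gate the FFA→Amy relay (B1 = 0.5, B2 = 0.3) and engage an mOFC→Amy
control loop that is inhibitory in the fear condition (B1 = −0.25,
B2 = −0.15) and weakly facilitatory in the happy condition (+0.12/+0.06).
This mirrors the reported regime for this network, in which the amygdala
edges carry small intrinsic and large modulatory weights, with mOFC→Amy
negative while fearful content is being downregulated. Two choices are
worth flagging:

* the mOFC has a slower time constant (self-decay −0.25 vs −0.5 to −0.6
  elsewhere) and receives mostly amygdala-driven input. Without this, FFA
  and mOFC time courses are so collinear that their respective influences
  on the amygdala are not identifiable from 240 volumes — any inversion
  scheme would be free to trade one off against the other;
* the happy-condition mOFC loop is kept modest because a facilitatory
  Amy↔mOFC cycle combined with training-related gain increase must remain
  dissipative (largest real eigenvalue of `A + B1 + B2` stays below zero
  for every group, run, and jittered participant).

Integration uses a fixed step (`integration_dt`, default 0.1 s) with
Heun's predictor–corrector for the drift and an additive Euler–Maruyama
noise increment (`neural_noise_sd`, default 0.03). A divergence guard
aborts with an explicit error if any state exceeds ±50.

## Hemodynamics and measurement

Latent states are observed through convolution with the canonical
double-gamma HRF (response peak 6 s, undershoot 16 s, unit dispersions,
peak:undershoot ratio 6, 32-s support, unit-peak normalised), sampled at
the end of each TR, plus Gaussian measurement noise (`obs_noise_sd`,
default 0.15 — roughly SNR 10–20 for the amygdala given typical simulated
signal amplitudes, and well above the SNR ≥ 2 regime where connectivity
recovery is tested). The gamma shapes are chosen so the kernel mode falls
exactly at the stated peak delay. A full balloon model is deliberately not
used: the offline analyses model the data with the canonical kernel, so
generating with the same kernel family keeps the simulation-analysis
relationship transparent; the cost is that hemodynamic nonlinearity and
regional HRF variability are not represented.

## The closed loop

Per TR during regulation blocks: (1) the currently displayed morph index —
lagged one volume, since a measurement can only influence the *next*
display — sets `u_int`; (2) states integrate across the TR; (3) the
amygdala observation enters the online chain (below); (4) the chain's
normalised output is mapped through the group's polarity to the next morph
index, `round(30·s)` with half-away-from-zero rounding. The first display
of a run is index 0; baseline blocks show a neutral display and have
`u_face = u_int = 0`, although the chain keeps processing every volume.
Baseline "mental counting" is modelled only as the absence of face input.

An instructed-regulation drive can be injected additively into the
amygdala during regulation blocks. The *effect scenario*
(`effect_scenario()`) sets its amplitude per group and run, a per-block
habituation decrement, and a per-run scaling of the modulatory matrices
(training-related connectivity change). The `"study"` preset encodes the
qualitative pattern the simulator targets — late-run amygdala decrease and
within-run habituation concentrated in the fear groups, growing FFA→Amy
gain in happy-up, declining gain in fear-down, and no psychometric change;
the `"null"` preset zeroes everything and is used for calibration studies.
Individual differences in neurofeedback success — a hallmark of the field —
are modelled by a per-participant efficacy factor drawn from N(1, 0.5)
(truncated to [0, 2]) that scales the regulation drive and its habituation;
this is what gives group-level slope tests and mixed models realistic
between-subject variance rather than near-degenerate random effects.
Psychometric scores (PANAS positive/negative, SDS) are plain numeric
pre/post outcomes with configurable post-shifts (zero by default).

## What the simulator does not emulate

No spatial structure (voxels, realignment, smoothing), no physiological
noise spectra or scanner drifts beyond what the chain's detrending is
asked to remove in tests, no balloon-model hemodynamics, no strategy or
attention dynamics, and no learning within the simulator itself — run
effects exist only where the scenario injects them. Passing tests
therefore demonstrate the *internal* correctness and statistical
calibration of the pipeline under a known generative model, not that the
pipeline would behave identically on real data.

# The online chain

The feedback signal is processed causally, one volume at a time, in the
order: spike removal → drift removal → AR(1) → dynamic-range scaling.
The stage order follows the order in which these steps are conventionally
listed for this pipeline; published descriptions do not pin down the exact
filter constants, so they are explicit configuration here
(`chain_settings()`):

* **Kalman de-spiking** — scalar random-walk state model; process variance
  0.05 and observation variance 0.25, calibrated so a flat stream
  converges within about ten samples. A sample whose innovation exceeds
  1.96 innovation-SDs is flagged, replaced by the one-step prediction, and
  the gain damped by 0.1. Setting the observation variance to 0 yields an
  exact pass-through.
* **Cumulative GLM detrend** — expanding-window least squares of all
  samples so far on constant + linear trend; the residual of the current
  sample is passed on. With fewer than three samples the fit is the
  running mean. Incremental sufficient statistics make this O(1) per
  volume and exactly equal to batch least squares on the same window.
* **AR(1)** — running lag-1 autocorrelation estimate (clipped at ±0.95),
  whitening each residual against its predecessor.
* **Dynamic-range scaling** — the unit-interval position of the whitened
  value between the running averages of the 5% lowest and 5% highest
  values seen so far (`ceil(0.05·n)` samples per tail, minimum one).
  Before 10 samples the bounds fall back to the running min/max. A
  degenerate range maps to 0.5, i.e. morph index 15, so the display never
  freezes at an extreme.

# The offline analysis chain

## Circularity-aware GLM

In a closed loop the stimulus depends on the measured target signal, so a
naive task regressor conflates regulation, stimulus response, and the
feedback source. The design therefore uses three regressors: x1, the
regulation boxcar convolved with the canonical HRF; x2, the normalised
feedback trace (what the participant actually saw, not the latent truth)
convolved with the kernel on the TR grid — a parametric modulator; and x3,
the residual of the normalised amygdala trace after regressing out
intercept, x1 and x2 — the feedback source independent of task and
stimulus response. x3 is orthogonal to x1 and x2 by construction
(`|corr| < 1e-6` is asserted on every simulated run); x2 is *not*
orthogonalised against x1, matching the residualise-only-x3 convention,
and the resulting collinearity risk is surfaced as an explicit rank error
in `fit_run_glm()`. Six motion nuisance columns complete the design.

## Block betas and habituation

Per run, the Kalman-processed amygdala trace is modelled with one
convolved boxcar per regulation block plus an intercept; the four block
coefficients are the block betas. Motion columns are excluded by default
(the processed trace is already cleaned) but can be included via a flag.
The within-run habituation slope is the least-squares line through the
four block betas against block index 1–4.

## Group statistics

Per condition (happy or fear), the per-run mean beta (mean of the four
block betas — the run-level reading is adopted because it makes the
denominator df of a two-group, four-run design come out near 90, matching
how such models are reported) is fitted with
`beta ~ run * group + (1 | participant)` by REML with Satterthwaite
denominator df (delegated to lmerTest), treatment-coded with run 1 and the
task-congruent group as references. Singular fits fall back to run-level
OLS with residual df and are flagged in the output. Habituation slopes get
per-group-and-run one-sample t-tests (df = n − 1), with an explicit
degenerate flag when the slope variance is zero. Psychometric scales are
fitted per scale and condition with `score ~ time * group +
(1 | participant)`. No multiple-testing correction is applied by default,
matching the uncorrected reporting convention; `add_holm()` is an opt-in.
Connectivity summaries are compared within group by paired t-tests (run 1
vs run 4) and between groups both by Welch's t-test and by a
"paired-style" statistic with df = n − 1 that plugs the two group
summaries into the two-sample formula — the convention the source
literature uses for such tables; both variants are always reported rather
than guessing intent.

# Reduced dynamic causal modelling

The DCM layer estimates the same bilinear model from data. The model space
toggles the seven optional connections on/off — 2^7 = 128 models — each
retaining self-connections and the V1 driving input; modulatory coupling
is restricted to the four amygdala edges and follows each model's
intrinsic mask (published descriptions do not state the modulation masks
separately, and the reported tables carry modulatory entries only on the
amygdala edges).

Inversion is a deliberately reduced scheme, not a port of the reference
implementation: one-state neural model, canonical-HRF observation with no
estimated hemodynamic parameters, independent Gaussian priors (mean 0,
variance 0.25 for off-diagonal A/B entries; mean −0.5, variance 0.25 for
self-connections; mean 0, variance 1 for driving inputs), MAP estimation
by Levenberg–Marquardt on the prior-augmented residual vector, per-region
noise variances re-estimated in a small outer loop, and a
Laplace-approximate log evidence `F = accuracy − complexity` with the
Gauss–Newton Hessian standing in for the posterior precision. Inversion is
deterministic: initialisation at the prior means, no random draws. Posterior
model probabilities are per-subject softmaxes of F under a uniform model
prior; the group weight of a model is the average of subject posteriors —
a documented simplification of the Dirichlet random-effects scheme, whose
exceedance machinery is out of scope. Model-averaged matrices sum absent
edges as zero, and "total" connectivity is `A + B1 + B2` elementwise. The
"±" spread reported alongside group totals is the between-subject SD and
is labelled as such.

Two caveats are documented rather than hidden: the instructed-regulation
drive used by some scenarios is not part of the DCM generative family, so
inversions of such runs absorb it into the amygdala couplings (chiefly
mOFC→Amy — which is also a plausible account of what happens when the
same model family is fitted to real regulation data); and with 240 volumes
the B1/B2 split on a given edge is only weakly identified because
`u_face` and `u_int` are correlated, which is why recovery is asserted on
totals.

# Numerical choices and degenerate inputs

* Morph rounding is half-away-from-zero so 0.5·30 = 15 on every platform;
  "30 steps" is read as 31 display states including both endpoints.
* Expanding-window detrend falls back to the running mean below three
  samples; out-of-order volume indices are an error, not a silent reset.
* `scale_to_unit()` returns 0.5 on a degenerate range; bounds fall back to
  min/max during warm-up.
* Rank-deficient designs name the collinear columns in the error; the x3
  builder residualises against the maximal independent subset with a
  warning instead of failing.
* The t statistic of identically-zero habituation slopes is reported as 0
  with p = 1; equal *nonzero* slopes are flagged degenerate.
* All per-run and per-participant seeds derive arithmetically from the
  master seed (kept below 2^31), so every artefact is reproducible from
  the configuration alone, and repeated generation is byte-identical.
* The printed block design accounts for 240 task seconds; the acquisition
  protocol it is modelled on records a few more volumes than that. The
  generator derives volume counts from the design and exposes optional
  `rest_pre`/`rest_post` padding rather than forcing a fixed acquisition
  count.

# Problem sizes used in the shipped checks

The test suite and the acceptance script run the full study geometry —
64 participants × 4 runs of 245 volumes — for structural and
orthogonalization checks; 2000 null and 500 effect replicates for mixed-
model calibration and power; 500 Monte-Carlo replicates for block-beta
bias; and a 16-subject, single-group, 8-model space (the structurally
richest models, always containing the full model) for connectivity
recovery. The 8-model space is the package's default for routine group
analyses, with the full 128-model space available behind a flag; model
evidence and averaging behave identically, only the computational budget
differs.

# Known limitations

Beyond the simulator's idealisations listed above: the online chain's
constants are package choices, not measured values from any deployed
system; the DCM inversion's free-energy values are comparable *within*
this implementation but not against other software; and between-group
"paired-style" t-tests are statistically unusual — they are provided for
comparability of output layout, with Welch's test alongside as the
defensible default.
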