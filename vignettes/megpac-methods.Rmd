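---
title: "Cross-regional alpha-gamma coupling and antidepressant response: models and methods"
author: "megpac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-regional alpha-gamma coupling and antidepressant response: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megpac)
```

## The scientific problem

Emotional visual input reaches the amygdala (AMG) along two routes: a fast
subcortical pathway through the thalamus (THA), active within roughly the
first 50 ms after a stimulus, and a slower cortical pathway through the
orbitofrontal cortex (OFC), active around 100--200 ms. In MEG recordings of
patients viewing sad faces, the interplay between these routes can be probed
with cross-regional phase-amplitude coupling (PAC): the degree to which the
phase of slow alpha oscillations (8--13 Hz) in a driver region modulates the
amplitude envelope of fast gamma activity (30--100 Hz) in the amygdala.
Attenuated coupling along both pathways distinguishes patients who will not
respond to a first course of SSRI treatment, and the per-patient strength of
the group-difference clusters correlates with the subsequent HAM-D-6
reduction ratio, making PAC a candidate baseline predictor of treatment
response.

`megpac` implements the full analysis chain -- preprocessing, source
reconstruction on a toy grid, time-frequency estimation, comodulograms,
cluster statistics, and ROC prediction -- together with a synthetic cohort
generator whose ground truth makes every stage verifiable at desk scale.

## The synthetic cohort generator

The generator (`simulationConfig()`, `simulateSubject()`,
`simulateCohort()`) uses the minimal model consistent with the phenomena the
analysis targets:

* each of the six regions (bilateral AMG, THA, OFC) carries unit-variance
  $1/f$ background noise (`noiseExponent`, default 1; the realized log-log
  spectral slope is within $\pm 0.3$ of its negative);
* the right THA and right OFC carry a sinusoidal alpha driver
  (`alphaFreq`, default 10 Hz) with trial-random phase and amplitude
  `alphaAmp` (default 1);
* the right AMG carries a gamma oscillation (`gammaFreq`, default 60 Hz)
  whose envelope inside each coupling window is
  $A_0\,(1 + \kappa\,\cos(\varphi_{\mathrm{driver}}(t) - \varphi_0))$ and
  $A_0$ elsewhere, with `gammaAmp` $= A_0$ (default 1) and the coupling
  windows 0--50 ms (thalamic phase) and 100--200 ms (orbitofrontal phase);
* non-responders additionally have their driver alpha multiplied by
  `alphaPowerAttenuation` (default 0.5) over 20--50 ms (rTHA) and
  110--145 ms (rOFC), reproducing the pathway-specific alpha deficits.

Modulation depths are `kappaByGroup` (responder 0.6, healthy control 0.6,
non-responder 0.2) with subject-level jitter `kappaSd` (default 0.1,
truncated to $[0,1]$). The jitter makes each subject's *realized* $\kappa$ a
meaningful individual quantity, which the clinical model then maps to the
HAM-D-6 reduction ratio: ratio $= 0.2 + 0.75\,\kappa + \varepsilon$,
$\varepsilon \sim N(0, 0.1^2)$, truncated to the side of the 50% responder
threshold that the subject's group demands and materialized as integer
baseline/endpoint scores. Group means of 0.35 (non-responders) and 0.65
(responders) straddle the threshold at a realistic distance, and the
positive coupling-improvement correlation the analysis should recover is
present by construction. Labels are always consistent with the
$\geq 50\%$ rule applied to the recorded scores, so the default cohort is
exactly 33 non-responders, 32 responders and 29 controls.

Amplitude defaults deserve a note: emotional-face paradigms show strong
gamma and comparatively weak alpha activation in these regions, so the gamma
carrier is given the same amplitude as the alpha driver. At lower gamma SNR
the injected coupling in the 0--50 ms window -- which spans only half an
alpha cycle, so the coherence noise floor is governed by the trial count --
would sink below the floor at 40 trials, defeating the generator's purpose
of providing recoverable ground truth.

`preStimS` (default 0.5 s) prepends pre-stimulus samples. Four-cycle
low-frequency analysis windows centered 20 ms after onset necessarily
extend before the stimulus; with the padding they are computable, without it
those bins are reported missing. Inter-stimulus intervals are not simulated:
epochs are already cut.

A toy forward model (`toyLeadField()`, `projectToSensors()`) maps ROI series
to sensors through a random unit-norm gain matrix with configurable
sensor-level SNR. It preserves exactly the algebra that source
reconstruction needs -- no head geometry, dipole physics or artifacts.

## Preprocessing

`notchBandpass()` removes the 50-Hz line and restricts to 1--100 Hz with
exactly zero phase. The default implementation multiplies the epoch spectrum
by a raised-cosine pass mask and stop notch. On finite epochs this is the
only family we found that realizes the nominal response: forward-backward
IIR filtering (including steady-state initialization and Gustafsson-style
edge handling) leaves notch-ring transients of several percent RMS at the
epoch edges, because a narrow band-stop rings longer than the epoch can
absorb. The FFT mask has no start-up transient, is exactly linear, and
attenuates an on-bin line component to numerical precision. A conventional
Butterworth path (2nd-order stop + 4th-order pass, forward-backward with
steady-state initial conditions and long odd-reflection padding) is kept
behind `method = "butterworth"` for comparison; the two agree in the
passband interior to better than 2%.

`rejectHighVariance()` computes log-variance per trial (pooled over
channels) and per channel (pooled over trials) and iteratively removes the
single worst entry whose robust z-score (median/MAD, two-sided) exceeds 3,
so both blown-up trials and dead channels are caught. The threshold is
scale-free and exposed; samples are never modified, only rows/columns
dropped.

## Source reconstruction and leakage control

`lcmvFilters()` builds the linearly constrained minimum-variance beamformer
$w_s = (l_s^\top C_r^{-1} l_s)^{-1} l_s^\top C_r^{-1}$ with diagonal loading
$C_r = C + 0.05\,\overline{\mathrm{diag}(C)}\,I$ (5% of mean sensor
variance, configurable; toy grids are well conditioned, so the default is
uncritical). The covariance is estimated from the whole epoch, all trials
pooled -- the most sample-efficient choice at desk scale. Scalar
(fixed-orientation) beamforming only: the toy lead fields are
fixed-orientation by construction.

`applyFilters()` aggregates member sources into ROI series by sign-aligned
averaging: each member is flipped to correlate positively with the ROI's
first principal direction before averaging, since lead-field column signs
are anatomically arbitrary and a plain mean can cancel. The overall polarity
is anchored to the plain member mean where informative and remains
arbitrary otherwise -- harmless downstream, because the PAC statistic is
invariant to constant phase rotations. A first-principal-component
aggregation is available (`aggregate = "pc1"`), since the ROI series
definition underlying published cross-regional PAC work is typically left
open; ROI *power* is defined separately (`roiPower()`) as the mean of
member-source powers.

`symmetricOrthogonalize()` removes zero-lag leakage correlations: it finds
the set of mutually uncorrelated region series closest to the input in total
squared error, by alternating the closest-orthonormal-matrix step (polar
decomposition via SVD of the scaled, demeaned, pooled time $\times$ regions
matrix) with per-region least-squares rescaling, to a relative objective
change below $10^{-9}$ (max 100 iterations; typical instances converge in
fewer than 15). No region is privileged, the map is idempotent, and
rank-deficient inputs fail with the offending region pair named. A
brute-force rotation-parameterized optimizer in the test suite confirms the
minimizer on small instances.

## Time-frequency estimation

`tfrHanning()` (1--30 Hz) uses the adaptive rule of four cycles per
frequency under a Hanning taper; `tfrMultitaper()` (30--100 Hz) uses three
Slepian tapers on a fixed 50-ms window. Three well-concentrated tapers force
a time-bandwidth product $NW = 2$ (by $K = 2NW - 1$), i.e. $\pm 40$ Hz
spectral smoothing at this window length. That smoothing dominates the gamma
axis: a pure 60-Hz sine produces an 80-Hz-wide plateau whose ripple
($\sim$7%) decides the argmax, so the carrier bin can only be asserted to
lie within ripple of the plateau maximum, and the 2-Hz default grid step
loses nothing. Power is normalized as one-sided PSD
($2|c|^2 / (f_s \sum h^2)$), so broadband white noise of unit variance
averages to $2/f_s$ per hertz. Time bins step 5 ms by default; bins whose
window does not fit in the epoch are missing (`NA`), never zero, and missing
values propagate. No baseline correction is applied anywhere; raw power is
analyzed and `normalizeSpectrum()` (division by the 1--100 Hz total) exists
only for the spectrum summary statistic.

## Phase-amplitude comodulograms

`phaseEnvelope()` band-passes the full epoch with an FFT-domain
raised-cosine mask and takes the analytic signal in the same transform,
then windows afterwards -- the only defensible order given 50-ms analysis
windows (half an alpha cycle; per-window filtering would be meaningless).
Phase bands are $f_p \pm 1$ Hz. Amplitude bands are
$f_a \pm \max(2, 1.2 \times \max f_p)$ Hz (15.6 Hz for the default grids):
the half-width must exceed the phase frequency or the modulation sidebands
at $f_a \pm f_p$ -- the very evidence of coupling -- are filtered out.

`pacCoherence()` quantifies coupling as the coherence between the unit
phasor of the slow phase and the fast envelope, pooled over window samples
and trials:

$$\mathrm{PAC} \;=\; \frac{\bigl|\sum_t \mathrm{env}(t)\,
e^{-i\varphi(t)}\bigr|}{\sqrt{N \sum_t \mathrm{env}(t)^2}} \in [0, 1].$$

It is bounded by Cauchy-Schwarz, invariant to phase rotation and envelope
scaling, and has a closed form for cosine modulation:
$\mathrm{env} = 1 + \cos\varphi$ with uniform phase gives
$\tfrac{1}{2}/\sqrt{3/2} = 1/\sqrt{6} \approx 0.408$, which the tests pin.
A normalized mean-vector-length variant
($|\langle \mathrm{env}\,e^{-i\varphi}\rangle| / \langle \mathrm{env}\rangle$)
is available as `estimator = "mvl"` for cross-checking. Trials are pooled,
not averaged per trial: a 50-ms window holds too few samples for stable
per-trial estimates. For the 0--50 ms window the pooled-phase noise floor is
approximately $1/\sqrt{n_{\mathrm{trials}}}$, since each trial contributes
only half an alpha cycle -- the reason comodulogram statistics are always
interpreted against permutation or group references, never absolutely.

`comodulogram()` fills the full grid (default 8--13 Hz step 1 $\times$
30--100 Hz step 1; the statistics default to restricting the amplitude axis
to 30--80 Hz) for one ordered region pair and window. The statistic is
deliberately asymmetric: phase comes from the driver region, envelope from
the amygdala.

## Group statistics

`pointwiseFFdr()` runs a fixed-effects one-way F test per time bin across
the three groups, with Benjamini-Hochberg correction (via `p.adjust`) at
$q = 0.05$ across bins; zero-variance bins are flagged and excluded from the
FDR family. `posthocT()` applies pooled-variance two-sample t tests on
surviving bins.

`clusterPermutation()` implements the nonparametric cluster test on
comodulogram maps: per-bin pooled t (group A $-$ B), two-sided
cluster-forming threshold at $\alpha = 0.05$, clusters of 4-connected bins
separately by sign, cluster mass = sum of t, and a max-|mass| null over 1000
label shuffles by default. The p-value convention $(1 + b)/(1 + P)$ counts
the observed labeling, so $p \geq 1/(P+1)$ and exact exchangeability is
honest. Group labels are shuffled pairwise (non-responder vs responder,
etc.), each contrast with its own null, because the reported contrasts are
pairwise; a joint three-group shuffle is a documented alternative reading.
`clusterMeanStrength()` averages a subject's comodulogram over a cluster's
bins -- the per-subject feature carried into prediction.

## Response prediction

`reductionRatio()` and `classifyResponse()` implement the
$(\mathrm{baseline} - \mathrm{endpoint})/\mathrm{baseline}$ ratio and the
boundary-inclusive $\geq 50\%$ responder rule. `exclusionCascade()` tracks
enrollment arithmetic. `correlateFeatures()` computes Pearson correlations
of cluster strengths with reduction ratios -- over patients only, since
controls have no ratio. `combineAndRoc()` takes "linear regression"
literally: an OLS fit of the two features on the binary non-responder
indicator supplies the score; AUC is the trapezoid over all thresholds and
the operating point maximizes Youden's J. The AUC is in-sample and is
reported as such -- with two fitted features it is upward-biased under the
null (about 0.58 at $n = 65$) -- and single-feature curves are reported
alongside the combination. `demographicsTable()` reproduces the
Table-1-style comparisons: one-way ANOVA (raw or via `anovaFromSummary()`
from mean/SD/n), Pearson chi-square without continuity correction, and
pooled two-sample t for patient-only scores.

## Orchestration and reproducibility

`pipelineConfig()` / `runPipeline()` chain simulate $\to$ preprocess $\to$
(optional sensor-projection/beamformer/orthogonalization round trip) $\to$
comodulograms $\to$ cluster tests $\to$ features $\to$ correlation and ROC.
Every stage draws from substreams derived deterministically from the single
master seed, so a rerun with the same config is numerically identical;
unknown configuration keys are rejected by name; intermediate results are
persisted as CSV when `outDir` is set. If a window yields no significant
negative cluster, the largest negative cluster (or, failing that, all
negatively shifted bins) is used for feature extraction and flagged.

```{r example, eval = FALSE}
run <- runPipeline(pipelineConfig(
  seed = 1,
  simulate = list(nTrials = 20, fs = 300, epochLenS = 1.0, preStimS = 0.2),
  cfc = list(ampFreqs = seq(30, 100, 2)),
  stats = list(P = 200)))
print(run)
```

## Verification protocol and problem sizes

The test suite validates each stage against independent oracles (closed
forms, brute-force optimizers, `pROC`, hand-enumerated BH masks) and runs
stochastic recovery checks at desk scale: 300 Hz sampling, 1.2-s epochs,
20--40 trials, full cohort structure 33/32/29, and 200 permutations for
permutation tests. These sizes keep the whole suite in the minutes range
while leaving all statistical conclusions comfortably powered; the same
protocol is recomputed from scratch by `scripts/acceptance.R`. Cluster-test
calibration uses 200 replicate null cohorts of 10 subjects per group;
injected-coupling localization and end-to-end recovery use 10--20 seeded
replicates.

## Limitations

Synthetic cohorts are deliberately minimal: sinusoidal drivers, a single
carrier, additive $1/f$ noise, no artifacts, no anatomy, no inter-subject
spectral variability beyond the coupling depth, and a linear clinical model.
Passing the recovery suite demonstrates that the *pipeline* is correct and
calibrated -- not that real MEG data carry effects of this size. The
published patient-data quantities (cluster p-values, correlation
coefficients of about 0.46, in-sample AUC 0.866) depend on unreleased
recordings and are not reproducible here; what the package reproduces
exactly is the cohort arithmetic and the Table-1 comparisons computable from
printed summaries, plus all method-level guarantees. Real-data users supply
their own epoched, artifact-cleaned sensor data (ICA is a manual,
inspection-driven step and is intentionally a no-op hook here) and an
anatomically meaningful lead field in place of the toy grid.
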