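---
title: "Methods: paradigm, observer model, and the two-level analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paradigm, observer model, and the two-level analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaeframes)
```

## The scientific problem

After a few tens of seconds of exposure to synchronous audio-visual
stimuli with a consistent spatial offset, auditory localization shifts
toward the visual side — the ventriloquism aftereffect (VAE). Because
audition is initially head-centred and vision eye-centred, the visual
"teaching signal" could be read out in either frame. The paradigm
implemented here dissociates them with three fixation conditions: with
central fixation (eye+head-consistent) the ±20° audio-visual disparity is
consistent in both frames; with fixation on the visual stimulus and audio
offset from 0° azimuth (eye-consistent) only the eye-centred disparity is
constant, while the head-centred one varies over ±30° around the offset;
with fixation on the visual stimulus and audio offset from it
(head-consistent) the converse holds. A fourth regime (variable
disparity) makes the disparity itself vary uniformly over the same ±30°
range in both frames, and factorially crossing adaptation durations of
35/70/105/140 s asks whether each frame's contribution changes with
exposure time.

`disparity_profile()` computes these per-event disparities in either
frame and is tested exhaustively over all 24 + 8 condition combinations:
the consistent frame yields a single value equal to the block offset, the
inconsistent frame seven equally frequent values at 10° spacing around
it, and the variable-disparity condition yields identical uniform
profiles in both frames.

## Schedule generation

One adaptation pass presents 5 × 500 ms stimuli (300 ms ISI) at each of 7
visual azimuths, with a 1 s interval after every set of five — counted
once per set including the last, because
7 × (5 × 0.8 s + 1 s) = 35 s is exactly the printed per-pass duration and
1–4 passes then give 35/70/105/140 s. Test phases draw each of their 10
azimuths independently and uniformly (with replacement) from the 13-point
±30°/5° grid; nothing in the design balances azimuths within a test
phase, and each test phase uses its own sampling stream (whether one
stream continues across cycles is unspecified in the design; independent
streams are the simpler reproducible choice). Block order is a uniform
random permutation per participant. The 10 s inter-cycle countdown and
inter-block breaks are recorded as metadata only — they play no role in
analysis. Degenerate requests (zero passes, unknown conditions,
off-grid disparities) fail immediately rather than returning empty
schedules.

## Stimulus synthesis and spatialization

The auditory stimulus is a 0.5 s pink-noise burst, band-limited to
100–4000 Hz, sampled at 44.1 kHz. Synthesis shapes white Gaussian noise
in the frequency domain with a $1/\sqrt{f}$ amplitude profile and
brick-wall band edges; the averaged periodogram slope is checked against
the −10 dB/decade pink target within ±1.5 dB/decade. Amplitude
modulation is a 6 Hz sinusoidal envelope in linear amplitude whose
peak-to-trough ratio is the depth in dB (3 dB default); the alternative
reading — a sinusoid in the dB domain — was considered and not used, as
the linear-envelope form makes depth 0 an exact identity and the
measured ratio exact. Raised-cosine gates of 25 ms
(`round(0.025 * 44100)` = 1102 samples, R's round-half-to-even) scale
only the edges.

Reverberation uses a 2-D (floor-plan) image-source model: the room is
specified by width and depth only, and the listener position only in the
plane, so ceiling/floor reflections are out of scope. The 4.2 × 5.2 m
room is oriented with 5.2 m left–right and 4.2 m front–back: the listener
sits on the midline 1.5 m from the back wall, leaving 2.7 m ahead and
±2.6 m laterally, so the whole ±90° source arc at 2.5 m lies strictly
inside the room — the opposite orientation would place sources beyond
±57° outside it. Wall absorbance 0.2 is an *energy* absorbance, giving a
pressure reflection coefficient $r=\sqrt{1-0.2}$ per bounce (so full
absorbance kills all reflections exactly). Each image source of total
order $k$ at distance $d$ contributes a pulse of amplitude $r^k/d$ at
delay $d/c$ ($c$ = 343 m/s, a fixed conventional value), placed at the
nearest sample — fractional-delay interpolation would buy at most 11 µs
of timing accuracy at 44.1 kHz and is omitted. Image enumeration is the
standard mirror lattice and is verified against a brute-force recursive
reflection oracle through order 5.

Binaural rendering convolves the room impulse response with a
same-azimuth head-related impulse response for all reflections — the
"reverberant HRTF" construction, in which reflections do not get
direction-specific filters. The built-in HRIR set is a synthetic
spherical-head model: interaural delay from Woodworth's formula
$\tau = (a/c)(\theta + \sin\theta)$ with $a$ = 8.75 cm, and a
contralateral head-shadow low-pass implemented as a one-pole filter run
forward and backward (zero phase, so the interaural lag measured by
cross-correlation equals the placed ITD) with strength proportional to
$|\sin\theta|$ — identically transparent at 0°, where the two ears must
match. Measured HRIRs can be substituted from per-azimuth stereo WAV
files; they are used as-is, at any length. Output levels are normalized
to 0.9 peak; absolute playback calibration (dB SPL) is outside numerical
scope.

## The synthetic observer

The generator exists to produce data with exactly the statistical
structure the analysis assumes, plus the contaminants the robust step
must handle:

| parameter | default | units | role |
|---|---|---|---|
| gain $g$ | 0.9 ± 0.1 | – | slope of response on azimuth |
| bias $b$ | 0 ± 2 | deg | baseline intercept |
| asymptote $M_c$ | 6 / 4.5 / 4.5 / 5 (± 1) | deg | full −20>+20 contrast at saturation (eye+head, eye, head, variable) |
| time constant $\tau_c$ | 30 / 60 / 60 / 40 (± 0.2 log) | s | saturation rate of the shift |
| response SD $\sigma$ | 5 | deg | Gaussian localization noise |
| outlier rate | 0.03 | – | uniform lapses over ±90° |

A response is $r = g a + b -\operatorname{sign}(\delta)\,
\frac{M_c}{2}\bigl(1-e^{-T/\tau_c}\bigr) + \varepsilon$ for disparity
$\delta=\pm20°$ and adaptation duration $T$. Exponential saturation is a
modelling choice: the empirical literature reports that the VAE
approaches saturation over this range without committing to a functional
form, and the exponential is the simplest curve with an interpretable
asymptote and rate. The shift is constant across test azimuths (bias,
not gain, changes — matching the finding that gain differences are
null), and no inter-cycle carryover or within-test decay is modelled
(per-cycle analyses found no cycle effects); the cycle tag in the trial
table is the hook for adding either later. Asymptote magnitudes sit in
the few-degrees range typical of this paradigm and are ordered eye+head >
eye = head with slower accumulation for the single-frame conditions;
they are plausible round numbers, never estimates of any particular
dataset. Localization blur psychometrics, eye movements, and response
times are not simulated.

What passing tests on these data do show: the pipeline's estimators are
unbiased for the generative bias/gain/VAE structure, the robust step
rejects at its nominal rate, and the ANOVA engines hold their error
rates. What they cannot show: robustness to real-data features the
generator omits — heteroscedastic noise across eccentricity, compressive
response nonlinearity, serial dependence, motor drift.

## First level: robust rejection and regression

Outliers are flagged per participant × condition in the bivariate
(stimulus, response) plane using a robust Mahalanobis distance. The
robust location/scatter estimator is the minimum covariance determinant
with subset fraction 0.75 (the procedure behind the published robust
distance metric is not spelled out; MCD is the standard choice and is
documented as such), and squared distances are compared with the
$\chi^2_2$ quantile at $1-\alpha$, $\alpha = .01$. On clean Gaussian data
this flags roughly 1–2% of trials (MCD distances are mildly
conservative at these sizes); planted gross outliers at ~10 robust SDs
are always removed. Singular robust scatter falls back to the classical
covariance with a warning; if that is singular too, nothing is rejected.
$\alpha$ = 0 (or NULL) disables the step entirely, which is how clean
simulation studies skip its cost honestly. Bias and gain are the
intercept and slope of per-cell OLS (`stats::lm`), with standard errors
verified against the closed-form normal equations; the −20 > +20
contrast of intercepts is the VAE magnitude, of slopes the gain change.
Rank-deficient cells (fewer than 3 kept trials or fewer than 2 distinct
azimuths) are errors naming the cell, never silently dropped.

## Second level: ANOVA engine and inference

The repeated-measures and mixed ANOVAs are computed from explicit sums
of squares on the subject × cell matrix (validated against the
`stats::aov` strata decomposition on toy tables): subject-by-effect
error terms for fully within designs; subjects-within-groups for the
between factor of the mixed design, which for groups of 20 and 12 gives
the F(1, 30) layout. Greenhouse-Geisser $\hat\varepsilon$ is computed per
effect from the orthonormal-contrast covariance of the subject data
(pooled within groups for the mixed design) and multiplies both dfs;
$\hat\varepsilon$ is clamped to $[1/(k-1), 1]$ and equals 1 for k = 2 and
under compound symmetry. Effect sizes are
$\eta^2_P = SS_e/(SS_e+SS_{err})$ and generalized $\eta^2_G$ with all
subject-variance terms in the denominator (the all-factors-manipulated
convention). Missing cells are an error — the designs are complete, and
imputation would change the error structure silently.

Calibration is checked on 2000 spherical Gaussian null simulations per
engine. Under such a null the *uncorrected* F is the exactly calibrated
test, and it is what the ±0.02 band is asserted on; the GG-corrected
test is additionally required never to exceed the uncorrected rejection
rate (it is conservative by design under sphericity — applying the band
to it would mistake its intended behaviour for miscalibration).

Post-hoc machinery: Holm step-down correction (`stats::p.adjust`);
paired/one-sample t-tests with Cohen's $d_z$ and Hedges'
$g_{av} = \bar d / \overline{s}\cdot J(n-1)$ using the exact
gamma-function small-sample correction; orthogonal polynomial duration
contrasts tested against the pooled subject × duration interaction error
with $(k-1)(n-1)$ df — for 4 durations and 20 subjects, t(57), matching
the printed df convention of this design; JZS Bayes factors for t-tests
by one-dimensional quadrature of the Cauchy-prior ($r=\sqrt2/2$) mixture
integral, validated against an independent noncentral-t quadrature
oracle. Bayes factors for ANOVA effects (multi-effect g-prior models)
are deliberately out of scope. Power for paired designs searches the
smallest $n$ whose noncentral-t power reaches the target; the G*Power
repeated-measures sample-size figure used in planning such designs
depends on undocumented software conventions and is intentionally not
reproduced. All tests are two-tailed with $\alpha = .05$ defaults,
configurable.

## Reproducibility and problem sizes

Every stochastic entry point takes an explicit seed; `run_pipeline()`
requires schedule/observer/analysis seeds in its config and emits a
provenance block (config hash, seeds, package version), with identical
configs producing byte-identical outputs. The test suite's simulation
studies use sizes chosen to bound their Monte-Carlo error meaningfully:
2000 replicates for ANOVA type-I calibration (binomial SE ≈ 0.5%), 200
full simulate→analyse replicates for the end-to-end null-interaction
rate (SE ≈ 1.5%), 60 replicates of 8-participant cohorts for estimator
unbiasedness, and a single 20-participant cohort at σ = 5° for parameter
recovery, mirroring the design's own sample size.

## Known limitations

- The acoustics are 2-D and the binaural model parametric; no torso,
  pinna, or elevation cues, and no measured-HRTF redistribution.
- SOFA HRIR containers are not read (no HDF5 reader among the package's
  dependencies); measured sets load from per-azimuth stereo WAV files.
- The mixed-effects variant of the first level (pooling participants in
  one regression) is not implemented; per-participant OLS is the primary
  route.
- The observer's adaptation dynamics are a one-exponential
  approximation; any study of the *shape* of VAE accumulation should
  treat $\tau_c$ as a nuisance, not a finding.
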