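# vaeframes

Tools for studying the **ventriloquism aftereffect (VAE)** — the persistent
shift in perceived auditory location that follows exposure to spatially
offset audio-visual stimuli — and in particular the question of *which
visual reference frame* (eye-centred or head-centred) drives that
recalibration, and how its contribution develops over adaptation durations
of 35–140 s.

The package is aimed at auditory/multisensory psychophysicists. It covers
the whole workflow:

- **Paradigm generation** (`generate_experiment()`, `generate_block()`,
  `generate_adapt_sequence()`): blocked fixation-condition ×
  adaptation-duration × disparity designs. Adaptation phases sweep visual
  azimuths −30°…+30° in 10° steps (5 × 500 ms presentations per azimuth,
  300 ms ISI, 1 s between sets, so one pass = 35 s), with the auditory
  stimulus offset ±20° relative to the visual stimulus (eye+head- and
  head-consistent), relative to 0° azimuth (eye-consistent), or with
  trial-varying offsets spanning ±30° around the mean (variable
  disparity). Test phases present 10 unimodal auditory trials drawn from a
  13-point ±30° grid; 4 adapt/test cycles per block.
- **Stimulus synthesis** (`make_stimulus()`): 500 ms pink-noise bursts
  (100–4000 Hz, −10 dB/decade), 6 Hz / 3 dB sinusoidal amplitude
  modulation, 25 ms raised-cosine gates, image-source room reverberation
  (rectangular 4.2 × 5.2 m room, absorbance 0.2, reflections to order 5,
  sources on a 2.5 m arc) and spherical-head binaural filters (Woodworth
  ITD, head-shadow low-pass) on a ±90°/5° azimuth grid; measured HRIRs can
  be loaded from per-azimuth stereo WAV files instead.
- **Observer simulation** (`simulate_dataset()`): responses
  `r = g·a + b + shift + ε`, with per-participant gain `g` and bias `b`,
  an adaptation shift that saturates exponentially with duration and whose
  sign follows the ±20° disparity, Gaussian response noise, and a small
  uniform outlier mixture.
- **Two-level analysis**: robust-Mahalanobis outlier rejection
  (MCD scatter, χ²₂ cutoff at p < .01), per participant × condition OLS of
  response on stimulus azimuth (`bias` = intercept, `gain` = slope), the
  −20° > +20° disparity contrasts (`vae_magnitude`, `gain_change`), then
  repeated-measures / mixed ANOVAs with Greenhouse-Geisser correction and
  ηP²/ηG², pairwise t-tests with Hedges *g*<sub>av</sub> and Holm
  correction, orthogonal polynomial duration trends tested on the pooled
  subject × duration error, JZS Bayes factors, and noncentral-*t* power
  computations.

## Worked example

```r
library(vaeframes)

sim <- simulate_dataset(1, n_participants = 20, seed = 301)
set.seed(401)
fl <- first_level_pipeline(sim$trials, alpha = 0.01)
sl <- second_level(fl$contrasts, experiment = 1)
sl$anova_vae[, c("effect", "df_num_gg", "df_den_gg", "f_value", "p_gg")]
```

Running the scripted version (`analysis/03…05`) prints:

```
Experiment 1: 480 cells fitted; 5.02% of trials rejected
  mean gain 0.911, mean VAE magnitude 3.92 deg
Experiment 1 VAE-magnitude ANOVA (Greenhouse-Geisser corrected):
  condition              F(1.92, 36.51) =  47.44, p(GG) = 0.0000, pes = 0.714, ges = 0.425
  duration_s             F(2.59, 49.27) =  30.30, p(GG) = 0.0000, pes = 0.615, ges = 0.233
  condition:duration_s   F(4.11, 78.15) =   2.31, p(GG) = 0.0639, pes = 0.108, ges = 0.039
Polynomial duration trends (pooled interaction error):
  linear     t(57) =  9.31, p = 0.0000
```

Reading: roughly 5% of trials are flagged by the robust distance rule
(3% simulated lapses plus the ~1–2% a χ² cutoff takes from clean data);
localization gain sits near the generative 0.9; the VAE magnitude — the
bias difference between the two adapting disparities — is positive in
every condition, larger under eye+head-consistent fixation (the
`condition` main effect), and grows with adaptation duration (the positive
linear trend), saturating per the observer's exponential dynamics.

The `analysis/` directory holds the full numbered workflow — schedules and
disparity profiles (`01`), rendered stimuli and room acoustics (`02`),
cohort simulation (`03`), first level (`04`), second level (`05`) — each
writing its tables under `results/`.

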