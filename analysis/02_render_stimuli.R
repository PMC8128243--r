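#!/usr/bin/env Rscript
# Render example spatialized stimuli and characterize the acoustics:
# pink-noise spectrum, AM depth, room impulse response, and binaural cues.

library(vaeframes)

dir.create("results", showWarnings = FALSE)
set.seed(202)

spec <- noise_spec()
room <- room_spec()
hrirs <- synth_hrir_set(seq(-90, 90, by = 5))

for (az in c(-30, 0, 30)) {
  st <- make_stimulus(az, spec, room, hrirs)
  out <- sprintf("results/stimulus_az%+03d.wav", az)
  write_wav(st$samples, st$fs_hz, out, bits = 16)
  cat("wrote", out, sprintf("(%.2f s stereo at %d Hz)\n",
                            nrow(st$samples) / st$fs_hz, st$fs_hz))
}

# spectral slope of the synthesized noise (average periodogram)
n <- round(spec$duration_s * spec$fs_hz)
f <- seq(0, n - 1) * spec$fs_hz / n
p <- 0
for (i in 1:40) p <- p + Mod(fft(synth_pink_noise(spec)))^2
inband <- f >= 150 & f <= 3500
slope <- 10 * unname(coef(lm(log10(p[inband]) ~ log10(f[inband])))[2])
cat(sprintf("In-band spectral slope: %.2f dB/decade (pink target: -10)\n",
            slope))

env <- apply_am(rep(1, n), spec$am_rate_hz, spec$am_depth_db, spec$fs_hz)
cat(sprintf("AM envelope depth: %.2f dB (target 3)\n",
            20 * log10(max(env) / min(env))))

# room impulse response properties across azimuth and absorbance
ir_rows <- do.call(rbind, lapply(c(-60, -30, 0, 30, 60), function(az) {
  ir <- build_room_ir(room, az)
  data.frame(azimuth = az, n_pulses = nrow(ir$pulses),
             direct_delay_ms = 1000 * ir$pulses$delay_s[1],
             energy = sum(ir$taps^2),
             itd_ms = 1000 * itd_woodworth(az))
}))
write.csv(ir_rows, "results/room_ir_properties.csv", row.names = FALSE)
cat("\nRoom IR / binaural cue summary:\n")
print(ir_rows, row.names = FALSE)
cat("\nThe direct path (2.5 m) arrives after",
    sprintf("%.2f ms;", 1000 * 2.5 / 343),
    "reflections up to order", room$max_reflections,
    "add", ir_rows$n_pulses[1] - 1, "later pulses.\n")
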