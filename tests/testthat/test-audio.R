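test_that("pink noise has the right length, band limits, and 1/f slope", {
  set.seed(1)
  spec <- noise_spec()
  x <- synth_pink_noise(spec)
  expect_length(x, 22050)
  expect_equal(max(abs(x)), 0.9)
  # averaged periodogram over realizations: in-band slope ~ -10 dB/decade
  n <- length(x)
  f <- seq(0, n - 1) * spec$fs_hz / n
  p_acc <- 0
  for (r in 1:40) p_acc <- p_acc + Mod(stats::fft(synth_pink_noise(spec)))^2
  inband <- f >= 150 & f <= 3500
  fit <- stats::lm(log10(p_acc[inband]) ~ log10(f[inband]))
  slope_db_per_decade <- 10 * unname(coef(fit)[2])
  expect_lt(abs(slope_db_per_decade - (-10)), 1.5)
  # power outside the passband is filtered out
  out_of_band <- f > 4300 & f < spec$fs_hz - 4300 | (f < 80 & f > 0)
  expect_lt(sum(p_acc[out_of_band]) / sum(p_acc), 0.01)
  expect_error(noise_spec(band_hz = c(100, 30000)), "Nyquist|band")
})

test_that("amplitude modulation has the stated envelope depth and rate", {
  carrier <- rep(1, 22050)
  expect_identical(apply_am(carrier, 6, 0, 44100), carrier)
  y <- apply_am(carrier, 6, 3, 44100)
  expect_equal(20 * log10(max(y) / min(y)), 3.0, tolerance = 0.1 / 3)
  # 6 Hz over 0.5 s -> envelope's dominant DFT bin at 3 cycles
  spec_bins <- Mod(stats::fft(y - mean(y)))[2:50]
  expect_equal(which.max(spec_bins) + 1 - 1, 3)
  expect_error(apply_am(carrier, 6, -1, 44100), ">= 0")
})

test_that("raised-cosine ramps gate the edges and leave the middle alone", {
  fs <- 44100
  x <- rep(1, 22050)
  y <- apply_ramps(x, 0.025, fs)
  nr <- round(0.025 * fs)
  expect_equal(nr, 1102)
  expect_equal(y[1], 0)
  expect_equal(y[length(y)], 0)
  expect_equal(y[ceiling(nr / 2)], 0.5, tolerance = 0.01)
  expect_identical(y[(nr + 1):(length(y) - nr)], x[(nr + 1):(length(y) - nr)])
  expect_error(apply_ramps(rep(1, 100), 0.025, fs), "longer")
})

test_that("image sources match a brute-force mirror enumeration", {
  room <- room_spec()
  src <- arc_source_xy(room, 17)
  expect_equal(nrow(image_sources(room, src, max_order = 0)), 1)
  expect_equal(nrow(image_sources(room, src, max_order = 1)), 5)
  for (ord in c(2, 3, 5)) {
    im <- image_sources(room, src, max_order = ord)
    oracle <- oracle_image_sources(room, src, ord)
    expect_equal(nrow(im), length(oracle))
    expect_setequal(paste(round(im$x, 9), round(im$y, 9), sep = ","), oracle)
  }
  expect_error(image_sources(room, c(10, 10)), "inside")
})

test_that("room IRs have closed-form direct delays and sane amplitudes", {
  room <- room_spec()
  ir <- build_room_ir(room, 0)
  expect_equal(ir$pulses$delay_s[1], 2.5 / 343)
  expect_equal(which(ir$taps != 0)[1], round(2.5 / 343 * 44100) + 1)
  expect_equal(which.max(ir$pulses$amplitude), 1)  # direct path dominates
  expect_equal(nrow(ir$pulses),
               nrow(image_sources(room, arc_source_xy(room, 0))))
  # full absorbance leaves only the direct pulse
  dead <- room_spec(absorbance = 1)
  expect_equal(nrow(build_room_ir(dead, 30)$pulses), 1)
  # IR energy decreases as walls absorb more
  energies <- vapply(seq(0.1, 0.9, 0.2), function(a)
    sum(build_room_ir(room_spec(absorbance = a), 20)$taps^2), numeric(1))
  expect_true(all(diff(energies) < 0))
})

test_that("spherical-head HRIRs encode Woodworth ITD and mirror symmetry", {
  expect_equal(itd_woodworth(90), 0.0875 / 343 * (pi / 2 + 1))
  expect_equal(itd_woodworth(0), 0)
  h0 <- spherical_head_hrir(0)
  expect_identical(h0$left, h0$right)
  for (az in c(15, 40, 90)) {
    hp <- spherical_head_hrir(az)
    hm <- spherical_head_hrir(-az)
    expect_identical(hp$left, hm$right)
    expect_identical(hp$right, hm$left)
  }
  expect_error(spherical_head_hrir(100), "90")
})

test_that("spatialize is linear, length-accounting, and preserves ITD", {
  set.seed(2)
  hr <- synth_hrir_set(seq(-90, 90, 5))
  room <- room_spec()
  w <- synth_pink_noise(noise_spec(duration_s = 0.1))
  s1 <- spatialize(w, 30, hr, room)
  expect_equal(ncol(s1), 2)
  ir_len <- length(build_room_ir(room, 30)$taps)
  expect_equal(nrow(s1), length(w) + ir_len + 256 - 2)
  expect_equal(spatialize(2 * w, 30, hr, room), 2 * s1)
  # anechoic room: interaural lag equals the rounded Woodworth ITD +/- 1
  dead <- room_spec(absorbance = 1)
  for (az in c(-60, 25, 80)) {
    s <- spatialize(w, az, hr, dead)
    cc <- stats::ccf(s[, 1], s[, 2], lag.max = 40, plot = FALSE)
    lag <- cc$lag[which.max(cc$acf)]
    expect_lte(abs(abs(lag) - round(itd_woodworth(az) * 44100)), 1)
    # leading ear is on the source side
    if (az > 0) expect_gt(lag, 0) else expect_lt(lag, 0)
  }
  expect_error(spatialize(w, 95, hr, room), "90")
})

test_that("the stimulus chain preserves sample count and renders stereo", {
  spec <- noise_spec()
  set.seed(3)
  x <- synth_pink_noise(spec)
  y <- apply_ramps(apply_am(x, spec$am_rate_hz, spec$am_depth_db,
                            spec$fs_hz), spec$ramp_s, spec$fs_hz)
  expect_length(y, length(x))
  st <- make_stimulus(10, spec, hrirs = synth_hrir_set(seq(-90, 90, 15)),
                      seed = 11)
  expect_equal(ncol(st$samples), 2)
  expect_equal(max(abs(st$samples)), 0.9)
  expect_equal(st$fs_hz, 44100)
})

test_that("WAV files round-trip and feed the measured-HRIR loader", {
  set.seed(4)
  x <- matrix(stats::runif(2000, -0.9, 0.9), ncol = 2)
  p16 <- withr::local_tempfile(fileext = ".wav")
  p32 <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 44100, p16, bits = 16)
  write_wav(x, 44100, p32, bits = 32)
  r16 <- read_wav(p16); r32 <- read_wav(p32)
  expect_equal(r16$fs_hz, 44100)
  expect_equal(r16$samples, x, tolerance = 1 / 32000)
  expect_equal(r32$samples, x, tolerance = 1e-6)
  # loader: store spherical-head HRIRs as stereo WAVs and read them back
  dir <- withr::local_tempdir()
  azs <- c(-30, 0, 30)
  paths <- file.path(dir, sprintf("az%+04d.wav", azs))
  for (i in seq_along(azs)) {
    h <- spherical_head_hrir(azs[i])
    write_wav(cbind(h$left, h$right), 44100, paths[i], bits = 32)
  }
  hs <- load_hrir_wav(paths, azs)
  expect_equal(hs$provenance, "loaded")
  expect_equal(hs$azimuths, azs)
  expect_equal(hs$left[[3]], spherical_head_hrir(30)$left, tolerance = 1e-6)
  expect_error(load_hrir_wav(file.path(dir, "nope.wav"), 0), "nope.wav")
})
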