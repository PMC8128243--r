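#' Parametric observer for localization responses
#'
#' The observer maps a stimulus azimuth `a` to a response
#' `r = g * a + b + shift + noise`, where `g` is the spatial gain
#' (regression slope), `b` the baseline bias (intercept), and `shift` the
#' adaptation-induced recalibration. The shift follows the visual-offset
#' direction and saturates exponentially with adaptation duration `T`:
#' `shift = -sign(disparity) * (M / 2) * (1 - exp(-T / tau))`, so the
#' -20 > +20 disparity contrast of the fitted biases equals
#' `M * (1 - exp(-T / tau))` -- `M` is the full contrast at saturation.
#' `M` and `tau` are per fixation condition; the shift is constant across
#' test azimuths (adaptation changes bias, not gain). With probability
#' `outlier_rate` a response is replaced by a uniform draw over
#' `outlier_range` (lapses / motor slips); otherwise Gaussian noise with
#' SD `response_noise_sd` is added.
#'
#' @param gain Unitless response slope.
#' @param bias Baseline response bias, degrees.
#' @param vae_asymptote Named vector: full disparity-contrast asymptote
#'   `M` per condition, degrees (>= 0).
#' @param vae_timeconstant Named vector: saturation time constant `tau`
#'   per condition, seconds of adaptation (> 0).
#' @param response_noise_sd Gaussian response noise SD, degrees (> 0).
#' @param outlier_rate Contamination probability in `[0, 0.5)`.
#' @param outlier_range Uniform outlier support `c(lo, hi)`, degrees.
#' @return Object of class `observer_params`.
#' @export
observer_params <- function(gain = 0.9, bias = 0,
                            vae_asymptote = c(eye_head_consistent = 6,
                                              eye_consistent = 4.5,
                                              head_consistent = 4.5,
                                              variable_disparity = 5),
                            vae_timeconstant = c(eye_head_consistent = 30,
                                                 eye_consistent = 60,
                                                 head_consistent = 60,
                                                 variable_disparity = 40),
                            response_noise_sd = 5, outlier_rate = 0.03,
                            outlier_range = c(-90, 90)) {
  if (response_noise_sd <= 0) stop("response_noise_sd must be > 0")
  if (outlier_rate < 0 || outlier_rate >= 0.5)
    stop("outlier_rate must be in [0, 0.5)")
  if (any(vae_asymptote < 0)) stop("vae_asymptote must be >= 0")
  if (any(vae_timeconstant <= 0)) stop("vae_timeconstant must be > 0")
  if (is.null(names(vae_asymptote)) || is.null(names(vae_timeconstant)))
    stop("vae_asymptote and vae_timeconstant must be named by condition")
  structure(list(gain = gain, bias = bias, vae_asymptote = vae_asymptote,
                 vae_timeconstant = vae_timeconstant,
                 response_noise_sd = response_noise_sd,
                 outlier_rate = outlier_rate, outlier_range = outlier_range),
            class = "observer_params")
}

#' Adaptation-induced response shift
#'
#' @param condition Fixation condition label.
#' @param duration_s Adaptation duration, seconds.
#' @param disparity Adapting disparity (-20 or +20 degrees).
#' @param params An [observer_params()].
#' @return Shift in degrees (positive rightward).
#' @export
adaptation_shift <- function(condition, duration_s, disparity, params) {
  M <- params$vae_asymptote[[condition]]
  tau <- params$vae_timeconstant[[condition]]
  -sign(disparity) * (M / 2) * (1 - exp(-duration_s / tau))
}

#' Simulate localization responses
#'
#' Vectorized over `stimulus_az`.
#'
#' @inheritParams adaptation_shift
#' @param stimulus_az Stimulus azimuths, degrees.
#' @return Response azimuths, degrees.
#' @export
simulate_response <- function(stimulus_az, condition, duration_s, disparity,
                              params = observer_params()) {
  shift <- adaptation_shift(condition, duration_s, disparity, params)
  n <- length(stimulus_az)
  r <- params$gain * stimulus_az + params$bias + shift +
    stats::rnorm(n, 0, params$response_noise_sd)
  out <- stats::runif(n) < params$outlier_rate
  if (any(out))
    r[out] <- stats::runif(sum(out), params$outlier_range[1],
                           params$outlier_range[2])
  r
}

#' Population-level observer specification
#'
#' Describes the distribution participants are drawn from: population-mean
#' parameters plus between-participant jitter. Gain and bias jitter are
#' Gaussian; asymptotes are Gaussian truncated at 0; time constants are
#' jittered on the log scale (they are positive and right-skewed).
#'
#' @param means An [observer_params()] holding the population means.
#' @param sd_gain,sd_bias,sd_asymptote Between-participant SDs.
#' @param sd_log_timeconstant SD of `log(tau)` jitter.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(means = observer_params(), sd_gain = 0.1,
                            sd_bias = 2, sd_asymptote = 1,
                            sd_log_timeconstant = 0.2) {
  stopifnot(inherits(means, "observer_params"))
  structure(list(means = means, sd_gain = sd_gain, sd_bias = sd_bias,
                 sd_asymptote = sd_asymptote,
                 sd_log_timeconstant = sd_log_timeconstant),
            class = "population_spec")
}

draw_participant <- function(pop) {
  m <- pop$means
  observer_params(
    gain = stats::rnorm(1, m$gain, pop$sd_gain),
    bias = stats::rnorm(1, m$bias, pop$sd_bias),
    vae_asymptote = pmax(0, stats::rnorm(length(m$vae_asymptote),
                                         m$vae_asymptote,
                                         pop$sd_asymptote)) |>
      stats::setNames(names(m$vae_asymptote)),
    vae_timeconstant = exp(stats::rnorm(length(m$vae_timeconstant),
                                        log(m$vae_timeconstant),
                                        pop$sd_log_timeconstant)) |>
      stats::setNames(names(m$vae_timeconstant)),
    response_noise_sd = m$response_noise_sd,
    outlier_rate = m$outlier_rate, outlier_range = m$outlier_range)
}

#' Simulate a full experiment cohort
#'
#' Draws `n_participants` observers from the population, gives each an
#' independently randomized block schedule (24 blocks for experiment 1, 8
#' for experiment 2, 40 test responses per block), and simulates all test
#' responses. Deterministic given `seed`.
#'
#' @param experiment 1 or 2.
#' @param n_participants Number of simulated participants (>= 2).
#' @param pop A [population_spec()].
#' @param seed Optional integer seed.
#' @return Object of class `vae_simulation`: list with `trials` (one row
#'   per test trial: participant, experiment, condition, duration_s,
#'   disparity, block_idx, cycle, trial_idx, stimulus_az, response_az),
#'   `participants` (per-participant parameter snapshot), and `pop`.
#' @export
simulate_dataset <- function(experiment, n_participants,
                             pop = population_spec(), seed = NULL) {
  if (n_participants < 2) stop("n_participants must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  all_trials <- vector("list", n_participants)
  snaps <- vector("list", n_participants)
  for (s in seq_len(n_participants)) {
    prm <- draw_participant(pop)
    sched <- generate_experiment(experiment, include_adapt = FALSE)
    rows <- lapply(seq_along(sched$blocks), function(b) {
      blk <- sched$blocks[[b]]
      sp <- blk$spec
      resp <- simulate_response(blk$tests$auditory_az, sp$condition,
                                sp$duration_s, sp$disparity, prm)
      data.frame(participant = s, experiment = experiment,
                 condition = sp$condition, duration_s = sp$duration_s,
                 disparity = sp$disparity, block_idx = b,
                 cycle = blk$tests$cycle_idx, trial_idx = blk$tests$trial_idx,
                 stimulus_az = blk$tests$auditory_az, response_az = resp)
    })
    all_trials[[s]] <- do.call(rbind, rows)
    snaps[[s]] <- data.frame(participant = s, gain = prm$gain,
                             bias = prm$bias,
                             condition = names(prm$vae_asymptote),
                             vae_asymptote = unname(prm$vae_asymptote),
                             vae_timeconstant = unname(prm$vae_timeconstant))
  }
  trials <- do.call(rbind, all_trials)
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 participants = do.call(rbind, snaps), pop = pop),
            class = "vae_simulation")
}
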