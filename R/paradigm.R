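#' Fixation conditions of the adaptation paradigm
#'
#' The paradigm manipulates which visual reference frame (eye-centred,
#' head-centred, or both) carries a spatially consistent audio-visual
#' disparity during adaptation. The three fixed-disparity conditions belong
#' to experiment 1; `"variable_disparity"` (disparities drawn uniformly
#' around the mean offset) belongs to experiment 2.
#'
#' @param experiment 1, 2, or NULL for all conditions.
#' @return Character vector of condition labels.
#' @export
vae_conditions <- function(experiment = NULL) {
  exp1 <- c("eye_head_consistent", "eye_consistent", "head_consistent")
  exp2 <- "variable_disparity"
  if (is.null(experiment)) return(c(exp1, exp2))
  if (experiment == 1) return(exp1)
  if (experiment == 2) return(exp2)
  stop("experiment must be 1 or 2")
}

VISUAL_AZIMUTHS <- seq(-30, 30, by = 10)   # adaptation grid, degrees
TEST_AZIMUTHS   <- seq(-30, 30, by = 5)    # unimodal test grid, degrees
DISPARITIES     <- c(-20, 20)              # audio offsets / mean offsets, degrees
ADAPT_DURATIONS <- c(35, 70, 105, 140)     # seconds, 1..4 passes

#' Timing parameters of an adaptation pass
#'
#' Defaults reproduce the paradigm timing: 500 ms audio-visual stimuli with
#' a 300 ms inter-stimulus interval, 5 consecutive presentations per
#' azimuth, a 1 s gap after each set of 5 (time to re-fixate), 7 visual
#' azimuths per pass, and a 200 ms inter-trial interval in test phases.
#'
#' @param stim_dur_s,isi_s,reps_per_set,interset_isi_s,n_azimuths,test_iti_s
#'   Timing fields; all strictly positive.
#' @return Object of class `timing_spec`.
#' @export
timing_spec <- function(stim_dur_s = 0.5, isi_s = 0.3, reps_per_set = 5,
                        interset_isi_s = 1.0, n_azimuths = 7, test_iti_s = 0.2) {
  spec <- list(stim_dur_s = stim_dur_s, isi_s = isi_s,
               reps_per_set = reps_per_set, interset_isi_s = interset_isi_s,
               n_azimuths = n_azimuths, test_iti_s = test_iti_s)
  if (any(vapply(spec, function(x) !is.numeric(x) || length(x) != 1 || x <= 0,
                 logical(1))))
    stop("all timing_spec fields must be positive scalars")
  structure(spec, class = "timing_spec")
}

#' Duration of an adaptation phase
#'
#' One pass visits each azimuth once as a set of `reps_per_set`
#' presentations; the inter-set interval is counted once per set, including
#' the last. With default timing one pass lasts
#' 7 x (5 x 0.8 s + 1 s) = 35 s, so 1--4 passes give 35/70/105/140 s.
#'
#' @param n_passes Positive integer number of passes over the azimuth grid.
#' @param timing A [timing_spec()].
#' @return Phase duration in seconds.
#' @export
phase_duration <- function(n_passes, timing = timing_spec()) {
  if (!is.numeric(n_passes) || length(n_passes) != 1 ||
      n_passes < 1 || n_passes != round(n_passes))
    stop("n_passes must be a positive integer")
  set_dur <- timing$reps_per_set * (timing$stim_dur_s + timing$isi_s) +
    timing$interset_isi_s
  n_passes * timing$n_azimuths * set_dur
}

#' Auditory offsets for the variable-disparity design
#'
#' Experiment 2 varies the audio offset trial-to-trial by up to 30 degrees
#' either side of the mean disparity in 10-degree steps, giving 7 offsets;
#' e.g. a -20 degree mean yields offsets -50 ... +10.
#'
#' @param mean_disparity -20 or +20 degrees.
#' @return Numeric vector of 7 offsets in degrees.
#' @export
exp2_offsets <- function(mean_disparity) {
  if (!mean_disparity %in% DISPARITIES)
    stop("mean_disparity must be -20 or +20")
  seq(mean_disparity - 30, mean_disparity + 30, by = 10)
}

#' Generate one adaptation sequence
#'
#' Each pass is a random permutation of the 7 visual azimuths, presented as
#' sets of 5 repetitions. Azimuth rules per condition (all angles
#' head-centred, positive rightward):
#' * `eye_head_consistent`: fixation at 0; audio at visual + offset.
#' * `eye_consistent`: fixation follows the visual stimulus; audio at
#'   0 + offset (so the audio is consistent with the eye-centred visual
#'   position but not the head-centred one).
#' * `head_consistent`: fixation follows the visual stimulus; audio at
#'   visual + offset.
#' * `variable_disparity`: fixation at 0; each pass uses each of the 7
#'   offsets `mean - 30 ... mean + 30` exactly once, one per set, in random
#'   order; audio at visual + offset.
#'
#' @param condition One of [vae_conditions()].
#' @param disparity Fixed offset (experiment 1) or mean offset (experiment
#'   2), -20 or +20 degrees.
#' @param n_passes Number of passes (1--4 in the study design; any positive
#'   integer accepted).
#' @param timing A [timing_spec()].
#' @return Data frame of adaptation events with onset times (seconds from
#'   phase start), visual/auditory/fixation azimuths, the per-event offset,
#'   and pass/set/rep indices.
#' @export
generate_adapt_sequence <- function(condition, disparity, n_passes,
                                    timing = timing_spec()) {
  condition <- match.arg(condition, vae_conditions())
  if (!disparity %in% DISPARITIES) stop("disparity must be -20 or +20")
  if (!is.numeric(n_passes) || n_passes < 1 || n_passes != round(n_passes))
    stop("n_passes must be a positive integer")

  set_dur <- timing$reps_per_set * (timing$stim_dur_s + timing$isi_s) +
    timing$interset_isi_s
  pass_dur <- timing$n_azimuths * set_dur
  reps <- timing$reps_per_set

  out <- vector("list", n_passes)
  for (p in seq_len(n_passes)) {
    vis <- sample(VISUAL_AZIMUTHS)
    offsets <- if (condition == "variable_disparity")
      sample(exp2_offsets(disparity)) else rep(disparity, length(vis))
    set_idx <- rep(seq_along(vis), each = reps)
    rep_idx <- rep(seq_len(reps), times = length(vis))
    visual_az <- vis[set_idx]
    offset <- offsets[set_idx]
    auditory_az <- if (condition == "eye_consistent") offset else
      visual_az + offset
    fixation_az <- if (condition %in% c("eye_consistent", "head_consistent"))
      visual_az else 0
    onset_s <- (p - 1) * pass_dur + (set_idx - 1) * set_dur +
      (rep_idx - 1) * (timing$stim_dur_s + timing$isi_s)
    out[[p]] <- data.frame(onset_s = onset_s, visual_az = visual_az,
                           auditory_az = auditory_az,
                           fixation_az = fixation_az, offset = offset,
                           pass_idx = p, set_idx = set_idx, rep_idx = rep_idx)
  }
  do.call(rbind, out)
}

#' Audio-visual disparity profile of an adaptation sequence
#'
#' Per-event disparity between the head-centred auditory azimuth and the
#' visual position expressed in the chosen reference frame. In the head
#' frame the visual position is its head-centred azimuth; in the eye frame
#' it is the eye-centred eccentricity (visual azimuth minus fixation
#' azimuth) combined directly with the head-centred auditory azimuth -- the
#' cross-frame pairing that defines the eye-centred disparity signal.
#'
#' @param events Data frame from [generate_adapt_sequence()].
#' @param frame `"head"` or `"eye"`.
#' @return Numeric vector of per-event disparities in degrees.
#' @export
disparity_profile <- function(events, frame = c("head", "eye")) {
  frame <- match.arg(frame)
  if (nrow(events) == 0) stop("events must be non-empty")
  v <- switch(frame,
              head = events$visual_az,
              eye  = events$visual_az - events$fixation_az)
  events$auditory_az - v
}

#' Block specification
#'
#' A block pairs one fixation condition with one adaptation duration and
#' one disparity, and comprises 4 cycles of alternating adaptation and test
#' phases with 10 unimodal test trials per cycle (40 responses per block).
#'
#' @param condition One of [vae_conditions()].
#' @param disparity -20 or +20 degrees (fixed offset, or mean offset for
#'   the variable-disparity condition).
#' @param n_passes Passes per adaptation phase (1--4); alternatively give
#'   `duration_s` as a multiple of one pass duration.
#' @param duration_s Adaptation phase duration in seconds (35/70/105/140
#'   under default timing). Supply either this or `n_passes`.
#' @param n_cycles,n_test_trials Cycles per block and test trials per cycle.
#' @param timing A [timing_spec()].
#' @return Object of class `block_spec`.
#' @export
block_spec <- function(condition, disparity, n_passes = NULL,
                       duration_s = NULL, n_cycles = 4, n_test_trials = 10,
                       timing = timing_spec()) {
  condition <- match.arg(condition, vae_conditions())
  if (!disparity %in% DISPARITIES) stop("disparity must be -20 or +20")
  one_pass <- phase_duration(1, timing)
  if (is.null(n_passes)) {
    if (is.null(duration_s)) stop("give n_passes or duration_s")
    n_passes <- duration_s / one_pass
    if (abs(n_passes - round(n_passes)) > 1e-9)
      stop("duration_s must be a multiple of one pass (", one_pass, " s)")
    n_passes <- round(n_passes)
  }
  if (n_passes < 1 || n_passes != round(n_passes))
    stop("n_passes must be a positive integer")
  structure(list(condition = condition, disparity = disparity,
                 n_passes = as.integer(n_passes),
                 duration_s = n_passes * one_pass,
                 n_cycles = as.integer(n_cycles),
                 n_test_trials = as.integer(n_test_trials),
                 timing = timing),
            class = "block_spec")
}

#' Generate one experimental block
#'
#' Produces the block's 4 cycles of adaptation events and test trials. Test
#' azimuths are drawn independently and uniformly (with replacement) from
#' the 13-point grid -30 ... +30 in 5-degree steps; each test phase has its
#' own sampling stream. The 10 s inter-cycle countdown is recorded as
#' metadata only.
#'
#' @param spec A [block_spec()].
#' @param include_adapt Generate the adaptation event table? Response
#'   simulation and analysis only need the test trials; skipping the event
#'   table speeds up large simulation studies.
#' @return Object of class `vae_block`: list with `spec`, `adapt` (events
#'   with a `cycle_idx` column, or NULL), `tests` (one row per test trial),
#'   and `countdown_s`.
#' @export
generate_block <- function(spec, include_adapt = TRUE) {
  stopifnot(inherits(spec, "block_spec"))
  adapt <- NULL
  if (include_adapt) {
    adapt <- do.call(rbind, lapply(seq_len(spec$n_cycles), function(cy) {
      ev <- generate_adapt_sequence(spec$condition, spec$disparity,
                                    spec$n_passes, spec$timing)
      cbind(cycle_idx = cy, ev)
    }))
  }
  nt <- spec$n_cycles * spec$n_test_trials
  tests <- data.frame(
    cycle_idx = rep(seq_len(spec$n_cycles), each = spec$n_test_trials),
    trial_idx = rep(seq_len(spec$n_test_trials), times = spec$n_cycles),
    auditory_az = sample(TEST_AZIMUTHS, nt, replace = TRUE),
    response_az = NA_real_)
  structure(list(spec = spec, adapt = adapt, tests = tests,
                 countdown_s = 10), class = "vae_block")
}

#' Generate a full experiment schedule
#'
#' Experiment 1 crosses 3 fixation conditions x 4 adaptation durations x 2
#' disparities (24 blocks); experiment 2 crosses 4 durations x 2 mean
#' disparities under the variable-disparity condition (8 blocks). Each
#' condition combination is allocated to exactly one block and block order
#' is fully randomised.
#'
#' @param experiment 1 or 2.
#' @param seed Optional integer seed; if given, the schedule is a pure
#'   function of it.
#' @param include_adapt Passed to [generate_block()].
#' @return Object of class `vae_schedule`: list with `experiment` and
#'   `blocks` (list of `vae_block` in presentation order).
#' @export
generate_experiment <- function(experiment, seed = NULL,
                                include_adapt = TRUE) {
  if (!experiment %in% c(1, 2)) stop("experiment must be 1 or 2")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(condition = vae_conditions(experiment),
                      n_passes = seq_along(ADAPT_DURATIONS),
                      disparity = DISPARITIES,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[sample(nrow(grid)), , drop = FALSE]
  blocks <- lapply(seq_len(nrow(grid)), function(i) {
    sp <- block_spec(grid$condition[i], grid$disparity[i],
                     n_passes = grid$n_passes[i])
    generate_block(sp, include_adapt = include_adapt)
  })
  structure(list(experiment = experiment, blocks = blocks),
            class = "vae_schedule")
}

#' Flatten a schedule to one tidy event table
#'
#' @param schedule A `vae_schedule`.
#' @return Data frame with one row per adaptation event and test trial
#'   (`phase` column distinguishes them), suitable for CSV export via
#'   [write_schedule_csv()].
#' @export
schedule_to_df <- function(schedule) {
  stopifnot(inherits(schedule, "vae_schedule"))
  rows <- lapply(seq_along(schedule$blocks), function(b) {
    blk <- schedule$blocks[[b]]
    sp <- blk$spec
    base <- data.frame(block_idx = b, condition = sp$condition,
                       duration_s = sp$duration_s, disparity = sp$disparity)
    parts <- list()
    if (!is.null(blk$adapt)) {
      a <- blk$adapt
      parts$adapt <- cbind(base[rep(1, nrow(a)), , drop = FALSE],
                           phase = "adapt", cycle_idx = a$cycle_idx,
                           onset_s = a$onset_s, visual_az = a$visual_az,
                           auditory_az = a$auditory_az,
                           fixation_az = a$fixation_az, offset = a$offset,
                           trial_idx = NA_integer_,
                           response_az = NA_real_)
    }
    t <- blk$tests
    parts$test <- cbind(base[rep(1, nrow(t)), , drop = FALSE],
                        phase = "test", cycle_idx = t$cycle_idx,
                        onset_s = NA_real_, visual_az = NA_real_,
                        auditory_az = t$auditory_az,
                        fixation_az = 0, offset = NA_real_,
                        trial_idx = t$trial_idx,
                        response_az = t$response_az)
    do.call(rbind, parts)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname schedule_to_df
#' @param path Output CSV path.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule_to_df(schedule), path, row.names = FALSE)
  invisible(path)
}
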