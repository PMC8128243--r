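TRIAL_COLUMNS <- c("participant", "condition", "duration_s", "disparity",
                   "cycle", "stimulus_az", "response_az")

validate_trials <- function(trials) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss)) stop("trial table lacks columns: ",
                         paste(miss, collapse = ", "))
  for (cl in c("stimulus_az", "response_az")) {
    bad <- which(!is.na(trials[[cl]]) & abs(trials[[cl]]) > 90)
    if (length(bad)) stop(cl, " outside +/-90 degrees at row ", bad[1])
  }
  bad <- which(!is.na(trials$cycle) & trials$cycle < 1)
  if (length(bad)) stop("cycle indices are 1-based; bad row ", bad[1])
  invisible(trials)
}

#' Read / write trial tables
#'
#' CSV schema: one row per unimodal test trial with columns `participant`,
#' `condition`, `duration_s`, `disparity`, `cycle` (1-based),
#' `stimulus_az`, `response_az` (signed decimal degrees, positive
#' rightward). Round trips are lossless; azimuths outside +/-90 degrees
#' are rejected with the offending row number.
#'
#' @param path CSV path.
#' @return `read_trials_csv()`: validated data frame.
#' @export
read_trials_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  validate_trials(utils::read.csv(path))
}

#' @rdname read_trials_csv
#' @param trials Trial table (data frame).
#' @export
write_trials_csv <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Reproducible run configuration
#'
#' All seeds are explicit (no wall-clock defaults); paths are validated
#' before any computation.
#'
#' @param experiment 1 or 2.
#' @param n_participants Cohort size.
#' @param seeds Named list with integer `schedule`, `observer`, and
#'   `analysis` seeds.
#' @param pop A [population_spec()].
#' @param alpha Outlier rejection criterion for the first level.
#' @param out_dir Output directory (created if absent).
#' @param hrir_dir Optional directory of measured per-azimuth stereo WAV
#'   HRIRs; must exist if given.
#' @return Object of class `run_config`.
#' @export
run_config <- function(experiment, n_participants, seeds, pop = population_spec(),
                       alpha = 0.01, out_dir, hrir_dir = NULL) {
  if (!experiment %in% c(1, 2)) stop("experiment must be 1 or 2")
  need <- c("schedule", "observer", "analysis")
  if (!is.list(seeds) || !all(need %in% names(seeds)) ||
      !all(vapply(seeds[need], function(s) is.numeric(s) && length(s) == 1,
                  logical(1))))
    stop("seeds must be a named list with integer schedule, observer, ",
         "and analysis entries")
  if (!is.null(hrir_dir) && !dir.exists(hrir_dir))
    stop("HRIR directory not found: ", hrir_dir)
  structure(list(experiment = experiment, n_participants = n_participants,
                 seeds = lapply(seeds[need], as.integer), pop = pop,
                 alpha = alpha, out_dir = out_dir, hrir_dir = hrir_dir),
            class = "run_config")
}

#' Second-level inference on disparity contrasts
#'
#' Experiment 1: one-sample t-tests of the VAE magnitude against zero per
#' fixation-condition x duration cell (Holm-corrected, with JZS Bayes
#' factors); two-way RM ANOVAs (fixation x duration, GG-corrected) of the
#' VAE magnitudes and of the gain changes; pairwise fixation t-tests
#' collapsed over durations (Holm, Hedges g_av, BF); and polynomial
#' duration contrasts. Experiment 2: one-sample t-tests per duration
#' (Holm) and a one-way RM ANOVA over duration.
#'
#' @param contrasts Contrast table from [first_level_pipeline()].
#' @param experiment 1 or 2.
#' @return Nested list of results keyed by effect name.
#' @export
second_level <- function(contrasts, experiment) {
  out <- list()
  cellkey <- interaction(contrasts$condition, contrasts$duration_s,
                         sep = "_", drop = TRUE)
  cells <- split(contrasts, cellkey)
  vs_zero <- lapply(cells, function(d)
    ttest_effects(d$vae_magnitude, kind = "one_sample", bf = TRUE))
  p_adj <- holm_adjust(vapply(vs_zero, `[[`, numeric(1), "p"))
  for (i in seq_along(vs_zero)) vs_zero[[i]]$p_holm <- unname(p_adj[i])
  out$vae_vs_zero <- vs_zero

  if (experiment == 1) {
    out$anova_vae <- rm_anova_two_way(contrasts, "vae_magnitude",
                                      "participant", "condition",
                                      "duration_s")
    out$anova_gain_change <- rm_anova_two_way(contrasts, "gain_change",
                                              "participant", "condition",
                                              "duration_s")
    # pairwise fixation-condition tests, collapsed over durations
    bysub <- stats::aggregate(vae_magnitude ~ participant + condition,
                              contrasts, mean)
    conds <- sort(unique(bysub$condition))
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    ph <- lapply(pairs, function(pr) {
      x <- bysub$vae_magnitude[bysub$condition == pr[1]]
      y <- bysub$vae_magnitude[bysub$condition == pr[2]]
      ttest_effects(x, y, kind = "paired", bf = TRUE)
    })
    names(ph) <- vapply(pairs, paste, character(1), collapse = "_vs_")
    p_adj <- holm_adjust(vapply(ph, `[[`, numeric(1), "p"))
    for (i in seq_along(ph)) ph[[i]]$p_holm <- unname(p_adj[i])
    out$pairwise_fixation <- ph
    bydur <- stats::aggregate(vae_magnitude ~ participant + duration_s,
                              contrasts, mean)
    out$duration_trends <- lapply(
      stats::setNames(nm = c("linear", "quadratic", "cubic")),
      function(o) polynomial_contrast(bydur, "vae_magnitude", "participant",
                                      "duration_s", order = o))
  } else {
    out$anova_vae <- rm_anova_one_way(contrasts, "vae_magnitude",
                                      "participant", "duration_s")
    out$anova_gain_change <- rm_anova_one_way(contrasts, "gain_change",
                                              "participant", "duration_s")
  }
  out
}

#' Constant- versus variable-disparity comparison
#'
#' Mixed-design ANOVA comparing the variable-disparity cohort (experiment
#' 2) with the eye+head-consistent condition of the constant-disparity
#' cohort (experiment 1): between-subjects factor disparity-type, within
#' factor adaptation duration.
#'
#' @param contrasts_constant Experiment-1 contrast table (its
#'   eye+head-consistent rows are used).
#' @param contrasts_variable Experiment-2 contrast table.
#' @return Mixed ANOVA table (see [mixed_anova()]).
#' @export
compare_disparity_type <- function(contrasts_constant, contrasts_variable) {
  cc <- contrasts_constant[contrasts_constant$condition ==
                             "eye_head_consistent", , drop = FALSE]
  cc$disparity_type <- "constant"
  cc$participant <- paste0("c", cc$participant)
  cv <- contrasts_variable
  cv$disparity_type <- "variable"
  cv$participant <- paste0("v", cv$participant)
  cols <- c("participant", "disparity_type", "duration_s", "vae_magnitude")
  mixed_anova(rbind(cc[cols], cv[cols]), "vae_magnitude", "participant",
              "disparity_type", "duration_s")
}

#' Run the full simulation-and-analysis pipeline
#'
#' Generation -> observer simulation -> first-level quantification ->
#' second-level inference, with all artifacts written to the configured
#' output directory: `schedule.csv` (an example single-participant
#' schedule), `trials.csv`, `estimates.csv`, `contrasts.csv`,
#' `stats.json` (results plus a provenance block with the config hash,
#' seeds, and package version), and `summary.txt`. Identical configs give
#' identical outputs.
#'
#' @param config A [run_config()].
#' @return The results list, invisibly (component `files` lists outputs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir))
    stop("cannot create output directory: ", config$out_dir)
  paths <- file.path(config$out_dir,
                     c(config_json = "config.json", schedule = "schedule.csv",
                       trials = "trials.csv", estimates = "estimates.csv",
                       contrasts = "contrasts.csv", stats = "stats.json",
                       summary = "summary.txt"))
  names(paths) <- c("config_json", "schedule", "trials", "estimates",
                    "contrasts", "stats", "summary")

  cfg_json <- list(experiment = config$experiment,
                   n_participants = config$n_participants,
                   seeds = config$seeds, alpha = config$alpha,
                   pop = unclass_deep(config$pop))
  jsonlite::write_json(cfg_json, paths["config_json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  config_hash <- unname(tools::md5sum(paths["config_json"]))

  sched <- generate_experiment(config$experiment,
                               seed = config$seeds$schedule)
  write_schedule_csv(sched, paths["schedule"])

  sim <- simulate_dataset(config$experiment, config$n_participants,
                          pop = config$pop, seed = config$seeds$observer)
  write_trials_csv(sim$trials, paths["trials"])

  set.seed(config$seeds$analysis)
  fl <- first_level_pipeline(sim$trials, alpha = config$alpha)
  utils::write.csv(fl$estimates, paths["estimates"], row.names = FALSE)
  utils::write.csv(fl$contrasts, paths["contrasts"], row.names = FALSE)

  sl <- second_level(fl$contrasts, config$experiment)
  report <- list(provenance = list(config_hash = config_hash,
                                   seeds = config$seeds,
                                   package_version =
                                     as.character(utils::packageVersion("vaeframes"))),
                 rejection_rate = fl$rejection_rate,
                 second_level = sl)
  jsonlite::write_json(report, paths["stats"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)

  av <- sl$anova_vae
  lines <- c(
    sprintf("vaeframes pipeline run (experiment %d, n = %d)",
            config$experiment, config$n_participants),
    sprintf("config hash: %s", config_hash),
    sprintf("trials: %d; outlier rejection rate: %.2f%%",
            nrow(sim$trials), 100 * fl$rejection_rate),
    "VAE-magnitude ANOVA (GG-corrected):",
    sprintf("  %s: F(%.2f, %.2f) = %.2f, p = %.4f, pes = %.3f, ges = %.3f",
            av$effect, av$df_num_gg, av$df_den_gg, av$f_value, av$p_gg,
            av$pes, av$ges))
  writeLines(lines, paths["summary"])

  invisible(c(report, list(first_level = fl, files = paths)))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
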