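#' Robust multivariate outlier rejection
#'
#' Flags trials whose (stimulus, response) pair is an outlier under a
#' robust Mahalanobis distance: location and scatter are estimated by the
#' minimum covariance determinant (MCD, subset size `ceiling(0.75 n)`) and
#' squared distances are compared to the chi-squared quantile with 2 df at
#' `1 - alpha`. If the robust scatter is singular the classical covariance
#' is used with a warning; if that is singular too, nothing is rejected.
#'
#' @param stimulus_az,response_az Paired trial vectors, degrees.
#' @param alpha Rejection criterion (default 0.01); `alpha = 0` or NULL
#'   disables rejection.
#' @return List with `keep` (logical), `d2` (squared robust distances),
#'   `threshold`, and `estimator` ("mcd", "classical", or "none").
#' @export
remove_outliers <- function(stimulus_az, response_az, alpha = 0.01) {
  n <- length(stimulus_az)
  stopifnot(length(response_az) == n)
  if (is.null(alpha) || alpha <= 0)
    return(list(keep = rep(TRUE, n), d2 = rep(0, n), threshold = Inf,
                estimator = "none"))
  if (n < 10) stop("need at least 10 trials for outlier rejection")
  x <- cbind(stimulus_az, response_az)
  est <- tryCatch({
    r <- MASS::cov.rob(x, method = "mcd",
                       quantile.used = ceiling(0.75 * n))
    if (!is.finite(determinant(r$cov)$modulus) ||
        determinant(r$cov)$modulus < log(1e-10)) stop("singular")
    list(center = r$center, cov = r$cov, estimator = "mcd")
  }, error = function(e) {
    warning("robust scatter estimation failed (", conditionMessage(e),
            "); falling back to classical covariance")
    cc <- stats::cov(x)
    if (!is.finite(determinant(cc)$modulus) ||
        determinant(cc)$modulus < log(1e-10)) NULL
    else list(center = colMeans(x), cov = cc, estimator = "classical")
  })
  if (is.null(est)) {
    warning("covariance singular; no trials rejected")
    return(list(keep = rep(TRUE, n), d2 = rep(0, n), threshold = Inf,
                estimator = "none"))
  }
  d2 <- stats::mahalanobis(x, est$center, est$cov)
  thr <- stats::qchisq(1 - alpha, df = 2)
  list(keep = d2 <= thr, d2 = d2, threshold = thr, estimator = est$estimator)
}

#' Per-condition bias/gain regression
#'
#' Ordinary least squares of response azimuth on stimulus azimuth: the
#' intercept is the spatial bias (degrees) and the slope the spatial gain
#' (unitless), each with its standard error.
#'
#' @param stimulus_az,response_az Paired trial vectors (after outlier
#'   rejection), degrees.
#' @return One-row data frame: `bias`, `gain`, `se_bias`, `se_gain`,
#'   `n_used`.
#' @export
fit_bias_gain <- function(stimulus_az, response_az) {
  n <- length(stimulus_az)
  if (n < 3) stop("need at least 3 trials to fit bias and gain")
  if (length(unique(stimulus_az)) < 2)
    stop("need at least 2 distinct stimulus azimuths (rank-deficient fit)")
  fit <- stats::lm(response_az ~ stimulus_az)
  cf <- summary(fit)$coefficients
  data.frame(bias = cf[1, 1], gain = cf[2, 1],
             se_bias = cf[1, 2], se_gain = cf[2, 2], n_used = n)
}

#' Disparity contrast of bias/gain estimates
#'
#' The -20 > +20 contrast: `vae_magnitude = bias(-20) - bias(+20)`
#' (positive = recalibration in the visual-offset direction) and
#' `gain_change = gain(-20) - gain(+20)`. Swapping the disparity labels
#' flips both signs.
#'
#' @param est_neg,est_pos Rows from [fit_bias_gain()] for the -20 and +20
#'   degree disparity conditions.
#' @return One-row data frame: `vae_magnitude`, `gain_change`.
#' @export
contrast_disparities <- function(est_neg, est_pos) {
  data.frame(vae_magnitude = est_neg$bias - est_pos$bias,
             gain_change = est_neg$gain - est_pos$gain)
}

#' First-level analysis pipeline
#'
#' For each participant x fixation-condition x duration x disparity cell:
#' robust outlier rejection, then the bias/gain regression; then the
#' -20 > +20 disparity contrast per participant x condition x duration.
#'
#' @param trials Trial table (columns `participant`, `condition`,
#'   `duration_s`, `disparity`, `cycle`, `stimulus_az`, `response_az`).
#' @param alpha Outlier rejection criterion; NULL or 0 disables the
#'   rejection step (useful for clean simulations).
#' @param cycles Optional vector of cycle indices to keep (the per-cycle
#'   re-analysis); NULL uses all trials.
#' @return List with `estimates` (per-cell bias/gain with `n_used`,
#'   `n_rejected`), `contrasts` (per participant x condition x duration),
#'   and `rejection_rate` (overall fraction rejected).
#' @export
first_level_pipeline <- function(trials, alpha = 0.01, cycles = NULL) {
  req <- c("participant", "condition", "duration_s", "disparity",
           "stimulus_az", "response_az")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trial table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!is.null(cycles)) {
    if (!"cycle" %in% names(trials)) stop("no cycle column to filter on")
    trials <- trials[trials$cycle %in% cycles, , drop = FALSE]
  }
  key <- interaction(trials$participant, trials$condition,
                     trials$duration_s, trials$disparity, drop = TRUE)
  parts <- split(trials, key)
  est <- do.call(rbind, lapply(parts, function(d) {
    ol <- remove_outliers(d$stimulus_az, d$response_az, alpha)
    fit <- fit_bias_gain(d$stimulus_az[ol$keep], d$response_az[ol$keep])
    cbind(d[1, c("participant", "condition", "duration_s", "disparity")],
          fit, n_rejected = sum(!ol$keep))
  }))
  rownames(est) <- NULL
  ckey <- interaction(est$participant, est$condition, est$duration_s,
                      drop = TRUE)
  contrasts <- do.call(rbind, lapply(split(est, ckey), function(e) {
    neg <- e[e$disparity == -20, , drop = FALSE]
    pos <- e[e$disparity == 20, , drop = FALSE]
    if (nrow(neg) != 1 || nrow(pos) != 1)
      stop("both disparities required for participant ", e$participant[1],
           ", ", e$condition[1], ", ", e$duration_s[1], " s")
    cbind(e[1, c("participant", "condition", "duration_s")],
          contrast_disparities(neg, pos))
  }))
  rownames(contrasts) <- NULL
  list(estimates = est, contrasts = contrasts,
       rejection_rate = sum(est$n_rejected) /
         (sum(est$n_used) + sum(est$n_rejected)))
}
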