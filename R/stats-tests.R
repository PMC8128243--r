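# Second-level t-tests, effect sizes, multiplicity, power, Bayes factors.

# Exact small-sample bias correction for standardized mean differences.
hedges_j <- function(df) exp(lgamma(df / 2) - log(sqrt(df / 2)) -
                               lgamma((df - 1) / 2))

#' t-test with paired-design effect sizes
#'
#' One-sample or paired two-tailed t-test reporting Cohen's d_z (mean
#' difference over the SD of the differences) and, for paired data,
#' Hedges' g_av: the mean difference divided by the average of the two
#' conditions' SDs, with the exact small-sample correction J(n - 1).
#'
#' @param x Values (one-sample) or first condition (paired).
#' @param y Second condition for `kind = "paired"`.
#' @param kind `"one_sample"` or `"paired"`.
#' @param mu Null value for the (difference in) means.
#' @param bf Also compute the JZS Bayes factor?
#' @return List: `t`, `df`, `p`, `d_z`, `g_av` (paired only, else NA),
#'   `bf10` (if requested), `n`, `mean_diff`.
#' @export
ttest_effects <- function(x, y = NULL, kind = c("one_sample", "paired"),
                          mu = 0, bf = FALSE) {
  kind <- match.arg(kind)
  if (kind == "paired") {
    stopifnot(!is.null(y), length(x) == length(y))
    d <- x - y
  } else d <- x
  n <- length(d)
  if (n < 2) stop("need at least 2 observations")
  md <- mean(d) - mu
  sd_d <- stats::sd(d)
  t <- if (sd_d == 0) {
    if (md == 0) 0 else sign(md) * Inf
  } else md / (sd_d / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  d_z <- if (sd_d == 0 && md == 0) 0 else md / sd_d
  g_av <- NA_real_
  if (kind == "paired") {
    s_av <- (stats::sd(x) + stats::sd(y)) / 2
    g_av <- if (s_av == 0 && md == 0) 0 else
      md / s_av * hedges_j(df)
  }
  out <- list(t = t, df = df, p = p, d_z = d_z, g_av = g_av, n = n,
              mean_diff = md)
  if (bf) out$bf10 <- jzs_bf_ttest(t, n)
  out
}

#' Holm-Bonferroni adjustment
#'
#' Step-down Holm correction (monotone, capped at 1).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Minimum n for a paired t-test at target power
#'
#' Smallest sample size whose two-tailed paired (equivalently one-sample)
#' t-test reaches the target power under the noncentral t distribution
#' with noncentrality `d_z * sqrt(n)` and `n - 1` df.
#'
#' @param d_z Cohen's d_z effect size (> 0).
#' @param alpha Two-tailed alpha criterion.
#' @param target_power Required power in (0, 1).
#' @param n_max Search limit.
#' @return Minimum n (integer).
#' @export
power_paired_t <- function(d_z, alpha = 0.05, target_power = 0.80,
                           n_max = 1e5) {
  if (d_z <= 0) stop("d_z must be > 0")
  if (alpha <= 0 || alpha >= 1 || target_power <= 0 || target_power >= 1)
    stop("alpha and target_power must be in (0, 1)")
  for (n in 2:n_max) {
    if (paired_t_power(n, d_z, alpha) >= target_power) return(n)
  }
  stop("no n <= ", n_max, " reaches the target power")
}

#' @rdname power_paired_t
#' @param n Sample size.
#' @return `paired_t_power()`: the power at that n.
#' @export
paired_t_power <- function(n, d_z, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, n - 1)
  ncp <- d_z * sqrt(n)
  stats::pt(tc, n - 1, ncp, lower.tail = FALSE) +
    stats::pt(-tc, n - 1, ncp)
}

#' Cohen's f from an ANOVA F statistic
#'
#' Via partial eta-squared: `eta_p^2 = df1 F / (df1 F + df2)` and
#' `f = sqrt(eta_p^2 / (1 - eta_p^2)) = sqrt(df1 F / df2)`.
#'
#' @param f_stat Observed F (>= 0).
#' @param df_num,df_den Numerator and denominator df (may be
#'   sphericity-corrected, hence non-integer).
#' @return Cohen's f.
#' @export
cohens_f_from_F <- function(f_stat, df_num, df_den) {
  if (f_stat < 0 || df_num <= 0 || df_den <= 0)
    stop("F must be >= 0 and dfs > 0")
  sqrt(df_num * f_stat / df_den)
}

#' Default (JZS) Bayes factor for a t statistic
#'
#' BF10 for a one-sample/paired (give `n1` only) or two-sample (give both)
#' t-test under the Jeffreys-Zellner-Siow default prior: a Cauchy prior
#' with scale `r` on the standardized effect size, integrated via the
#' inverse-gamma mixture representation in a one-dimensional quadrature.
#'
#' @param t Observed t statistic.
#' @param n1,n2 Group sizes (`n2 = NULL` for one-sample/paired).
#' @param r Cauchy prior scale (default sqrt(2)/2).
#' @return BF10 (> 0); values below 1 favour the null.
#' @export
jzs_bf_ttest <- function(t, n1, n2 = NULL, r = sqrt(2) / 2) {
  if (is.null(n2)) {
    N <- n1; nu <- n1 - 1
  } else {
    N <- n1 * n2 / (n1 + n2); nu <- n1 + n2 - 2
  }
  if (nu < 1) stop("need df >= 1")
  marg1 <- function(g)
    (1 + N * g)^(-0.5) *
    (1 + t^2 / ((1 + N * g) * nu))^(-(nu + 1) / 2) *
    (r^2 / 2)^0.5 / gamma(0.5) * g^(-1.5) * exp(-r^2 / (2 * g))
  num <- stats::integrate(marg1, 0, Inf, rel.tol = 1e-10)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num / den
}
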