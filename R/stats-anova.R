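# Repeated-measures and mixed ANOVA with Greenhouse-Geisser correction,
# partial and generalized eta-squared, and polynomial contrasts.

# Orthonormal contrast rows for a k-level factor (orthogonal to the
# constant); any orthonormal basis gives the same epsilon.
orth_rows <- function(k) t(stats::contr.poly(k))

# Greenhouse-Geisser epsilon from a covariance matrix and an orthonormal
# effect-contrast matrix.
epsilon_from_cov <- function(sigma, C) {
  M <- C %*% sigma %*% t(C)
  q <- nrow(C)
  ev <- sum(diag(M))^2 / (q * sum(M * M))
  min(1, max(1 / q, ev))
}

#' Greenhouse-Geisser epsilon
#'
#' Sphericity-correction factor computed from the covariance matrix of the
#' k within-subject conditions (double-centring form). Bounded by
#' `1/(k-1)` and 1; equals 1 under compound symmetry.
#'
#' @param sigma k x k covariance matrix of subject scores across
#'   conditions (or an n x k data matrix, from which the covariance is
#'   taken).
#' @return epsilon-hat.
#' @export
gg_epsilon <- function(sigma) {
  if (!is.matrix(sigma)) stop("sigma must be a matrix")
  if (nrow(sigma) != ncol(sigma)) sigma <- stats::cov(sigma)
  k <- ncol(sigma)
  if (k < 2) stop("need at least 2 conditions")
  epsilon_from_cov(sigma, orth_rows(k))
}

# Reshape a long table to a subjects x cells matrix with cells ordered by
# (levels of f1) x (levels of f2); errors on missing or duplicated cells.
wide_cells <- function(data, dv, subject, factors) {
  for (cl in c(dv, subject, factors)) {
    if (!cl %in% names(data)) stop("column not found: ", cl)
  }
  levs <- lapply(factors, function(f) sort(unique(data[[f]])))
  cell <- do.call(interaction,
                  c(lapply(rev(factors), function(f)
                    factor(data[[f]], levels = sort(unique(data[[f]])))),
                    list(drop = FALSE)))
  subj <- factor(data[[subject]])
  tab <- table(subj, cell)
  if (any(tab != 1))
    stop("design must be complete and balanced with one observation per ",
         "subject x cell (no imputation performed)")
  Y <- matrix(NA_real_, nlevels(subj), nlevels(cell),
              dimnames = list(levels(subj), levels(cell)))
  Y[cbind(as.integer(subj), as.integer(cell))] <- data[[dv]]
  list(Y = Y, levels = levs, k = vapply(levs, length, integer(1)))
}

anova_row <- function(effect, ss, df1, ss_err, df2, eps, ges_den) {
  ms <- ss / df1
  f <- ms / (ss_err / df2)
  data.frame(effect = effect, ss = ss, df_num = df1, df_den = df2,
             f_value = f,
             gg_epsilon = eps,
             df_num_gg = eps * df1, df_den_gg = eps * df2,
             p_uncorrected = stats::pf(f, df1, df2, lower.tail = FALSE),
             p_gg = stats::pf(f, eps * df1, eps * df2, lower.tail = FALSE),
             pes = ss / (ss + ss_err),
             ges = ss / (ss + ges_den))
}

#' Two-way repeated-measures ANOVA
#'
#' Fully within-subject two-factor ANOVA (one observation per subject x
#' cell): classical SS decomposition with subject-by-effect error terms,
#' Greenhouse-Geisser correction per effect (from the effect-contrast
#' covariance of the subject data), partial eta-squared, and generalized
#' eta-squared with the all-factors-manipulated convention (all
#' subject-variance terms in the denominator).
#'
#' @param data Long data frame.
#' @param dv,subject,factor_a,factor_b Column names.
#' @return Data frame (one row per effect) with SS, dfs, F, epsilon,
#'   uncorrected and GG-corrected p, and both eta-squared measures.
#' @export
rm_anova_two_way <- function(data, dv, subject, factor_a, factor_b) {
  w <- wide_cells(data, dv, subject, c(factor_a, factor_b))
  Y <- w$Y
  a <- w$k[1]; b <- w$k[2]; n <- nrow(Y)
  if (n < 2) stop("need at least 2 subjects")
  grand <- mean(Y)
  # cell means indexed [A, B]; columns of Y are A-major
  cellm <- matrix(colMeans(Y), nrow = b)        # rows = B, cols = A
  m_a <- colMeans(cellm); m_b <- rowMeans(cellm)
  m_s <- rowMeans(Y)
  idx_a <- rep(seq_len(a), each = b); idx_b <- rep(seq_len(b), times = a)
  m_sa <- t(apply(Y, 1, function(r) tapply(r, idx_a, mean)))
  m_sb <- t(apply(Y, 1, function(r) tapply(r, idx_b, mean)))
  ss_s  <- a * b * sum((m_s - grand)^2)
  ss_a  <- n * b * sum((m_a - grand)^2)
  ss_b  <- n * a * sum((m_b - grand)^2)
  ss_ab <- n * sum((t(cellm) - outer(m_a, m_b, "+") + grand)^2)
  ss_as <- b * sum((m_sa - outer(m_s, m_a, "+") + grand)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, m_b, "+") + grand)^2)
  ss_t  <- sum((Y - grand)^2)
  ss_abs <- ss_t - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
  sigma <- stats::cov(Y)
  u_a <- matrix(1 / sqrt(a), 1, a); u_b <- matrix(1 / sqrt(b), 1, b)
  C_a <- orth_rows(a); C_b <- orth_rows(b)
  eps_a  <- epsilon_from_cov(sigma, C_a %x% u_b)
  eps_b  <- epsilon_from_cov(sigma, u_a %x% C_b)
  eps_ab <- epsilon_from_cov(sigma, C_a %x% C_b)
  ges_den <- ss_s + ss_as + ss_bs + ss_abs
  out <- rbind(
    anova_row(factor_a, ss_a, a - 1, ss_as, (a - 1) * (n - 1), eps_a,
              ges_den),
    anova_row(factor_b, ss_b, b - 1, ss_bs, (b - 1) * (n - 1), eps_b,
              ges_den),
    anova_row(paste0(factor_a, ":", factor_b), ss_ab, (a - 1) * (b - 1),
              ss_abs, (a - 1) * (b - 1) * (n - 1), eps_ab, ges_den))
  attr(out, "ss_subjects") <- ss_s
  attr(out, "ss_total") <- ss_t
  out
}

#' One-way repeated-measures ANOVA
#'
#' @inheritParams rm_anova_two_way
#' @param within Within-subject factor column name.
#' @return Data frame with one row (the within effect), as in
#'   [rm_anova_two_way()].
#' @export
rm_anova_one_way <- function(data, dv, subject, within) {
  w <- wide_cells(data, dv, subject, within)
  Y <- w$Y
  k <- w$k[1]; n <- nrow(Y)
  grand <- mean(Y)
  m_w <- colMeans(Y); m_s <- rowMeans(Y)
  ss_s <- k * sum((m_s - grand)^2)
  ss_w <- n * sum((m_w - grand)^2)
  ss_t <- sum((Y - grand)^2)
  ss_err <- ss_t - ss_s - ss_w
  eps <- epsilon_from_cov(stats::cov(Y), orth_rows(k))
  out <- anova_row(within, ss_w, k - 1, ss_err, (k - 1) * (n - 1), eps,
                   ss_s + ss_err)
  attr(out, "ss_subjects") <- ss_s
  attr(out, "ss_total") <- ss_t
  out
}

#' Two-way mixed-design ANOVA
#'
#' One between-subjects factor (each subject in exactly one group; groups
#' may be unequal) crossed with one complete within-subjects factor. The
#' between effect is tested against subjects-within-groups; the within and
#' interaction effects against the pooled subject x within error, with a
#' Greenhouse-Geisser correction computed from the pooled within-group
#' covariance.
#'
#' @inheritParams rm_anova_two_way
#' @param between,within Column names of the between- and within-subjects
#'   factors.
#' @return Data frame with one row per effect (between, within,
#'   interaction).
#' @export
mixed_anova <- function(data, dv, subject, between, within) {
  grp_of <- tapply(data[[between]], data[[subject]],
                   function(g) {
                     u <- unique(g)
                     if (length(u) != 1)
                       stop("each subject must be in exactly one group")
                     u[1]
                   })
  w <- wide_cells(data, dv, subject, within)
  Y <- w$Y
  k <- w$k[1]; N <- nrow(Y)
  grp <- factor(grp_of[rownames(Y)])
  g <- nlevels(grp)
  if (g < 2) stop("need at least 2 groups")
  n_j <- as.vector(table(grp))
  grand <- mean(Y)
  m_s <- rowMeans(Y)
  m_grp <- tapply(m_s, grp, mean)
  m_w <- colMeans(Y)
  cell_jw <- do.call(rbind, lapply(split(as.data.frame(Y), grp), colMeans))
  ss_bs   <- k * sum((m_s - grand)^2)
  ss_g    <- k * sum(n_j * (m_grp - grand)^2)
  ss_swg  <- ss_bs - ss_g
  ss_w    <- N * sum((m_w - grand)^2)
  dev <- sweep(sweep(cell_jw, 1, m_grp, "-"), 2, m_w, "-") + grand
  ss_gw <- sum(n_j * rowSums(dev^2))
  ss_t <- sum((Y - grand)^2)
  ss_err_w <- ss_t - ss_bs - ss_w - ss_gw
  sigma_pooled <- Reduce(`+`, lapply(levels(grp), function(l) {
    Yl <- Y[grp == l, , drop = FALSE]
    (nrow(Yl) - 1) * stats::cov(Yl)
  })) / (N - g)
  eps <- epsilon_from_cov(sigma_pooled, orth_rows(k))
  ges_den <- ss_swg + ss_err_w
  out <- rbind(
    anova_row(between, ss_g, g - 1, ss_swg, N - g, 1, ges_den),
    anova_row(within, ss_w, k - 1, ss_err_w, (N - g) * (k - 1), eps,
              ges_den),
    anova_row(paste0(between, ":", within), ss_gw, (g - 1) * (k - 1),
              ss_err_w, (N - g) * (k - 1), eps, ges_den))
  attr(out, "ss_subjects_within_groups") <- ss_swg
  attr(out, "ss_total") <- ss_t
  out
}

#' Polynomial trend contrast over a within-subject factor
#'
#' Applies the orthogonal polynomial contrast of the requested order to
#' each subject's condition means and tests it against the pooled
#' subject x factor interaction error, with `(k - 1)(n - 1)` df (e.g.
#' df = 57 for k = 4 levels and n = 20 subjects).
#'
#' @inheritParams rm_anova_one_way
#' @param order `"linear"`, `"quadratic"`, or `"cubic"`.
#' @return List: `estimate` (mean contrast score), `t`, `df`, `p`
#'   (two-tailed).
#' @export
polynomial_contrast <- function(data, dv, subject, within,
                                order = c("linear", "quadratic", "cubic")) {
  order <- match.arg(order)
  w <- wide_cells(data, dv, subject, within)
  Y <- w$Y
  k <- w$k[1]; n <- nrow(Y)
  ord_idx <- match(order, c("linear", "quadratic", "cubic"))
  if (ord_idx > k - 1) stop("order exceeds k - 1")
  cf <- stats::contr.poly(k)[, ord_idx]
  scores <- as.vector(Y %*% cf)
  # pooled subject x within error from the one-way RM decomposition
  grand <- mean(Y)
  ss_w <- n * sum((colMeans(Y) - grand)^2)
  ss_s <- k * sum((rowMeans(Y) - grand)^2)
  ss_err <- sum((Y - grand)^2) - ss_w - ss_s
  df <- (k - 1) * (n - 1)
  ms_err <- ss_err / df
  se <- sqrt(ms_err * sum(cf^2) / n)
  t <- if (se == 0) {
    if (mean(scores) == 0) 0 else sign(mean(scores)) * Inf
  } else mean(scores) / se
  list(estimate = mean(scores), t = t, df = df,
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}
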