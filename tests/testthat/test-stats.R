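test_that("t statistics and paired effect sizes match hand arithmetic", {
  z <- ttest_effects(c(0, 0, 0), kind = "one_sample")
  expect_equal(z$t, 0); expect_equal(z$d_z, 0)
  # toy pairs (1,2), (2,4), (3,3): diffs (-1,-2,0), sd(x)=sd(y)=1
  r <- ttest_effects(c(1, 2, 3), c(2, 4, 3), kind = "paired")
  expect_equal(r$t, -sqrt(3))
  expect_equal(r$df, 2)
  expect_equal(r$d_z, -1)
  expect_equal(r$g_av, -1 * exp(lgamma(1) - log(1) - lgamma(0.5)))
  expect_equal(r$g_av, -0.5641896, tolerance = 1e-6)
  # scale invariance of t
  r2 <- ttest_effects(2 * c(1, 2, 3), 2 * c(2, 4, 3), kind = "paired")
  expect_equal(r2$t, r$t)
  expect_error(ttest_effects(1), "at least 2")
})

test_that("Holm step-down matches the hand-worked example", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(unname(holm_adjust(c(0.01, 0.04, 0.03))),
               c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Greenhouse-Geisser epsilon hits its bounds", {
  expect_equal(gg_epsilon(diag(2) + 0.3), 1)           # k = 2 forced
  k <- 4
  cs <- diag(k) * 2 + matrix(0.7, k, k)                # compound symmetry
  expect_equal(gg_epsilon(cs), 1)
  # rank-1 deviation in contrast space -> epsilon -> 1/(k-1)
  v <- stats::contr.poly(k)[, 1]
  worst <- tcrossprod(v) * 100 + diag(k) * 1e-8
  expect_equal(gg_epsilon(worst), 1 / (k - 1), tolerance = 1e-5)
  # from raw data matrix
  set.seed(1)
  Y <- matrix(rnorm(60), 12, 5)
  eps <- gg_epsilon(Y)
  expect_gte(eps, 1 / 4); expect_lte(eps, 1)
})

test_that("two-way RM ANOVA matches the aov strata decomposition", {
  set.seed(2)
  d <- null_rm_table(7, 3, 4)
  d$y <- d$y + as.integer(factor(d$A)) * 0.8 + d$B * 0.3
  res <- rm_anova_two_way(d, "y", "participant", "A", "B")
  fit <- stats::aov(y ~ A * factor(B) + Error(factor(participant) /
                                               (A * factor(B))), data = d)
  sm <- summary(fit)
  ref <- rbind(sm[["Error: factor(participant):A"]][[1]]["A", ],
               sm[["Error: factor(participant):factor(B)"]][[1]]["factor(B)", ],
               sm[["Error: factor(participant):A:factor(B)"]][[1]]["A:factor(B)", ])
  expect_equal(res$ss, ref[, "Sum Sq"], ignore_attr = TRUE)
  expect_equal(res$f_value, ref[, "F value"], ignore_attr = TRUE)
  expect_equal(res$p_uncorrected, ref[, "Pr(>F)"], ignore_attr = TRUE)
  # SS terms add up to the total SS
  ss_err <- res$ss / res$f_value * res$df_den / res$df_num
  expect_equal(sum(res$ss) + sum(ss_err) + attr(res, "ss_subjects"),
               attr(res, "ss_total"))
  # invariances and bounds
  d2 <- d; d2$y <- d2$y + 100
  res2 <- rm_anova_two_way(d2, "y", "participant", "A", "B")
  expect_equal(res2$f_value, res$f_value)
  expect_true(all(res$p_gg >= res$p_uncorrected))
  expect_true(all(res$gg_epsilon >= 1 / res$df_num & res$gg_epsilon <= 1))
  expect_true(all(res$ges <= res$pes + 1e-12))
  expect_error(rm_anova_two_way(d[-1, ], "y", "participant", "A", "B"),
               "complete")
})

test_that("mixed ANOVA matches aov and the printed df convention", {
  set.seed(3)
  n1 <- 20; n2 <- 12; k <- 4
  d <- expand.grid(participant = seq_len(n1 + n2), W = seq_len(k))
  d$G <- ifelse(d$participant <= n1, "constant", "variable")
  d$y <- rnorm(nrow(d)) + (d$G == "variable") * 0.5 + d$W * 0.2
  res <- mixed_anova(d, "y", "participant", "G", "W")
  expect_equal(res$df_num, c(1, k - 1, k - 1))
  expect_equal(res$df_den[1], n1 + n2 - 2)          # F(1, 30) layout
  fit <- stats::aov(y ~ G * factor(W) + Error(factor(participant)),
                    data = d)
  sm <- summary(fit)
  btw <- sm[["Error: factor(participant)"]][[1]]
  wth <- sm[["Error: Within"]][[1]]
  expect_equal(res$ss, c(btw["G", "Sum Sq"], wth["factor(W)", "Sum Sq"],
                         wth["G:factor(W)", "Sum Sq"]))
  expect_equal(res$f_value, c(btw["G", "F value"], wth["factor(W)", "F value"],
                              wth["G:factor(W)", "F value"]))
  # group means forced identical -> between F exactly 0
  d0 <- d
  offs <- rnorm(n1 + n2)
  offs <- offs - stats::ave(offs, c(rep(1, n1), rep(2, n2)))
  d0$y <- offs[d0$participant] + d0$W * 0.2 + rnorm(nrow(d0), 0, 0.01)
  d0$y <- d0$y - stats::ave(d0$y, d0$G) + mean(d0$y)
  res0 <- mixed_anova(d0, "y", "participant", "G", "W")
  expect_equal(res0$f_value[1], 0, tolerance = 1e-12)
  expect_error(mixed_anova(transform(d, G = "one"), "y", "participant",
                           "G", "W"), "2 groups")
})

test_that("polynomial contrasts use the pooled interaction error", {
  set.seed(4)
  n <- 20; k <- 4
  d <- expand.grid(participant = seq_len(n), W = c(35, 70, 105, 140))
  d$y <- rnorm(nrow(d)) + d$W / 100
  pc <- polynomial_contrast(d, "y", "participant", "W", "linear")
  expect_equal(pc$df, (k - 1) * (n - 1))             # t(57) layout
  expect_equal(pc$df, 57)
  # linear coefficients proportional to (-3, -1, 1, 3)
  cf <- stats::contr.poly(4)[, 1]
  expect_equal(cf / cf[4], c(-3, -1, 1, 3) / 3)
  # perfectly linear per-subject data: higher orders vanish
  d$y <- rep(rnorm(n), times = k) + d$W * 0.05
  expect_equal(polynomial_contrast(d, "y", "participant", "W",
                                   "quadratic")$estimate, 0,
               tolerance = 1e-12)
  expect_equal(polynomial_contrast(d, "y", "participant", "W",
                                   "cubic")$estimate, 0, tolerance = 1e-12)
})

test_that("noncentral-t power search reproduces published sample sizes", {
  expect_equal(power_paired_t(0.94, 0.05, 0.80), 11)
  expect_equal(power_paired_t(0.5, 0.05, 0.80), 34)
  # power is non-decreasing in n
  pw <- vapply(5:40, paired_t_power, numeric(1), d_z = 0.5)
  expect_true(all(diff(pw) > 0))
  expect_error(power_paired_t(-1), "> 0")
})

test_that("Cohen's f conversion is exact and invertible", {
  expect_equal(cohens_f_from_F(3.32, 1.59, 6.36), 0.91, tolerance = 0.005)
  expect_equal(cohens_f_from_F(0, 2, 10), 0)
  f <- cohens_f_from_F(4.2, 3, 45)
  expect_equal(cohens_f_from_F(f^2 * 45 / 3, 3, 45), f)
  expect_error(cohens_f_from_F(-1, 2, 10), ">= 0")
})

test_that("JZS Bayes factors match an independent quadrature oracle", {
  r <- sqrt(2) / 2
  oracle <- function(t, n) {
    nu <- n - 1
    m1 <- suppressWarnings(stats::integrate(function(d)
      stats::dt(t, nu, ncp = d * sqrt(n)) * stats::dcauchy(d, 0, r),
      -Inf, Inf, rel.tol = 1e-10)$value)
    m1 / stats::dt(t, nu)
  }
  for (case in list(c(2.5, 20), c(0.5, 12), c(4, 8))) {
    expect_equal(jzs_bf_ttest(case[1], case[2]), oracle(case[1], case[2]),
                 tolerance = 5e-4)
  }
  expect_lt(jzs_bf_ttest(0, 20), 1)
  bfs <- vapply(seq(0, 5, 0.5), jzs_bf_ttest, numeric(1), n1 = 15)
  expect_true(all(diff(bfs) > 0))
  # two-sample form uses the effective sample size
  expect_gt(jzs_bf_ttest(3, 15, 15), 1)
})

test_that("null p-values are well distributed across both engines", {
  set.seed(5)
  reps <- 200
  ps <- matrix(NA_real_, reps, 2)
  tpl <- expand.grid(participant = 1:12, A = letters[1:3], B = 1:4,
                     stringsAsFactors = FALSE)
  tplm <- expand.grid(participant = 1:12, W = 1:4)
  tplm$G <- ifelse(tplm$participant <= 6, "g1", "g2")
  for (i in seq_len(reps)) {
    tpl$y <- rnorm(nrow(tpl))
    ps[i, 1] <- rm_anova_two_way(tpl, "y", "participant", "A",
                                 "B")$p_uncorrected[3]
    tplm$y <- rnorm(nrow(tplm))
    ps[i, 2] <- mixed_anova(tplm, "y", "participant", "G",
                            "W")$p_uncorrected[2]
  }
  # uncorrected p uniform under a spherical null
  expect_gt(stats::ks.test(ps[, 1], "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(ps[, 2], "punif")$p.value, 0.01)
})
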