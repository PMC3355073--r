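test_that("nested F equals a hand-assembled RSS comparison", {
  set.seed(21)
  age <- c(0, 0.4, 0.8, 2, 6, 12, 17, 19, 30, 45, 70, 95,
           0, 0.3, 0.9, 3, 7, 13, 16, 20, 33, 48, 72, 90)
  grp <- rep(c("A", "B"), each = 12)
  y <- predict(lym_params, age) + rnorm(24, 0, 0.7) +
    ifelse(grp == "B", 0.5, 0)
  out <- nested_f_test(age, y, grp)
  # oracle: direct arithmetic on the two models' RSS and dfs
  rss1 <- fit_piecewise(age, y)$rss
  rss2 <- fit_piecewise(age[grp == "A"], y[grp == "A"])$rss +
          fit_piecewise(age[grp == "B"], y[grp == "B"])$rss
  f_hand <- ((rss1 - rss2) / 4) / (rss2 / (24 - 8))
  expect_equal(out$f_stat, f_hand, tolerance = 1e-12)
  expect_identical(out$df_num, 4L)
  expect_identical(out$df_den, 24L - 8L)
  expect_lte(out$rss_stratified, out$rss_pooled)
  # cross-check against stats::anova on the equivalent interaction model
  X <- hinge_design(age)[, -1]
  m1 <- lm(y ~ X)
  m2 <- lm(y ~ X * grp)
  a <- anova(m1, m2)
  expect_equal(out$f_stat, a$F[2], tolerance = 1e-9)
  expect_equal(out$p_value, a$`Pr(>F)`[2], tolerance = 1e-9)
})

test_that("nested F has the published df shape and null behaviour", {
  co <- cohort_subset(default_cohort, "naiveT_CD45RAposCD20neg")
  # two-level factor on the 4-coefficient model: F(4, n - 8)
  out <- nested_f_test(co$age_years, co$mtl_kb, co$sex)
  expect_identical(out$df_num, 4L)
  expect_identical(out$df_den, nrow(co) - 8L)
  # a random split of one population gives an unremarkable F
  set.seed(99)
  fake <- sample(c("A", "B"), nrow(co), replace = TRUE)
  null_out <- nested_f_test(co$age_years, co$mtl_kb, fake)
  expect_gt(null_out$p_value, 0.001)
  expect_error(nested_f_test(co$age_years, co$mtl_kb,
                             rep("A", nrow(co))), "2 levels")
  # a stratum confined to one segment is named in the error
  grp <- ifelse(co$age_years > 30, "old", "rest")
  expect_error(nested_f_test(co$age_years, co$mtl_kb, grp), "old")
})

test_that("nested F type-I error is calibrated at the 5% level", {
  set.seed(2026)
  n <- 60
  rej <- logical(2000)
  for (i in seq_len(2000)) {
    age <- c(0, 0.3, 0.6, 0.9, runif(26, 1, 18), runif(30, 18, 100))
    y <- predict(lym_params, age) + rnorm(n, 0, 0.96)
    grp <- rep(c("A", "B"), n / 2)  # no true effect
    rej[i] <- nested_f_test(age, y, grp)$p_value < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("the configured sex effect is detected with high power", {
  # naive T cells carry the largest female-male offset; at the default
  # cohort size the stratified model should win almost always
  hits <- sapply(1:25, function(s) {
    co <- generate_cohort(default_healthy_config(seed = 700 + s))
    nt <- cohort_subset(co, "naiveT_CD45RAposCD20neg")
    nested_f_test(nt$age_years, nt$mtl_kb, nt$sex)$p_value < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("one-way ANOVA: df structure, F = t^2 for 2 groups, degenerate F", {
  set.seed(5)
  # 6 groups, total N = 271 -> df (5, 265), as in a six-subset comparison
  groups6 <- split(rnorm(271), rep(1:6, length.out = 271))
  out <- one_way_anova(groups6)
  expect_identical(out$df_between, 5L)
  expect_identical(out$df_within, 265L)
  # two groups: F equals the squared pooled t
  a <- rnorm(12); b <- rnorm(15, 0.8)
  f2 <- one_way_anova(list(a, b))
  tt <- two_sample_t(a, b)
  expect_equal(f2$f_stat, tt$t_stat^2, tolerance = 1e-10)
  expect_equal(f2$p_value, tt$p_two_tailed, tolerance = 1e-10)
  # identical constant groups: F = 0
  f0 <- one_way_anova(list(rep(2, 5), rep(2, 6)))
  expect_equal(f0$f_stat, 0)
  expect_error(one_way_anova(list(rnorm(3))), "2 groups")
})

test_that("Tukey HSD matches stats::TukeyHSD and is conservative", {
  set.seed(8)
  vals <- c(rnorm(10, 0), rnorm(12, 0.5), rnorm(9, 1.2))
  lab <- rep(c("a", "b", "c"), c(10, 12, 9))
  mine <- tukey_hsd(vals, lab)
  ref <- TukeyHSD(aov(vals ~ factor(lab)))$`factor(lab)`
  expect_equal(mine$mean_diff, unname(ref[, "diff"]), tolerance = 1e-10)
  expect_equal(mine$p_adj, unname(ref[, "p adj"]), tolerance = 1e-8)
  # adjusted p never undercuts the unadjusted pairwise comparison at the
  # same pooled error: p_unadj = 2 * pt(-q / sqrt(2), df_within)
  df_w <- length(vals) - 3L
  p_unadj <- 2 * pt(-mine$q_stat / sqrt(2), df_w)
  expect_true(all(mine$p_adj >= p_unadj - 1e-12))
  # identical groups: all adjusted p ~ 1
  same <- tukey_hsd(list(rnorm(8) + 100, rnorm(8) + 100, rnorm(8) + 100))
  expect_true(all(same$p_adj > 0.0001))
})

test_that("two groups reduce Tukey to the pooled two-sample comparison", {
  set.seed(9)
  a <- rnorm(10); b <- rnorm(10, 0.7)
  tk <- tukey_hsd(list(a, b))
  tt <- two_sample_t(a, b)
  # q = sqrt(2) * |t|, and the k = 2 studentized range p equals the t p
  expect_equal(tk$q_stat, sqrt(2) * abs(tt$t_stat), tolerance = 1e-10)
  expect_equal(tk$p_adj, tt$p_two_tailed, tolerance = 1e-4)
})

test_that("pooled t-test: formula, separation and degenerate conventions", {
  a <- c(1, 2, 3); b <- c(2, 3, 5)
  out <- two_sample_t(a, b)
  # direct arithmetic oracle
  sp2 <- (sum((a - 2)^2) + sum((b - 10 / 3)^2)) / 4
  expect_equal(out$t_stat, (2 - 10 / 3) / sqrt(sp2 * (2 / 3)),
               tolerance = 1e-12)
  expect_identical(out$df, 4L)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(out$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(out$p_two_tailed, ref$p.value, tolerance = 1e-12)
  # identical samples -> t 0, p 1; strong separation -> tiny p
  same <- two_sample_t(c(4, 4), c(4, 4))
  expect_equal(same$t_stat, 0); expect_equal(same$p_two_tailed, 1)
  sep <- two_sample_t(c(1, 2, 3), c(11, 12, 13) + rnorm(3, 0, 1e-6))
  expect_lt(sep$p_two_tailed, 1e-3)
  shifted <- two_sample_t(c(5, 5), c(7, 7))
  expect_identical(shifted$p_two_tailed, 0)
})
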