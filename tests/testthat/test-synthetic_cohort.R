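test_that("default healthy config carries the published trend table", {
  cfg <- default_healthy_config()
  expect_setequal(names(cfg$subset_params), TELO_SUBSETS)
  lym <- cfg$subset_params$lymphocytes
  expect_equal(lym$intercept_kb, 11.2)
  expect_equal(lym$slopes_kb_yr, c(-1.190, -0.126, -0.043))
  # noise sd inverts the central 80% spread of a Gaussian: 2.45 kb 10-90
  expect_equal(cfg$subset_sd[["lymphocytes"]],
               2.45 / (qnorm(0.9) - qnorm(0.1)), tolerance = 1e-12)
  # all six subsets distinct
  ints <- vapply(cfg$subset_params, `[[`, numeric(1), "intercept_kb")
  expect_identical(length(unique(ints)), 6L)
  expect_length(cfg$group_deltas, 0)
  # sex offsets small and female-positive
  expect_true(all(cfg$sex_offset > 0 & cfg$sex_offset <= 0.5))
})

test_that("affected config adds carrier/relative deficits and age laws", {
  cfg <- default_affected_config()
  expect_equal(cfg$group_deltas$carrier_TERT[["naiveT_CD45RAposCD20neg"]],
               -3.1)
  expect_equal(cfg$group_deltas$carrier_TERC[["naiveT_CD45RAposCD20neg"]],
               -3.3)
  # pooled carriers (37 TERT + 23 TERC) recover the pooled deficit -3.2
  pooled <- (37 * -3.1 + 23 * -3.3) / 60
  expect_equal(round(pooled, 1), -3.2)
  expect_equal(cfg$group_deltas$relative_unspecified[["granulocytes"]], -0.9)
  expect_equal(cfg$age_laws$carrier_TERT$mean, 41)
  expect_equal(cfg$age_laws$relative_unspecified$mean, 45)
  # healthy remains the implicit zero-deficit reference
  expect_false("healthy" %in% names(cfg$group_deltas))
})

test_that("config validation rejects inconsistent inputs", {
  p <- list(lymphocytes = lym_params)
  expect_error(generator_config(p, c(other = 1), c(lymphocytes = 0.1)),
               "subset_sd")
  expect_error(generator_config(p, c(lymphocytes = -1),
                                c(lymphocytes = 0.1)), "non-negative")
  expect_error(piecewise_params(10, c(-1, -0.1, -0.05), c(18, 1)),
               "breakpoints")
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_cohort(default_healthy_config(seed = 9),
                       c(healthy = 50))
  b <- generate_cohort(default_healthy_config(seed = 9),
                       c(healthy = 50))
  d <- generate_cohort(default_healthy_config(seed = 10),
                       c(healthy = 50))
  expect_identical(a, b)
  expect_false(identical(a$mtl_kb, d$mtl_kb))
})

test_that("zero-noise generation sits exactly on the configured curve", {
  cfg <- default_healthy_config(seed = 5)
  cfg$subset_sd[] <- 0
  cfg$sex_offset[] <- 0
  co <- generate_cohort(cfg, c(healthy = 200))
  for (ss in TELO_SUBSETS) {
    d <- cohort_subset(co, ss)
    expect_equal(d$mtl_kb, predict(cfg$subset_params[[ss]], d$age_years),
                 tolerance = 1e-12)
    # and a fit on the noise-free records returns the configured params
    fit <- fit_piecewise(d$age_years, d$mtl_kb)
    expect_equal(fit$params$intercept_kb,
                 cfg$subset_params[[ss]]$intercept_kb, tolerance = 1e-9)
    expect_equal(fit$params$slopes_kb_yr,
                 cfg$subset_params[[ss]]$slopes_kb_yr, tolerance = 1e-9)
  }
})

test_that("cohort structure: density, cord blood, uniqueness, groups", {
  co <- default_cohort
  subjects <- unique(co$subject_id)
  expect_identical(length(subjects), 58L + 8L * 102L)
  expect_false(anyDuplicated(co[c("subject_id", "subset")]) > 0)
  lym <- cohort_subset(co, "lymphocytes")
  expect_identical(sum(lym$age_years == 0), 58L)  # cord blood, exact age 0
  expect_true(all(lym$age_years >= 0 & lym$age_years <= 102))
  # roughly 8 subjects per adult age-year
  expect_identical(sum(lym$age_years > 50 & lym$age_years <= 51), 8L)
  # cord-blood mean within 3 SE of the configured birth intercept
  cb <- lym$mtl_kb[lym$age_years == 0]
  se <- sd(cb) / sqrt(length(cb))
  expect_lt(abs(mean(cb) - 11.2), 3 * se)
  expect_error(generate_cohort(default_healthy_config(),
                               c(martians = 5)), "unknown group")
})

test_that("carrier and relative ages follow the truncated adult law", {
  cfg <- default_affected_config(seed = 31)
  co <- generate_cohort(cfg, c(carrier_TERT = 400, carrier_TERC = 200,
                               relative_unspecified = 300))
  age_c <- unique(co[co$group %in% c("carrier_TERT", "carrier_TERC"),
                     c("subject_id", "age_years")])$age_years
  age_r <- unique(co[co$group == "relative_unspecified",
                     c("subject_id", "age_years")])$age_years
  expect_true(all(age_c >= 19 & age_c <= 102))
  # truncation at 19 lifts the realised mean slightly above the 41 centre
  expect_gt(mean(age_c), 40); expect_lt(mean(age_c), 45)
  expect_gt(mean(age_r), 44); expect_lt(mean(age_r), 49)
})

test_that("residual spread converges to the configured 10-90 width", {
  cfg <- default_healthy_config(seed = 77)
  co <- generate_cohort(cfg, c(healthy = 6000))
  lym <- cohort_subset(co, "lymphocytes")
  resid <- lym$mtl_kb - predict(cfg$subset_params$lymphocytes,
                                lym$age_years) -
    ifelse(lym$sex == "F", 1, -1) * cfg$sex_offset[["lymphocytes"]] / 2
  width <- diff(quantile(resid, c(0.1, 0.9), names = FALSE))
  expect_equal(width, 2.45, tolerance = 0.08)  # ~3 MC SE at n = 6000
})

test_that("missingness drops subset records but keeps subjects", {
  cfg <- default_healthy_config(seed = 13)
  cfg$missing_rate <- 0.3
  co <- generate_cohort(cfg, c(healthy = 300))
  per_subj <- table(co$subject_id)
  expect_lt(nrow(co), 300 * 6)
  expect_true(any(per_subj < 6))
})
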