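test_that("identical config and seed reproduce cohorts and waveforms exactly", {
  cfg <- synthetic_config(n_subjects = 25, seed = 9, duration = 15)
  co1 <- sample_cohort(cfg)
  co2 <- sample_cohort(cfg)
  expect_identical(co1, co2)
  r1 <- synthesize_ppg(co1[3, ], cfg)
  r2 <- synthesize_ppg(co2[3, ], cfg)
  expect_identical(r1$samples, r2$samples)
})

test_that("invalid generator configs are rejected", {
  expect_error(synthetic_config(n_subjects = 0), "n_subjects")
  expect_error(synthetic_config(sampling_rate = 10), "sampling_rate")
  expect_error(synthetic_config(noise_sd = -1), "nonnegative")
})

test_that("cohort BP distribution has the required shape and tails", {
  cfg <- synthetic_config(n_subjects = 400, seed = 1)
  co <- sample_cohort(cfg)
  # tail mass demanded of a validation population
  expect_gte(mean(co$sbp_true <= 100), 0.05)
  expect_gte(mean(co$sbp_true >= 160), 0.05)
  # SBP rises with age
  expect_gt(mean(co$sbp_true[co$age >= 60]), mean(co$sbp_true[co$age < 30]))
  # hard physiological ranges
  expect_true(all(co$age >= 15 & co$age <= 94))
  expect_true(all(co$sbp_true >= 80 & co$sbp_true <= 250))
  expect_true(all(co$dbp_true >= 40 & co$dbp_true <= 150))
  expect_true(all(co$sbp_true > co$dbp_true))
  expect_true(all(co$heart_rate >= 40 & co$heart_rate <= 180))
})

test_that("per-age-bin means rise for SBP and peak near 60 for DBP", {
  co <- sample_cohort(synthetic_config(n_subjects = 2000, seed = 5))
  bins <- cut(co$age, c(15, 30, 45, 60, 75, 95), right = FALSE)
  sbp_means <- tapply(co$sbp_true, bins, mean)
  expect_true(all(diff(sbp_means) > 0))
  dbp_means <- tapply(co$dbp_true, bins, mean)
  expect_true(all(diff(dbp_means[1:4]) > 0))   # rising to the 60-75 bin
  expect_lt(dbp_means[5], dbp_means[4])        # falling after
})

test_that("waveform length and beat count match the configuration", {
  cfg <- clean_config(duration = 15)
  prof <- fixed_profile(hr = 60)
  rec <- synthesize_ppg(prof, cfg)
  expect_length(rec$samples, 15 * 256)
  n_beats <- nrow(detect_pulses(rec))
  expect_true(n_beats >= 14 && n_beats <= 16)
})

test_that("morphology link is monotone in blood pressure", {
  cfg <- clean_config()
  lo <- fixed_profile(sbp = 110)
  hi <- fixed_profile(sbp = 150)
  expect_gt(ground_truth_features(hi, cfg)["max_slope"],
            ground_truth_features(lo, cfg)["max_slope"])
  lo_d <- fixed_profile(dbp = 60)
  hi_d <- fixed_profile(dbp = 90)
  expect_gt(ground_truth_features(hi_d, cfg)["a2_ratio"],
            ground_truth_features(lo_d, cfg)["a2_ratio"])
})

test_that("ground-truth features satisfy their identities", {
  cfg <- clean_config()
  gt <- ground_truth_features(fixed_profile(hr = 60), cfg)
  expect_equal(unname(gt["a1_ratio"] + gt["a2_ratio"]), 1)
  expect_equal(unname(gt["mean_rr"]), 1.0)
  expect_length(gt, 10)
  expect_named(gt, feature_names())
})

test_that("noise-free features determine BP, so regression is well-posed", {
  cfg <- clean_config(n = 200, seed = 21)
  co <- sample_cohort(cfg)
  ft <- gt_feature_table(co, cfg)
  # injectivity on the generated cohort: no two subjects share a
  # feature vector
  X <- as.matrix(ft[, feature_names()])
  expect_identical(anyDuplicated(X), 0L)
  # recovery: within one demographic cell, a GP on the noise-free
  # features predicts held-out SBP far better than the cell SD
  cell <- which(co$gender == 1 & co$age >= 30 & co$age < 60)
  cell_ft <- ft[cell, ]
  n <- nrow(cell_ft)
  hold <- seq(2, n, by = 4)
  m <- fit_gpr(as.matrix(cell_ft[-hold, feature_names()]),
               cell_ft$sbp_true[-hold])
  pr <- predict(m, as.matrix(cell_ft[hold, feature_names()]))$mean
  rmse <- sqrt(mean((pr - cell_ft$sbp_true[hold])^2))
  expect_lt(rmse, 0.3 * sd(cell_ft$sbp_true))
})

test_that("age grouping moves SBP closer to within-group normality", {
  # Shapiro-Wilk p within 15-year bins exceeds the ungrouped p on
  # average over seeds
  diffs <- vapply(1:20, function(s) {
    co <- sample_cohort(synthetic_config(n_subjects = 200, seed = 1000 + s))
    p_all <- shapiro_wilk_test(co$sbp_true)$p
    bins <- cut(co$age, c(15, 30, 45, 60, 75, 95), right = FALSE)
    ps <- vapply(levels(bins), function(b) {
      v <- co$sbp_true[bins == b]
      if (length(v) < 3) return(NA_real_)
      shapiro_wilk_test(v)$p
    }, numeric(1))
    mean(ps, na.rm = TRUE) - p_all
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("profile validation rejects out-of-range subjects", {
  cfg <- clean_config()
  expect_error(synthesize_ppg(fixed_profile(age = 10L), cfg), "age")
  expect_error(synthesize_ppg(fixed_profile(gender = 2L), cfg), "gender")
  expect_error(synthesize_ppg(fixed_profile(sbp = 70, dbp = 80), cfg),
               "SBP must exceed DBP")
})
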