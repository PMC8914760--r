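# a feature row with given demographics, morphology irrelevant but fixed
flat_fv <- function(age, gender) {
  fv <- c(0.35, 0.65, 0.12, 0.24, 6.5, 0.3, 0.65, 0.85, age, gender)
  names(fv) <- feature_names()
  fv
}

# feature table with constant morphology per demographic cell and a
# constant target, enough subjects to train every cell
constant_cell_table <- function(ages, target_by_age, gender = c(0L, 1L),
                                n_per = 6) {
  rows <- list()
  k <- 0
  for (g in gender) for (a in ages) for (r in seq_len(n_per)) {
    k <- k + 1
    fv <- flat_fv(a + 0.0, g)
    fv[1:8] <- fv[1:8] * (1 + 0.01 * r)   # tiny spread so sd > 0
    rows[[k]] <- cbind(data.frame(subject_id = sprintf("C%03d", k),
                                  window_id = 1L),
                       as.data.frame(as.list(fv)),
                       data.frame(sbp_true = target_by_age(a),
                                  dbp_true = target_by_age(a) / 2))
  }
  do.call(rbind, rows)
}

test_that("age bins are half-open, lower-inclusive, and match both schemes", {
  sbp <- default_scheme("SBP")
  dbp <- default_scheme("DBP")
  expect_identical(sbp$labels, c("Age < 30", "30 <= Age < 60", "60 <= Age"))
  expect_identical(dbp$labels, c("Age < 30", "30 <= Age < 45",
                                 "45 <= Age < 60", "60 <= Age < 75",
                                 "75 <= Age"))
  expect_identical(assign_group(25, sbp), "Age < 30")
  expect_identical(assign_group(30, dbp), "30 <= Age < 45")
  expect_identical(assign_group(94, dbp), "75 <= Age")
  expect_identical(assign_group(60, sbp), "60 <= Age")
  expect_error(assign_group(10, sbp), "out of range")
  expect_identical(age_bin_scheme(100)$labels, "All ages")
})

test_that("training yields one model per populated cell: 6 for SBP, 10 for DBP", {
  tab <- constant_cell_table(c(22, 40, 52, 65, 80), function(a) 100 + a)
  sbp_bank <- train_bank(tab, "SBP")
  expect_length(sbp_bank$models, 6)
  dbp_bank <- train_bank(tab, "DBP")
  expect_length(dbp_bank$models, 10)
  # one gender only: the other gender's lookups fail loudly
  solo <- train_bank(tab[tab$gender == 1, ], "SBP")
  expect_length(solo$models, 3)
  expect_error(predict_uncalibrated(solo, flat_fv(25, 0)), "missing model")
  # undersized cells are skipped with a warning
  small <- tab[!(tab$gender == 0 & tab$age == 22) | tab$subject_id %in%
                 sprintf("C%03d", 1:2), ]
  expect_warning(b <- train_bank(small, "SBP"), "undersized")
  expect_true("g0|Age < 30" %in% b$provenance$skipped_cells)
})

test_that("uncalibrated prediction uses the subject's own cell deterministically", {
  tab <- constant_cell_table(c(22, 40, 70), function(a) 120)
  bank <- train_bank(tab, "SBP")
  fv <- flat_fv(22, 1)
  p1 <- predict_uncalibrated(bank, fv)
  expect_equal(p1, 120, tolerance = 0.5)
  expect_identical(p1, predict_uncalibrated(bank, fv))
})

test_that("calibration selects the bin with minimal reference error", {
  # three bins whose constant targets are 130, 143 and 160; against a
  # cuff reading of 140 the middle bin (error 3) must win
  tab <- constant_cell_table(c(22, 40, 70),
                             function(a) c(`22` = 130, `40` = 143,
                                           `70` = 160)[as.character(a)])
  bank <- train_bank(tab, "SBP")
  fv <- flat_fv(25, 1)                     # chronological bin differs
  state <- calibrate_select(bank, fv, 140, gender = 1)
  expect_identical(state$selected_bin, "30 <= Age < 60")
  expect_true(all(state$scores[state$selected_bin] <= state$scores + 1e-12))
  expect_error(calibrate_select(bank, fv, 140, gender = 3), "missing model")
})

test_that("a single-bin bank is always selected", {
  tab <- constant_cell_table(c(40), function(a) 125)
  bank <- train_bank(tab, "SBP")
  state <- calibrate_select(bank, flat_fv(80, 0), 200, gender = 0)
  expect_identical(state$selected_bin, "30 <= Age < 60")
})

test_that("augmentation interpolates the calibration pair and shrinks variance", {
  bank <- small_sbp_bank()
  cfg <- synthetic_config(n_subjects = 150, seed = 11)
  prof <- fixed_profile(age = 40L, gender = 1L, sbp = 141, dbp = 82, hr = 70)
  fv <- ground_truth_features(prof, cfg)
  state <- calibrate_select(bank, fv, 140, gender = 1)
  aug <- augment_model(state, bank)
  expect_true(aug$state$augmented)
  base <- bank$models[[paste0("g1|", state$selected_bin)]]
  v_before <- predict(base, matrix(fv, 1))$variance
  v_after <- predict(aug$model, matrix(fv, 1))$variance
  expect_lt(v_after, v_before)
  # with the noise variance forced to ~0, augmentation interpolates exactly
  m0 <- base
  m0$params$sigma_n2 <- 1e-12
  m0 <- ppgbp:::gpr_cache_alpha(m0)
  m0 <- gpr_augment(m0, matrix(fv, 1), 140)
  expect_equal(predict(m0, matrix(fv, 1))$mean, 140, tolerance = 1e-4)
  # zero pairs leave the model untouched
  expect_identical(gpr_augment(base, matrix(numeric(0), 0, 10), numeric(0)),
                   base)
})

test_that("calibrated prediction equals uncalibrated when the own bin is
           selected without augmentation", {
  tab <- constant_cell_table(c(22, 40, 70), function(a) 100 + a)
  bank <- train_bank(tab, "SBP")
  fv <- flat_fv(40, 0)
  state <- calibrate_select(bank, fv, 140, gender = 0)
  expect_identical(state$selected_bin, "30 <= Age < 60")
  expect_equal(predict_calibrated(state, bank, fv, augment = FALSE),
               predict_uncalibrated(bank, fv))
  expect_error(predict_calibrated(NULL, bank, fv), "calibration state")
})

test_that("bank training is stable under subject permutation", {
  tab <- constant_cell_table(c(22, 40), function(a) 100 + a)
  b1 <- train_bank(tab, "SBP")
  b2 <- train_bank(tab[rev(seq_len(nrow(tab))), ], "SBP")
  fv <- flat_fv(25, 1)
  expect_equal(predict_uncalibrated(b1, fv), predict_uncalibrated(b2, fv),
               tolerance = 1e-6)
})
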