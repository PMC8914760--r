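`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("delta statistics follow the actual-minus-estimated convention", {
  s <- delta_stats(c(120, 120), c(123, 123))
  expect_equal(s$mean, -3)                      # overestimation is negative
  s0 <- delta_stats(c(110, 120, 130), c(110, 120, 130))
  expect_equal(s0$mean, 0)
  expect_equal(s0$sd, 0)
  expect_equal(c(s0$cum5, s0$cum10, s0$cum15), c(100, 100, 100))
  s3 <- delta_stats(c(103, 107, 112), c(100, 100, 100))
  expect_equal(s3$cum5, 100 / 3, tolerance = 1e-10)
  expect_equal(s3$cum10, 200 / 3, tolerance = 1e-10)
  expect_equal(s3$cum15, 100)
  expect_true(s3$cum5 <= s3$cum10 && s3$cum10 <= s3$cum15)
  expect_error(delta_stats(1:3, 1:4), "equal length")
})

test_that("BHS grading implements the standard column criteria", {
  g <- bhs_grade(71.834, 96.382, 99.225)
  expect_identical(g$overall, "A")
  g2 <- bhs_grade(37.421, 58.379, 70.974)
  expect_identical(g2$overall, "D")
  g3 <- bhs_grade(50, 80, 100)
  expect_identical(unname(g3$per_threshold), c("B", "B", "A"))
  expect_identical(g3$overall, "B")
  # exact boundary: criteria are >= thresholds
  expect_identical(bhs_grade(60, 85, 95)$overall, "A")
  expect_error(bhs_grade(80, 70, 90), "non-decreasing")
})

test_that("AAMI bound is |mean| <= 5 and sd <= 8, inclusive", {
  mk <- function(mean, sd) structure(list(mean = mean, sd = sd, n = 100,
                                          cum5 = 50, cum10 = 75, cum15 = 90),
                                     class = "delta_bp_stats")
  expect_true(aami_check(mk(-0.1776, 4.7361)))
  expect_false(aami_check(mk(-0.1809, 10.7177)))
  expect_true(aami_check(mk(0, 0)))
  expect_true(aami_check(mk(5, 8)))
  expect_false(aami_check(mk(5.01, 8)))
})

test_that("Bland-Altman limits are mean +/- 1.96 sd", {
  mk <- function(mean, sd) structure(list(mean = mean, sd = sd, n = 100,
                                          cum5 = 50, cum10 = 75, cum15 = 90),
                                     class = "delta_bp_stats")
  ba <- bland_altman_limits(mk(-0.1809, 10.7177))
  expect_equal(round(unname(ba), 4), c(-21.1876, 20.8258))
  ba2 <- bland_altman_limits(mk(0.5539, 7.8138))
  expect_equal(round(unname(ba2), 4), c(-14.7611, 15.8689))
  expect_equal(unname(bland_altman_limits(mk(0, 1))), c(-1.96, 1.96))
})

test_that("Pearson correlation matches the textbook formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_corr(x, x * 2)$r, 1)
  expect_equal(pearson_corr(x, -x + 10)$r, -1)
  set.seed(19)
  a <- rnorm(50); b <- 0.5 * a + rnorm(50)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  p_hand <- 2 * pt(-abs(r_hand * sqrt(48 / (1 - r_hand^2))), df = 48)
  pc <- pearson_corr(a, b)
  expect_equal(pc$r, r_hand, tolerance = 1e-10)
  expect_equal(pc$p, p_hand, tolerance = 1e-10)
  expect_error(pearson_corr(rep(1, 5), 1:5), "zero variance")
})

test_that("Shapiro-Wilk wrapper enforces sizes and rejects non-normal data", {
  expect_error(shapiro_wilk_test(c(1, 2)), "sample size")
  set.seed(23)
  expect_lt(shapiro_wilk_test(runif(500))$p, 0.01)
  expect_gt(shapiro_wilk_test(rnorm(100))$p, 1e-4)
})

test_that("interval breakdown partitions by the actual reading", {
  actual <- c(85, 95, 129, 130, 150)
  est <- actual + c(1, -2, 0, 3, -1)
  br <- interval_breakdown(actual, est, "SBP")
  expect_true(isTRUE(br$hypotension$undefined))  # only one hypotensive pair
  expect_equal(br$hypotension$n, 1L)
  expect_equal(br$normotension$stats$n, 2)
  expect_equal(br$hypertension$stats$n, 2)
  # DBP cuts: 59 is hypotensive, 60 normotensive, 80 hypertensive
  br2 <- interval_breakdown(c(59, 59, 60, 79, 80, 85), rep(70, 6), "DBP")
  expect_equal(br2$hypotension$stats$n, 2)
  expect_equal(br2$normotension$stats$n, 2)
  expect_equal(br2$hypertension$stats$n, 2)
  total <- sum(vapply(br2, function(s) if (isTRUE(s$undefined)) s$n else
    s$stats$n, numeric(1)))
  expect_equal(total, 6)
})

test_that("full report is internally consistent and serializes", {
  set.seed(31)
  actual <- rnorm(60, 120, 15)
  est <- actual + rnorm(60, 0, 4)
  rep <- evaluate_bp(actual, est, "SBP")
  expect_s3_class(rep, "eval_report")
  expect_lte(rep$ba_lower, rep$ba_upper)
  expect_identical(rep$bhs$overall,
                   bhs_grade(rep$stats$cum5, rep$stats$cum10,
                             rep$stats$cum15)$overall)
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$stats$mean, rep$stats$mean, tolerance = 1e-12)
  expect_identical(back$bhs$overall, rep$bhs$overall)
})

test_that("grouping sweep retrains per width and favours grouping", {
  cfg <- synthetic_config(n_subjects = 160, seed = 17)
  co <- sample_cohort(cfg)
  ft <- gt_feature_table(co, cfg, jitter_sd = 0.05)
  tr <- ft[1:110, ]; te <- ft[111:160, ]
  sw <- suppressWarnings(grouping_sweep(tr, te, "SBP", widths = c(30, 100),
                                        min_cell_size = 3))
  expect_identical(sw$width, c(30, 100))
  expect_true(all(is.finite(sw$sd_delta)))
  # grouping by the generating regime width beats no grouping
  expect_lt(sw$sd_delta[sw$width == 30], sw$sd_delta[sw$width == 100])
  expect_error(grouping_sweep(tr, te, "SBP", widths = c(7)), "widths")
})
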