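#' Device-validation statistics
#'
#' Every statistic used to judge the estimator: the error summary on
#' `delta = actual - estimated` (negative values mean overestimation),
#' cumulative percentages of absolute errors within 5/10/15 mmHg and the
#' BHS letter grades they imply, the AAMI accuracy bound (|mean| <= 5 mmHg
#' and SD <= 8 mmHg), Bland-Altman limits of agreement (mean +/- 1.96 SD),
#' Pearson correlation, Shapiro-Wilk normality, the interval-mode
#' breakdown into hypotension / normotension / hypertension subgroups, and
#' the sweep over age-grouping widths.
#'
#' @name evaluation
NULL

#' Error summary for paired BP readings
#'
#' @param actual,estimated equal-length numeric vectors, mmHg (length >= 2)
#' @return an object of class `delta_bp_stats`: `mean`, `sd` (sample SD),
#'   `n`, and inclusive cumulative percentages `cum5`, `cum10`, `cum15`
#' @export
delta_stats <- function(actual, estimated) {
  if (length(actual) != length(estimated))
    stop("actual and estimated must have equal length")
  if (length(actual) < 2) stop("need at least 2 paired readings")
  d <- actual - estimated
  structure(list(mean = mean(d), sd = stats::sd(d), n = length(d),
                 cum5 = 100 * mean(abs(d) <= 5),
                 cum10 = 100 * mean(abs(d) <= 10),
                 cum15 = 100 * mean(abs(d) <= 15)),
            class = "delta_bp_stats")
}

## BHS column criteria: cumulative % within 5/10/15 mmHg per grade.
BHS_CRITERIA <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))

#' BHS letter grades from cumulative percentages
#'
#' Grades each threshold column against the BHS criteria
#' (A: 60/85/95, B: 50/75/90, C: 40/65/85, D below C); the overall grade
#' is the worst of the three columns.
#'
#' @param cum5,cum10,cum15 cumulative percentages of absolute errors
#'   within 5, 10 and 15 mmHg (must be non-decreasing)
#' @return list with `per_threshold` (three letters) and `overall`
#' @export
bhs_grade <- function(cum5, cum10, cum15) {
  if (any(!is.finite(c(cum5, cum10, cum15))) ||
      cum5 > cum10 || cum10 > cum15 ||
      cum5 < 0 || cum15 > 100)
    stop("cumulative percentages must be non-decreasing within [0, 100]")
  grade_one <- function(value, col) {
    for (g in c("A", "B", "C"))
      if (value >= BHS_CRITERIA[[g]][col]) return(g)
    "D"
  }
  per <- c(grade_one(cum5, 1L), grade_one(cum10, 2L), grade_one(cum15, 3L))
  list(per_threshold = stats::setNames(per, c("cum5", "cum10", "cum15")),
       overall = c("A", "B", "C", "D")[max(match(per, c("A", "B", "C", "D")))])
}

#' AAMI accuracy check
#'
#' Passes iff |mean error| <= 5 mmHg and SD <= 8 mmHg (bounds inclusive).
#'
#' @param stats a `delta_bp_stats`
#' @return logical
#' @export
aami_check <- function(stats) {
  stopifnot(inherits(stats, "delta_bp_stats"))
  abs(stats$mean) <= 5 && stats$sd <= 8
}

#' Bland-Altman limits of agreement
#'
#' @param stats a `delta_bp_stats`
#' @return named vector `c(lower, upper)` = mean -/+ 1.96 SD, mmHg
#' @export
bland_altman_limits <- function(stats) {
  stopifnot(inherits(stats, "delta_bp_stats"))
  c(lower = stats$mean - 1.96 * stats$sd,
    upper = stats$mean + 1.96 * stats$sd)
}

#' Pearson correlation between actual and estimated BP
#'
#' @param actual,estimated equal-length numeric vectors (length >= 3)
#' @return list `r` (sample correlation) and `p` (two-sided, t transform)
#' @export
pearson_corr <- function(actual, estimated) {
  if (length(actual) != length(estimated) || length(actual) < 3)
    stop("need equal-length vectors with at least 3 pairs")
  if (stats::sd(actual) < 1e-12 || stats::sd(estimated) < 1e-12)
    stop("undefined correlation: zero variance input")
  ct <- stats::cor.test(actual, estimated, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Shapiro-Wilk normality test
#'
#' Royston's approximation as implemented in `stats::shapiro.test()`;
#' a higher p-value is consistent with normality.
#'
#' @param values numeric vector, 3 <= n <= 5000
#' @return list `W` and `p`
#' @export
shapiro_wilk_test <- function(values) {
  if (length(values) < 3 || length(values) > 5000)
    stop("sample size must be within 3-5000")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

## Clinical BP intervals by ACTUAL reading.
bp_interval <- function(actual, target) {
  cuts <- if (target == "SBP") c(90, 130) else c(60, 80)
  labs <- c("hypotension", "normotension", "hypertension")
  labs[findInterval(actual, cuts) + 1L]
}

#' Full evaluation report
#'
#' @param actual,estimated paired readings, mmHg
#' @param target `"SBP"` or `"DBP"` (sets the interval cut points)
#' @param subgroups include the interval-mode breakdown (default TRUE)
#' @return an object of class `eval_report`: `stats`, `bhs`, `aami_pass`,
#'   `ba_lower`/`ba_upper`, `pearson_r`/`pearson_p`, and (optionally)
#'   `subgroups`
#' @export
evaluate_bp <- function(actual, estimated, target = c("SBP", "DBP"),
                        subgroups = TRUE) {
  target <- match.arg(target)
  st <- delta_stats(actual, estimated)
  ba <- bland_altman_limits(st)
  pc <- tryCatch(pearson_corr(actual, estimated),
                 error = function(e) list(r = NA_real_, p = NA_real_))
  rep <- structure(list(target = target, stats = st,
                        bhs = bhs_grade(st$cum5, st$cum10, st$cum15),
                        aami_pass = aami_check(st),
                        ba_lower = unname(ba["lower"]),
                        ba_upper = unname(ba["upper"]),
                        pearson_r = pc$r, pearson_p = pc$p),
                   class = "eval_report")
  if (subgroups) rep$subgroups <- interval_breakdown(actual, estimated, target)
  rep
}

#' Interval-mode subgroup breakdown
#'
#' Partitions pairs by the ACTUAL reading into hypotension / normotension /
#' hypertension (SBP: <90 / 90-129 / >=130; DBP: <60 / 60-79 / >=80 mmHg)
#' and evaluates each subgroup.  Subgroups with fewer than 2 pairs are
#' reported with their `n` and `undefined = TRUE`.
#'
#' @inheritParams evaluate_bp
#' @return named list of per-subgroup reports; subgroup `n`s sum to the
#'   total number of pairs
#' @export
interval_breakdown <- function(actual, estimated, target = c("SBP", "DBP")) {
  target <- match.arg(target)
  if (length(actual) != length(estimated)) stop("length mismatch")
  grp <- bp_interval(actual, target)
  out <- lapply(c("hypotension", "normotension", "hypertension"), function(g) {
    i <- grp == g
    if (sum(i) < 2)
      return(list(n = sum(i), undefined = TRUE))
    evaluate_bp(actual[i], estimated[i], target, subgroups = FALSE)
  })
  names(out) <- c("hypotension", "normotension", "hypertension")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$stats
  cat(sprintf("%s evaluation (n = %d)\n", x$target, s$n))
  cat(sprintf("  dBP = %.4f +/- %.4f mmHg (actual - estimated)\n", s$mean, s$sd))
  cat(sprintf("  <=5: %.3f%%  <=10: %.3f%%  <=15: %.3f%%  -> BHS %s\n",
              s$cum5, s$cum10, s$cum15, x$bhs$overall))
  cat(sprintf("  AAMI: %s;  LoA [%.4f, %.4f];  r = %.3f (p = %.3g)\n",
              if (x$aami_pass) "pass" else "fail",
              x$ba_lower, x$ba_upper, x$pearson_r, x$pearson_p))
  invisible(x)
}

#' Sweep over age-grouping widths
#'
#' Retrains an uncalibrated bank per grouping width on the training split
#' and summarizes the test-split errors, mirroring the search for the
#' best grouping period (width 100 = no grouping).
#'
#' @param train_features,test_features feature tables (as from
#'   [cohort_features()]) for the two splits
#' @param target `"SBP"` or `"DBP"`
#' @param widths grouping widths in years, subset of
#'   `c(5, 10, ..., 50, 100)`
#' @param min_cell_size passed to [train_bank()]
#' @return data.frame with one row per non-skipped width: `width`,
#'   `mean_delta`, `sd_delta`, `n`
#' @export
grouping_sweep <- function(train_features, test_features,
                           target = c("SBP", "DBP"),
                           widths = c(seq(5, 50, by = 5), 100),
                           min_cell_size = 5) {
  target <- match.arg(target)
  if (!all(widths %in% c(seq(5, 50, by = 5), 100)))
    stop("widths must lie in {5, 10, ..., 50, 100}")
  ycol <- if (target == "SBP") "sbp_true" else "dbp_true"
  rows <- lapply(widths, function(w) {
    scheme <- age_bin_scheme(w)
    bank <- tryCatch(
      suppressWarnings(train_bank(train_features, target, scheme,
                                  min_cell_size = min_cell_size)),
      error = function(e) NULL)
    if (is.null(bank)) {
      warning("skipping width ", w, ": no trainable cells")
      return(NULL)
    }
    est <- vapply(seq_len(nrow(test_features)), function(i) {
      fv <- as.numeric(test_features[i, FEATURE_NAMES])
      names(fv) <- FEATURE_NAMES
      tryCatch(predict_uncalibrated(bank, fv), error = function(e) NA_real_)
    }, numeric(1))
    ok <- !is.na(est)
    if (sum(ok) < 2) return(NULL)
    st <- delta_stats(test_features[[ycol]][ok], est[ok])
    data.frame(width = w, mean_delta = st$mean, sd_delta = st$sd, n = st$n)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
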