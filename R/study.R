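#' End-to-end synthetic study
#'
#' Reproduces the whole estimation protocol on synthetic data: draw a
#' cohort, synthesize and preprocess every record, extract windowed
#' feature vectors, split subjects into training and test sets, train the
#' gender-by-age-group banks, then for every test subject take the first
#' accepted window as the calibration reading (its reference is the
#' subject's cuff BP), select and augment the personal model, and predict
#' the remaining windows both with and without calibration.
#'
#' @param seed integer seed driving every stochastic stage
#' @param n_subjects cohort size (default 435)
#' @param n_train,n_test subjects in the training/test split (defaults
#'   306/129); `n_train + n_test` must not exceed `n_subjects`
#' @param targets which pressures to model (default both)
#' @param config optional [synthetic_config()]; its `n_subjects`/`seed`
#'   are overridden by the arguments above
#' @param min_cell_size passed to [train_bank()]
#' @return list with `cohort`, `features`, `split` (subject-id lists),
#'   per-target `banks`, and per-target `results`: data.frame of
#'   per-window `subject_id`, `actual`, `uncalibrated`, `calibrated`
#' @export
run_study <- function(seed = 1, n_subjects = 435, n_train = 306,
                      n_test = 129, targets = c("SBP", "DBP"),
                      config = NULL, min_cell_size = 5) {
  if (n_train + n_test > n_subjects)
    stop("n_train + n_test exceeds n_subjects")
  if (is.null(config)) {
    config <- synthetic_config(n_subjects = n_subjects, seed = seed)
  } else {
    config$n_subjects <- as.integer(n_subjects)
    config$seed <- as.integer(seed)
  }
  cohort <- sample_cohort(config)
  feats <- cohort_features(cohort, config)

  ids <- cohort$subject_id
  perm <- with_local_seed(config$seed + 1L, sample(ids))
  train_ids <- perm[seq_len(n_train)]
  test_ids <- perm[n_train + seq_len(n_test)]
  tr <- feats[feats$subject_id %in% train_ids, ]
  te <- feats[feats$subject_id %in% test_ids, ]

  banks <- list()
  results <- list()
  for (target in targets) {
    ycol <- if (target == "SBP") "sbp_true" else "dbp_true"
    bank <- suppressWarnings(train_bank(tr, target, min_cell_size = min_cell_size))
    banks[[target]] <- bank

    rows <- lapply(unique(te$subject_id), function(sid) {
      sw <- te[te$subject_id == sid, ]
      if (nrow(sw) < 2) return(NULL)       # need a calibration + held-out window
      ref <- sw[[ycol]][1L]
      Xall <- as.matrix(sw[, FEATURE_NAMES])
      calib_fv <- Xall[1L, ]
      eval_X <- Xall[-1L, , drop = FALSE]

      uncal <- tryCatch(predict_uncalibrated(bank, eval_X),
                        error = function(e) rep(NA_real_, nrow(eval_X)))
      cal <- tryCatch({
        state <- calibrate_select(bank, calib_fv, ref, sw$gender[1L], sid)
        predict_calibrated(state, bank, eval_X)
      }, error = function(e) rep(NA_real_, nrow(eval_X)))
      data.frame(subject_id = sid, window_id = sw$window_id[-1L],
                 actual = sw[[ycol]][-1L], uncalibrated = uncal,
                 calibrated = cal, stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(res) <- NULL
    results[[target]] <- res
  }
  list(cohort = cohort, features = feats,
       split = list(train = train_ids, test = test_ids),
       banks = banks, results = results)
}

#' Summarize a study's results for one target
#'
#' @param study output of [run_study()]
#' @param target `"SBP"` or `"DBP"`
#' @return list of `eval_report`s: `uncalibrated` and `calibrated`
#' @export
study_reports <- function(study, target = c("SBP", "DBP")) {
  target <- match.arg(target)
  res <- study$results[[target]]
  ok <- stats::complete.cases(res[, c("actual", "uncalibrated", "calibrated")])
  res <- res[ok, ]
  list(uncalibrated = evaluate_bp(res$actual, res$uncalibrated, target),
       calibrated = evaluate_bp(res$actual, res$calibrated, target))
}

#' Ordinary-least-squares baseline
#'
#' A linear sanity comparator: regresses the target on the ten feature
#' inputs with `lm()`.  Not part of the estimator; used to confirm the
#' GPR adds value over a linear fit.
#'
#' @param features training feature table (as from [cohort_features()])
#' @param target `"SBP"` or `"DBP"`
#' @return an `lm` object
#' @export
fit_ols_baseline <- function(features, target = c("SBP", "DBP")) {
  target <- match.arg(target)
  ycol <- if (target == "SBP") "sbp_true" else "dbp_true"
  df <- features[, c(FEATURE_NAMES, ycol)]
  names(df)[ncol(df)] <- "y"
  stats::lm(y ~ ., data = df)
}
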