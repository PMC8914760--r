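#' Gender-by-age-group model banks and feedback calibration
#'
#' Rather than one regression for everyone, separate GPR models are
#' trained per (gender, age group) cell: systolic pressure uses 30-year
#' groups (<30, 30-60, >=60) and diastolic pressure 15-year groups (<30,
#' 30-45, 45-60, 60-75, >=75), because grouping narrows the within-cell BP
#' distribution toward normality and improves the fit.  Uncalibrated
#' prediction uses the subject's own demographic cell.  Feedback
#' calibration takes one (or more) reference cuff readings, scores every
#' age group of the subject's gender by mean absolute prediction error
#' against the reference, selects the best-scoring group as the subject's
#' personal model, and can absorb the calibration pairs into that model's
#' training set (hyperparameters frozen).
#'
#' @name model_bank
NULL

#' Age-bin scheme
#'
#' Bins are anchored at age 30: a catch-all first bin below 30, then
#' half-open `[edge, edge + width)` bins of the given width, the last bin
#' unbounded above.  Width 100 means no grouping (a single bin).
#'
#' @param width bin width in years; 30 for the default SBP scheme, 15 for
#'   DBP, 100 for no grouping
#' @return an object of class `age_bin_scheme` with `width`, `edges`
#'   (lower bounds; `-Inf` leads) and `labels`
#' @export
age_bin_scheme <- function(width) {
  if (width >= 80) {
    edges <- -Inf
    labels <- "All ages"
  } else {
    lows <- seq(30, max(95 - width, 30), by = width)
    edges <- c(-Inf, lows)
    labels <- c("Age < 30",
                vapply(seq_along(lows), function(i) {
                  if (i == length(lows)) sprintf("%d <= Age", lows[i])
                  else sprintf("%d <= Age < %d", lows[i], lows[i + 1L])
                }, character(1)))
  }
  structure(list(width = width, edges = edges, labels = labels),
            class = "age_bin_scheme")
}

#' @rdname age_bin_scheme
#' @param target `"SBP"` or `"DBP"`
#' @export
default_scheme <- function(target = c("SBP", "DBP")) {
  target <- match.arg(target)
  age_bin_scheme(if (target == "SBP") 30 else 15)
}

#' Assign an age to its bin
#'
#' @param age age in years, within 15-94
#' @param scheme an [age_bin_scheme()]
#' @return the bin label (lower bound inclusive)
#' @export
assign_group <- function(age, scheme) {
  stopifnot(inherits(scheme, "age_bin_scheme"))
  if (any(age < 15 | age > 94)) stop("age out of range 15-94")
  idx <- findInterval(age, c(scheme$edges[-1L], Inf)) + 1L
  scheme$labels[idx]
}

bank_key <- function(gender, label) sprintf("g%d|%s", as.integer(gender), label)

#' Train a model bank
#'
#' Fits one exponential-kernel GPR per (gender, age-bin) cell of the
#' training table.  Cells with fewer than `min_cell_size` distinct
#' subjects are skipped with a warning (recorded in the bank's
#' provenance), not merged.
#'
#' @param features data.frame with the ten [feature_names()] columns plus
#'   `subject_id` and the target column (`sbp_true` or `dbp_true`)
#' @param target `"SBP"` or `"DBP"`
#' @param scheme an [age_bin_scheme()]; defaults to the target's scheme
#' @param min_cell_size minimum distinct subjects per trainable cell
#'   (default 5)
#' @param ... passed to [fit_gpr()]
#' @return an object of class `model_bank`
#' @export
train_bank <- function(features, target = c("SBP", "DBP"),
                       scheme = NULL, min_cell_size = 5, ...) {
  target <- match.arg(target)
  if (is.null(scheme)) scheme <- default_scheme(target)
  ycol <- if (target == "SBP") "sbp_true" else "dbp_true"
  need <- c(FEATURE_NAMES, "subject_id", ycol)
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("feature table missing columns: ",
                         paste(miss, collapse = ", "))
  features$.bin <- assign_group(features$age, scheme)

  models <- list()
  skipped <- character(0)
  for (g in sort(unique(features$gender))) {
    for (lab in scheme$labels) {
      cell <- features[features$gender == g & features$.bin == lab, ]
      if (nrow(cell) == 0) next
      if (length(unique(cell$subject_id)) < min_cell_size) {
        warning(sprintf("skipping undersized cell %s (%d subjects)",
                        bank_key(g, lab), length(unique(cell$subject_id))))
        skipped <- c(skipped, bank_key(g, lab))
        next
      }
      X <- as.matrix(cell[, FEATURE_NAMES])
      models[[bank_key(g, lab)]] <- fit_gpr(X, cell[[ycol]], ...)
    }
  }
  if (!length(models))
    stop("empty bank: no (gender, age-bin) cell had enough subjects")
  structure(list(target = target, scheme = scheme, models = models,
                 provenance = list(n_rows = nrow(features),
                                   n_subjects = length(unique(features$subject_id)),
                                   min_cell_size = min_cell_size,
                                   skipped_cells = skipped)),
            class = "model_bank")
}

#' @export
print.model_bank <- function(x, ...) {
  cat(sprintf("Model bank: %s, %d-year groups, %d fitted cells\n",
              x$target, x$scheme$width, length(x$models)))
  for (k in names(x$models))
    cat(sprintf("  %-22s n = %d\n", k, nrow(x$models[[k]]$X)))
  invisible(x)
}

bank_lookup <- function(bank, gender, label) {
  key <- bank_key(gender, label)
  m <- bank$models[[key]]
  if (is.null(m))
    stop("missing model for cell ", key, " in the ", bank$target, " bank")
  m
}

#' Predict without calibration
#'
#' Uses the model of the subject's own (gender, age-bin) cell.
#'
#' @param bank a `model_bank`
#' @param fv a feature vector (named, [feature_names()] order) or a matrix
#'   of such rows sharing one subject's age and gender
#' @return predicted BP in mmHg (vector, one per row)
#' @export
predict_uncalibrated <- function(bank, fv) {
  if (is.null(dim(fv))) fv <- matrix(fv, nrow = 1L,
                                     dimnames = list(NULL, names(fv)))
  age <- fv[1L, "age"]; gender <- fv[1L, "gender"]
  m <- bank_lookup(bank, gender, assign_group(age, bank$scheme))
  predict(m, fv[, FEATURE_NAMES, drop = FALSE])$mean
}

#' Select the best age-group model against reference readings
#'
#' For every age bin of the subject's gender, predicts the calibration
#' feature vectors and scores the bin by mean absolute error against the
#' reference cuff readings; the minimal-score bin becomes the subject's
#' personal model.  Ties break toward the subject's chronological bin,
#' then toward the younger bin.
#'
#' @param bank a `model_bank`
#' @param calib_features matrix (or single named vector) of calibration
#'   feature rows
#' @param reference_bp reference cuff readings, mmHg (recycled against
#'   rows if length 1)
#' @param gender subject gender code (0/1)
#' @param subject_id identifier recorded in the state
#' @return an object of class `calibration_state` with the selected bin,
#'   per-bin scores, and the calibration pairs
#' @export
calibrate_select <- function(bank, calib_features, reference_bp, gender,
                             subject_id = "") {
  if (is.null(dim(calib_features)))
    calib_features <- matrix(calib_features, nrow = 1L,
                             dimnames = list(NULL, names(calib_features)))
  if (nrow(calib_features) < 1) stop("need at least one calibration pair")
  if (length(reference_bp) == 1L)
    reference_bp <- rep(reference_bp, nrow(calib_features))
  stopifnot(length(reference_bp) == nrow(calib_features))

  labels <- bank$scheme$labels
  avail <- labels[vapply(labels, function(l)
    !is.null(bank$models[[bank_key(gender, l)]]), logical(1))]
  if (!length(avail))
    stop("missing model: no models for gender ", gender, " in the bank")

  X <- calib_features[, FEATURE_NAMES, drop = FALSE]
  scores <- vapply(avail, function(l) {
    pr <- predict(bank$models[[bank_key(gender, l)]], X)$mean
    mean(abs(pr - reference_bp))
  }, numeric(1))

  best <- min(scores)
  tied <- avail[scores <= best + 1e-12]
  chrono <- assign_group(calib_features[1L, "age"], bank$scheme)
  selected <- if (chrono %in% tied) chrono else tied[1L]

  structure(list(subject_id = subject_id, target = bank$target,
                 selected_bin = selected, selected_gender = as.integer(gender),
                 scores = scores,
                 calibration_pairs = list(features = X, reference = reference_bp),
                 augmented = FALSE),
            class = "calibration_state")
}

#' Absorb calibration pairs into the selected model
#'
#' Returns a personal copy of the selected cell's GPR model with the
#' calibration pairs appended to its training set and the predictive
#' cache recomputed; kernel hyperparameters stay frozen and the bank
#' itself is untouched.
#'
#' @param state a `calibration_state`
#' @param bank the `model_bank` the state was selected from
#' @return list with the personal `model` and the updated `state`
#'   (`augmented = TRUE` when pairs were added)
#' @export
augment_model <- function(state, bank) {
  stopifnot(inherits(state, "calibration_state"))
  m <- bank_lookup(bank, state$selected_gender, state$selected_bin)
  pairs <- state$calibration_pairs
  if (length(pairs$reference) > 0L) {
    m <- gpr_augment(m, pairs$features, pairs$reference)
    state$augmented <- TRUE
  }
  list(model = m, state = state)
}

#' Predict with the personal calibrated model
#'
#' @param state a `calibration_state`
#' @param bank the `model_bank`
#' @param fv feature vector or matrix of rows
#' @param augment absorb the calibration pairs before predicting
#'   (default TRUE)
#' @return predicted BP in mmHg
#' @export
predict_calibrated <- function(state, bank, fv, augment = TRUE) {
  if (!inherits(state, "calibration_state"))
    stop("missing calibration state: run calibrate_select() first")
  if (is.null(dim(fv))) fv <- matrix(fv, nrow = 1L,
                                     dimnames = list(NULL, names(fv)))
  m <- if (augment) augment_model(state, bank)$model
       else bank_lookup(bank, state$selected_gender, state$selected_bin)
  predict(m, fv[, FEATURE_NAMES, drop = FALSE])$mean
}
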