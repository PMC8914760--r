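#' PPG morphology features
#'
#' Eight per-pulse morphology parameters are computed from each delineated
#' beat: the systolic and diastolic areas A1 (onset to systolic peak) and
#' A2 (peak to end) taken against the onset-to-end chord, their fractions
#' of the total area, their ratios to the pulse amplitude AC (peak minus
#' onset, giving quantities in seconds), the maximal upslope, and the
#' systolic/diastolic phase durations.  Per-pulse values are averaged over
#' 15-s windows, the mean peak-to-peak (RR) interval appended, and age and
#' gender complete the ten-input feature vector the regression consumes.
#'
#' The systolic/diastolic split is the systolic peak (not the dicrotic
#' notch, which is unreliable on wrist PPG); `split = "notch"` would be the
#' natural extension point but is not implemented.
#'
#' @name features
NULL

## Fixed, documented column order of the ten model inputs.
FEATURE_NAMES <- c("a1_ratio", "a2_ratio", "a1_over_ac", "a2_over_ac",
                   "max_slope", "systolic_time", "diastolic_time",
                   "mean_rr", "age", "gender")

#' Feature-vector column order
#'
#' @return character vector naming the ten model inputs in their fixed
#'   order: the five waveform parameters, the three time-related
#'   parameters, then age and gender
#' @export
feature_names <- function() FEATURE_NAMES

#' Morphology parameters of a single pulse
#'
#' @param record a (filtered) `ppg_record`
#' @param segment one row of [detect_pulses()] output: `onset_index`,
#'   `peak_index`, `end_index`
#' @return named numeric vector with `a1_ratio`, `a2_ratio`, `a1_over_ac`,
#'   `a2_over_ac`, `max_slope`, `systolic_time`, `diastolic_time`; or
#'   `NULL` for a degenerate pulse (AC <= 0 or a zero-length phase), which
#'   callers skip
#' @export
pulse_features <- function(record, segment) {
  stopifnot(inherits(record, "ppg_record"))
  on <- segment$onset_index; pk <- segment$peak_index; en <- segment$end_index
  if (!(on < pk && pk < en) || on < 1 || en > length(record$samples))
    stop("segment indices must satisfy onset < peak < end within the record")
  x <- record$samples
  fs <- record$sampling_rate
  ac <- x[pk] - x[on]
  if (ac <= 0) return(NULL)

  idx <- on:en
  base <- x[on] + (x[en] - x[on]) * (idx - on) / (en - on)
  dev <- x[idx] - base
  dt <- 1 / fs
  trap <- function(v) if (length(v) < 2) 0 else sum((v[-1] + v[-length(v)]) / 2) * dt
  i_pk <- pk - on + 1L
  a1 <- trap(dev[1:i_pk])
  a2 <- trap(dev[i_pk:length(dev)])
  tot <- a1 + a2
  if (!is.finite(tot) || tot <= 0) return(NULL)
  slope <- max(diff(x[idx])) * fs
  c(a1_ratio = a1 / tot, a2_ratio = a2 / tot,
    a1_over_ac = a1 / ac, a2_over_ac = a2 / ac,
    max_slope = slope,
    systolic_time = (pk - on) / fs, diastolic_time = (en - pk) / fs)
}

#' Average per-pulse morphology over one window
#'
#' @param pulse_mat numeric matrix of per-pulse feature rows (the seven
#'   [pulse_features()] values), >= 3 rows
#' @param peak_times numeric vector of the window's systolic peak times in
#'   seconds (same pulses, used for the mean RR interval)
#' @return named numeric vector: the seven morphology means plus `mean_rr`
#' @export
window_features <- function(pulse_mat, peak_times) {
  pulse_mat <- rbind(pulse_mat)
  if (nrow(pulse_mat) < 3)
    stop("insufficient pulses: need >= 3 valid pulses per window, got ",
         nrow(pulse_mat))
  if (length(peak_times) != nrow(pulse_mat))
    stop("peak_times must match pulse rows")
  out <- colMeans(pulse_mat)
  c(out, mean_rr = mean(diff(sort(peak_times))))
}

#' Assemble the ten-input feature vector
#'
#' @param morph named vector from [window_features()] (eight values)
#' @param profile subject profile supplying `age` and `gender`
#' @return named numeric vector of length 10 in [feature_names()] order
#' @export
assemble_feature_vector <- function(morph, profile) {
  need <- FEATURE_NAMES[1:8]
  if (!all(need %in% names(morph)))
    stop("morphology vector missing: ",
         paste(setdiff(need, names(morph)), collapse = ", "))
  if (is.null(profile$age) || is.null(profile$gender) ||
      is.na(profile$age) || is.na(profile$gender))
    stop("invalid profile: age and gender are required")
  if (!profile$gender %in% c(0, 1))
    stop("invalid profile: gender must be coded 0 (female) or 1 (male)")
  fv <- c(morph[need], age = as.numeric(profile$age),
          gender = as.numeric(profile$gender))
  names(fv) <- FEATURE_NAMES
  fv
}

#' Extract windowed feature vectors from a raw record
#'
#' Runs the full per-subject chain: band-pass filter, pulse delineation,
#' per-pulse morphology, assignment of pulses to consecutive 15-s windows
#' by systolic-peak time (partial trailing windows discarded), activity
#' gating, window averaging, and assembly with age and gender.  Degenerate
#' pulses and windows with fewer than 3 valid pulses are dropped.
#'
#' @param record a raw `ppg_record`
#' @param profile the subject's profile row (for age/gender)
#' @param window_s window length in seconds (default 15)
#' @param activity_threshold maximum tolerated activity count (default 5);
#'   ignored when the record has no counts
#' @param filter band-pass before delineation (default TRUE)
#' @return data.frame with `subject_id`, `window_id` and the ten feature
#'   columns, one row per accepted window (possibly zero rows)
#' @export
extract_features <- function(record, profile, window_s = 15,
                             activity_threshold = 5, filter = TRUE) {
  stopifnot(inherits(record, "ppg_record"))
  fs <- record$sampling_rate
  filtered <- if (filter) bandpass_filter(record) else record
  seg <- detect_pulses(filtered)
  empty <- stats::setNames(
    data.frame(matrix(numeric(0), ncol = 12)),
    c("subject_id", "window_id", FEATURE_NAMES))
  if (nrow(seg) == 0) return(empty)

  n_win <- floor(length(record$samples) / fs / window_s)
  if (n_win < 1) return(empty)
  accepted <- if (is.null(record$activity_counts)) seq_len(n_win) else
    gate_by_activity(record, activity_threshold)

  peak_t <- (seg$peak_index - 1L) / fs
  win_id <- floor(peak_t / window_s) + 1L

  rows <- lapply(intersect(seq_len(n_win), accepted), function(w) {
    in_w <- which(win_id == w)
    if (length(in_w) < 3) return(NULL)
    pf <- lapply(in_w, function(i) pulse_features(filtered, seg[i, ]))
    ok <- !vapply(pf, is.null, logical(1))
    if (sum(ok) < 3) return(NULL)
    morph <- window_features(do.call(rbind, pf[ok]), peak_t[in_w][ok])
    fv <- assemble_feature_vector(morph, profile)
    cbind(data.frame(subject_id = profile$subject_id, window_id = w,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature tables for a whole cohort
#'
#' @param cohort a [sample_cohort()] data.frame
#' @param config the [synthetic_config()] used to synthesize waveforms
#' @param ... passed to [extract_features()]
#' @return stacked feature data.frame with the subjects' true BP joined on
#'   (`sbp_true`, `dbp_true`), one row per (subject, window)
#' @export
cohort_features <- function(cohort, config, ...) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    prof <- cohort[i, ]
    rec <- synthesize_ppg(prof, config)
    ft <- extract_features(rec, prof, ...)
    if (nrow(ft) == 0) return(NULL)
    ft$sbp_true <- prof$sbp_true
    ft$dbp_true <- prof$dbp_true
    ft
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no usable windows in the whole cohort")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
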