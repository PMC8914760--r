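#' File formats
#'
#' Tabular artifacts (cohorts, feature tables, predictions) travel as CSV
#' with fixed, documented headers; model banks, evaluation reports and
#' calibration states as JSON (no opaque binaries, so banks are portable
#' and diffable).  Waveforms are one-column CSV per subject plus a JSON
#' sidecar carrying the sampling rate.  Gender is coded 0 = female,
#' 1 = male; ages are integer years.
#'
#' @name io
NULL

BANK_FORMAT_VERSION <- 1L

check_columns <- function(df, required, kind) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("schema error in ", kind, " table: missing column(s) ",
         paste(miss, collapse = ", "))
  invisible(df)
}

#' Read / write cohort tables
#'
#' Columns: `subject_id`, `age`, `gender`, `sbp_true`, `dbp_true`,
#' `heart_rate`.
#'
#' @param cohort a cohort data.frame
#' @param path CSV file path
#' @return `read_cohort()` returns the validated data.frame
#' @export
write_cohort <- function(cohort, path) {
  check_columns(cohort, c("subject_id", "age", "gender", "sbp_true",
                          "dbp_true", "heart_rate"), "cohort")
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "age", "gender", "sbp_true",
                      "dbp_true", "heart_rate"), "cohort")
  df
}

#' Read / write feature tables
#'
#' Columns: `subject_id`, `window_id`, the ten [feature_names()] and,
#' when ground truth is attached, `sbp_true` and `dbp_true`.
#'
#' @param features a feature data.frame
#' @param path CSV file path
#' @return `read_features()` returns the validated data.frame
#' @export
write_features <- function(features, path) {
  check_columns(features, c("subject_id", "window_id", FEATURE_NAMES),
                "features")
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("subject_id", "window_id", FEATURE_NAMES), "features")
  df
}

#' Write a waveform with its JSON sidecar
#'
#' @param record a `ppg_record`
#' @param dir output directory; files are `<subject_id>.csv` (one
#'   `amplitude` column) and `<subject_id>.json`
#' @param seed seed recorded in the sidecar
#' @return `read_waveform()` returns the reconstructed `ppg_record`
#' @export
write_waveform <- function(record, dir, seed = NA_integer_) {
  stopifnot(inherits(record, "ppg_record"))
  base <- file.path(dir, record$subject_id)
  utils::write.csv(data.frame(amplitude = record$samples),
                   paste0(base, ".csv"), row.names = FALSE)
  side <- list(subject_id = record$subject_id,
               sampling_rate_hz = record$sampling_rate,
               duration_s = length(record$samples) / record$sampling_rate,
               seed = seed)
  if (!is.null(record$activity_counts))
    side$activity_counts <- record$activity_counts
  jsonlite::write_json(side, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(base)
}

#' @rdname write_waveform
#' @param subject_id id whose pair of files to read from `dir`
#' @export
read_waveform <- function(dir, subject_id) {
  base <- file.path(dir, subject_id)
  side <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(base, ".csv"))
  check_columns(df, "amplitude", "waveform")
  ppg_record(df$amplitude, side$sampling_rate_hz,
             activity_counts = side$activity_counts,
             subject_id = side$subject_id)
}

## Serialize one gpr_model to a plain list.
gpr_to_list <- function(m) {
  list(params = list(sigma_f = m$params$sigma_f, sigma_l = m$params$sigma_l,
                     sigma_n2 = m$params$sigma_n2,
                     distance = m$params$distance),
       ard = m$ard,
       standardizer = m$standardizer,
       X = m$X, y = m$y, log_marginal = m$log_marginal)
}

gpr_from_list <- function(l) {
  params <- kernel_params(l$params$sigma_f, l$params$sigma_l,
                          l$params$sigma_n2, distance = l$params$distance)
  st <- l$standardizer
  model <- structure(list(
    X = matrix(unlist(l$X), nrow = length(l$y)),
    y = as.numeric(l$y), params = params, ard = isTRUE(l$ard),
    standardizer = list(x_mean = as.numeric(st$x_mean),
                        x_sd = as.numeric(st$x_sd),
                        y_mean = st$y_mean, y_sd = st$y_sd),
    log_marginal = l$log_marginal), class = "gpr_model")
  gpr_cache_alpha(model)
}

#' Read / write a model bank as JSON
#'
#' The file holds a manifest (`format_version`, target, scheme,
#' provenance) plus every cell's standardizer, hyperparameters and
#' training data; the predictive cache is rebuilt on read.
#'
#' @param bank a `model_bank`
#' @param path JSON file path
#' @return `read_bank()` returns the reconstructed `model_bank`
#' @export
write_bank <- function(bank, path) {
  stopifnot(inherits(bank, "model_bank"))
  obj <- list(format_version = BANK_FORMAT_VERSION, target = bank$target,
              scheme = list(width = bank$scheme$width,
                            edges = bank$scheme$edges,
                            labels = bank$scheme$labels),
              provenance = bank$provenance,
              models = lapply(bank$models, gpr_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) ||
      obj$format_version != BANK_FORMAT_VERSION)
    stop("unknown bank format version: ",
         if (is.null(obj$format_version)) "<absent>" else obj$format_version)
  scheme <- structure(list(width = obj$scheme$width,
                           edges = as.numeric(obj$scheme$edges),
                           labels = obj$scheme$labels),
                      class = "age_bin_scheme")
  models <- lapply(obj$models, gpr_from_list)
  structure(list(target = obj$target, scheme = scheme, models = models,
                 provenance = obj$provenance), class = "model_bank")
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`
#' @param path JSON file path
#' @return the path, invisibly
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

report_to_list <- function(report) {
  out <- list(target = report$target,
              stats = unclass(report$stats),
              bhs = list(per_threshold = as.list(report$bhs$per_threshold),
                         overall = report$bhs$overall),
              aami_pass = report$aami_pass,
              ba_lower = report$ba_lower, ba_upper = report$ba_upper,
              pearson_r = report$pearson_r, pearson_p = report$pearson_p)
  if (!is.null(report$subgroups))
    out$subgroups <- lapply(report$subgroups, function(s) {
      if (isTRUE(s$undefined)) list(n = s$n, undefined = TRUE)
      else report_to_list(s)
    })
  out
}
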