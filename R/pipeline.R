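#' Pipeline configuration and command runner
#'
#' The pipeline ties the modules into shell-friendly stages operating on
#' files in an output directory: `simulate` writes the cohort and
#' waveforms, `train` the serialized model banks, `calibrate` per-subject
#' calibration states, `predict` a per-window BP table, `evaluate` the
#' total- and interval-mode report JSON, and `sweep` the grouping-width
#' table.  One seed in the configuration drives every stochastic stage,
#' so a full `simulate` to `evaluate` chain is reproducible.
#'
#' @name interface
NULL

#' Build a pipeline configuration
#'
#' @param config_file optional YAML file; keys below override the defaults
#'   and are themselves overridden by non-NULL arguments
#' @param seed integer master seed
#' @param n_subjects,n_train,n_test cohort size and subject split
#' @param duration,sampling_rate,noise_sd,baseline_wander_amplitude
#'   synthetic-generator settings (see [synthetic_config()])
#' @param filter_low,filter_high band-pass edges, Hz
#' @param window_s analysis-window length, seconds
#' @param activity_threshold motion-gating threshold, counts
#' @param sbp_width,dbp_width age-grouping widths in years
#' @param min_cell_size minimum subjects per trainable cell
#' @return an object of class `pipeline_config`
#' @export
pipeline_config <- function(config_file = NULL, seed = NULL,
                            n_subjects = NULL, n_train = NULL, n_test = NULL,
                            duration = NULL, sampling_rate = NULL,
                            noise_sd = NULL, baseline_wander_amplitude = NULL,
                            filter_low = NULL, filter_high = NULL,
                            window_s = NULL, activity_threshold = NULL,
                            sbp_width = NULL, dbp_width = NULL,
                            min_cell_size = NULL) {
  cfg <- list(seed = 1L, n_subjects = 435L, n_train = 306L, n_test = 129L,
              duration = 60, sampling_rate = 256, noise_sd = 0.02,
              baseline_wander_amplitude = 0.1,
              filter_low = 0.5, filter_high = 10,
              window_s = 15, activity_threshold = 5,
              sbp_width = 30, dbp_width = 15, min_cell_size = 5)
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ", config_file)
    user <- yaml::read_yaml(config_file)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("invalid config: unknown key(s) ",
                          paste(bad, collapse = ", "))
    cfg[names(user)] <- user
  }
  args <- list(seed = seed, n_subjects = n_subjects, n_train = n_train,
               n_test = n_test, duration = duration,
               sampling_rate = sampling_rate, noise_sd = noise_sd,
               baseline_wander_amplitude = baseline_wander_amplitude,
               filter_low = filter_low, filter_high = filter_high,
               window_s = window_s, activity_threshold = activity_threshold,
               sbp_width = sbp_width, dbp_width = dbp_width,
               min_cell_size = min_cell_size)
  set <- !vapply(args, is.null, logical(1))
  cfg[names(args)[set]] <- args[set]
  if (cfg$n_train + cfg$n_test > cfg$n_subjects)
    stop("invalid config: n_train + n_test exceeds n_subjects")
  if (!(cfg$filter_low > 0 && cfg$filter_low < cfg$filter_high &&
        cfg$filter_high < cfg$sampling_rate / 2))
    stop("invalid config: band edges must satisfy 0 < low < high < fs/2")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

cfg_synth <- function(cfg) {
  synthetic_config(n_subjects = cfg$n_subjects, seed = cfg$seed,
                   duration = cfg$duration, sampling_rate = cfg$sampling_rate,
                   noise_sd = cfg$noise_sd,
                   baseline_wander_amplitude = cfg$baseline_wander_amplitude)
}

need_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact '", path, "'; run the `", producer,
         "` command first")
  path
}

#' Run one pipeline command
#'
#' @param config a [pipeline_config()]
#' @param command one of `simulate`, `train`, `calibrate`, `predict`,
#'   `evaluate`, `sweep`
#' @param out_dir artifact directory (created if absent)
#' @return invisibly, the paths of the artifacts written
#' @export
run_pipeline <- function(config,
                         command = c("simulate", "train", "calibrate",
                                     "predict", "evaluate", "sweep"),
                         out_dir = ".") {
  stopifnot(inherits(config, "pipeline_config"))
  command <- match.arg(command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scfg <- cfg_synth(config)
  p <- function(...) file.path(out_dir, ...)
  message(sprintf("[ppgbp] %s (seed %d) -> %s", command, config$seed, out_dir))

  split_ids <- function(cohort) {
    perm <- with_local_seed(config$seed + 1L, sample(cohort$subject_id))
    list(train = perm[seq_len(config$n_train)],
         test = perm[config$n_train + seq_len(config$n_test)])
  }
  features_of <- function(cohort) {
    cohort_features(cohort, scfg, window_s = config$window_s,
                    activity_threshold = config$activity_threshold)
  }

  written <- character(0)
  if (command == "simulate") {
    cohort <- sample_cohort(scfg)
    write_cohort(cohort, p("cohort.csv"))
    wdir <- p("waveforms")
    dir.create(wdir, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort)))
      write_waveform(synthesize_ppg(cohort[i, ], scfg), wdir,
                     seed = config$seed)
    feats <- features_of(cohort)
    write_features(feats, p("features.csv"))
    written <- c(p("cohort.csv"), p("features.csv"), wdir)
  } else if (command == "train") {
    feats <- read_features(need_artifact(p("features.csv"), "simulate"))
    cohort <- read_cohort(need_artifact(p("cohort.csv"), "simulate"))
    ids <- split_ids(cohort)
    tr <- feats[feats$subject_id %in% ids$train, ]
    for (target in c("SBP", "DBP")) {
      width <- if (target == "SBP") config$sbp_width else config$dbp_width
      bank <- suppressWarnings(
        train_bank(tr, target, age_bin_scheme(width),
                   min_cell_size = config$min_cell_size))
      write_bank(bank, p(sprintf("bank_%s.json", tolower(target))))
      written <- c(written, p(sprintf("bank_%s.json", tolower(target))))
    }
  } else if (command %in% c("calibrate", "predict", "evaluate")) {
    feats <- read_features(need_artifact(p("features.csv"), "simulate"))
    cohort <- read_cohort(need_artifact(p("cohort.csv"), "simulate"))
    ids <- split_ids(cohort)
    preds <- list()
    for (target in c("SBP", "DBP")) {
      bank <- read_bank(need_artifact(p(sprintf("bank_%s.json",
                                                tolower(target))), "train"))
      ycol <- if (target == "SBP") "sbp_true" else "dbp_true"
      te <- feats[feats$subject_id %in% ids$test, ]
      if (!ycol %in% names(te))
        te <- merge(te, cohort[, c("subject_id", "sbp_true", "dbp_true")],
                    by = "subject_id")
      rows <- lapply(unique(te$subject_id), function(sid) {
        sw <- te[te$subject_id == sid, ]
        sw <- sw[order(sw$window_id), ]
        if (nrow(sw) < 2) return(NULL)
        X <- as.matrix(sw[, FEATURE_NAMES])
        state <- tryCatch(
          calibrate_select(bank, X[1L, ], sw[[ycol]][1L], sw$gender[1L], sid),
          error = function(e) NULL)
        if (is.null(state)) return(NULL)
        if (command == "calibrate") {
          jsonlite::write_json(
            list(subject_id = sid, target = target,
                 selected_bin = state$selected_bin,
                 selected_gender = state$selected_gender,
                 scores = as.list(state$scores)),
            p(sprintf("calibration_%s_%s.json", tolower(target), sid)),
            auto_unbox = TRUE, digits = NA)
          return(NULL)
        }
        est_u <- tryCatch(predict_uncalibrated(bank, X[-1L, , drop = FALSE]),
                          error = function(e) NULL)
        if (is.null(est_u)) return(NULL)   # e.g. subject's cell untrained
        data.frame(subject_id = sid, window_id = sw$window_id[-1L],
                   target = target, actual = sw[[ycol]][-1L],
                   uncalibrated = est_u,
                   calibrated = predict_calibrated(
                     state, bank, X[-1L, , drop = FALSE]),
                   stringsAsFactors = FALSE)
      })
      preds[[target]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    }
    if (command == "calibrate") {
      written <- Sys.glob(p("calibration_*.json"))
    } else {
      pred <- do.call(rbind, preds)
      rownames(pred) <- NULL
      if (command == "predict") {
        utils::write.csv(pred, p("predictions.csv"), row.names = FALSE)
        written <- p("predictions.csv")
      } else {
        for (target in c("SBP", "DBP")) {
          pr <- pred[pred$target == target, ]
          write_report(evaluate_bp(pr$actual, pr$calibrated, target),
                       p(sprintf("report_%s_calibrated.json", tolower(target))))
          write_report(evaluate_bp(pr$actual, pr$uncalibrated, target),
                       p(sprintf("report_%s_uncalibrated.json", tolower(target))))
        }
        written <- Sys.glob(p("report_*.json"))
      }
    }
  } else if (command == "sweep") {
    feats <- read_features(need_artifact(p("features.csv"), "simulate"))
    cohort <- read_cohort(need_artifact(p("cohort.csv"), "simulate"))
    ids <- split_ids(cohort)
    tr <- feats[feats$subject_id %in% ids$train, ]
    te <- feats[feats$subject_id %in% ids$test, ]
    out <- do.call(rbind, lapply(c("SBP", "DBP"), function(target) {
      sw <- grouping_sweep(tr, te, target,
                           min_cell_size = config$min_cell_size)
      sw$target <- target
      sw
    }))
    utils::write.csv(out, p("sweep.csv"), row.names = FALSE)
    written <- p("sweep.csv")
  }
  invisible(written)
}
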