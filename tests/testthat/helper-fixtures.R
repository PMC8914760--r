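# Shared fixtures, built in code.  Expensive objects are memoized per
# test run in this environment.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# noise-free generator config for oracle comparisons
clean_config <- function(n = 50, seed = 3, duration = 15) {
  synthetic_config(n_subjects = n, seed = seed, duration = duration,
                   noise_sd = 0, baseline_wander_amplitude = 0)
}

fixed_profile <- function(age = 40L, gender = 1L, sbp = 120, dbp = 75,
                          hr = 60, id = "SX01") {
  list(subject_id = id, age = age, gender = gender,
       sbp_true = sbp, dbp_true = dbp, heart_rate = hr)
}

# feature table straight from ground-truth morphology (no waveforms):
# fast fixture for bank/sweep tests; `jitter_sd` adds measurement-like
# noise on the morphology columns
gt_feature_table <- function(cohort, config, jitter_sd = 0, seed = 1) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    fv <- ground_truth_features(cohort[i, ], config)
    cbind(data.frame(subject_id = cohort$subject_id[i], window_id = 1L,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(fv)),
          data.frame(sbp_true = cohort$sbp_true[i],
                     dbp_true = cohort$dbp_true[i]))
  })
  out <- do.call(rbind, rows)
  if (jitter_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    for (cn in feature_names()[1:8]) {
      s <- stats::sd(out[[cn]])
      out[[cn]] <- out[[cn]] + stats::rnorm(nrow(out), 0, jitter_sd * s)
    }
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  out
}

# the full-size synthetic study (435 subjects, 306/129 split) at seed 1;
# shared by the acceptance checks
full_study <- function() memo("full_study", run_study(seed = 1))

# a small trained SBP bank over ground-truth features
small_sbp_bank <- function() memo("small_sbp_bank", {
  cfg <- synthetic_config(n_subjects = 150, seed = 11)
  co <- sample_cohort(cfg)
  suppressWarnings(train_bank(gt_feature_table(co, cfg), "SBP"))
})
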