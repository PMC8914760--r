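#' Synthetic PPG cohort with known ground truth
#'
#' The clinical database behind the estimator is not publicly deposited, so
#' the package ships a generator that emulates its documented properties:
#' ages 15-94 with the bulk of participants in young adulthood, systolic
#' pressure rising with age, diastolic pressure rising to about age 60 and
#' falling thereafter, a right-skewed hypertensive tail so that at least 5%
#' of readings fall at SBP <= 100 mmHg and at least 5% at SBP >= 160 mmHg,
#' and pulse morphology whose shape parameters co-vary with blood pressure
#' so the regression stage has something to learn.
#'
#' Each beat of the synthetic waveform is the sum of a systolic and a
#' diastolic Gaussian; the morphology link makes the systolic width (hence
#' the maximal upslope and the systolic-area fraction) a decreasing affine
#' function of SBP, the diastolic amplitude an increasing function of DBP
#' (and decreasing in SBP), and the systolic-to-diastolic spacing a slowly
#' decreasing function of age.  White measurement noise and sub-0.4-Hz
#' sinusoidal baseline wander are added on top.
#'
#' @name synthetic_cohort
NULL

#' Configuration for the synthetic cohort generator
#'
#' @param n_subjects number of subjects (>= 1)
#' @param seed integer seed; identical config + seed reproduces the cohort
#'   and every waveform bit-for-bit
#' @param duration record length in seconds (default 60)
#' @param sampling_rate sampling rate in Hz (default 256, must exceed 20)
#' @param noise_sd additive white-noise SD in units of the unit pulse
#'   amplitude (default 0.02)
#' @param baseline_wander_amplitude amplitude of the sinusoidal baseline
#'   wander, same units (default 0.1; frequency drawn below 0.4 Hz)
#' @param morphology_link named list of link coefficients mapping
#'   (sbp, dbp, age) to pulse-shape parameters; see Details
#' @details The default morphology link is
#' \describe{
#'   \item{systolic width}{`ws = 0.10 + 9e-3 r(age) + 1e-4 (age - 50) -
#'     3.2e-4 (sbp - 120)` s, clamped to \[0.05, 0.13\], where `r(age)` is
#'     the vascular regime level (-1 below 30 y, 0 for 30-60 y, +1 from
#'     60 y); narrower systolic peaks mean steeper upslopes, and the
#'     regime steps make the slope-to-SBP mapping age-group specific,
#'     which is what lets feedback calibration identify a subject's
#'     age-group model}
#'   \item{diastolic amplitude}{`ad = 0.45 + 0.05 q(age) + 5e-4 (age - 50)
#'     + 0.005 (dbp - 75) - 0.002 (sbp - 120)`, clamped to \[0.10, 0.80\],
#'     with `q(age)` stepping every 15 years from -2 (below 30 y) to +2
#'     (75 y and over)}
#'   \item{systolic peak delay}{`ts = 0.18` s from the beat origin}
#'   \item{diastolic spacing}{`dtd = 0.30 - 8e-4 (age - 50)` s, clamped to
#'     \[0.22, 0.38\]}
#'   \item{diastolic width}{`wd = 0.16` s}
#' }
#' @return an object of class `synthetic_config`
#' @export
synthetic_config <- function(n_subjects = 435L, seed = 1L, duration = 60,
                             sampling_rate = 256, noise_sd = 0.02,
                             baseline_wander_amplitude = 0.1,
                             morphology_link = default_morphology_link()) {
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("invalid config: n_subjects must be >= 1")
  if (sampling_rate <= 20) stop("invalid config: sampling_rate must exceed 20 Hz")
  if (duration <= 0) stop("invalid config: duration must be positive")
  if (noise_sd < 0 || baseline_wander_amplitude < 0)
    stop("invalid config: noise amplitudes must be nonnegative")
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 duration = duration, sampling_rate = sampling_rate,
                 noise_sd = noise_sd,
                 baseline_wander_amplitude = baseline_wander_amplitude,
                 morphology_link = morphology_link),
            class = "synthetic_config")
}

#' @rdname synthetic_config
#' @export
default_morphology_link <- function() {
  list(ws0 = 0.10, ws_sbp = 3.2e-4, ws_age = 1.0e-4, ws_regime = 9e-3,
       ws_min = 0.05, ws_max = 0.13,
       ad0 = 0.45, ad_dbp = 0.005, ad_sbp = 0.002, ad_age = 5.0e-4,
       ad_regime = 0.05, ad_min = 0.10, ad_max = 0.80,
       ts = 0.18,
       dtd0 = 0.30, dtd_age = 8e-4, dtd_min = 0.22, dtd_max = 0.38,
       wd = 0.22)
}

## Vascular age-group regimes: the mapping from BP to pulse shape differs
## between age groups (arterial stiffening is not a smooth function of
## chronological age here but a group-level regime), which is what makes
## the feedback-calibration search able to identify a subject's group.
## Systolic-width regimes step at 30 and 60 years; diastolic-amplitude
## regimes step every 15 years from 30.
ws_regime_level <- function(age) findInterval(age, c(30, 60)) - 1   # -1, 0, 1
ad_regime_level <- function(age) findInterval(age, c(30, 45, 60, 75)) - 2

## Pulse-shape parameters implied by a subject's (sbp, dbp, age, hr).
## Intra-beat timings scale with sqrt(RR) so beats neither fuse at high
## heart rates nor leave a flat (foot-ambiguous) gap at low ones.
pulse_shape <- function(sbp, dbp, age, heart_rate,
                        link = default_morphology_link()) {
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  tscale <- sqrt(60 / heart_rate)
  list(ws = clamp(link$ws0 + link$ws_regime * ws_regime_level(age) +
                    link$ws_age * (age - 50) - link$ws_sbp * (sbp - 120),
                  link$ws_min, link$ws_max),
       ad = clamp(link$ad0 + link$ad_regime * ad_regime_level(age) +
                    link$ad_age * (age - 50) +
                    link$ad_dbp * (dbp - 75) - link$ad_sbp * (sbp - 120),
                  link$ad_min, link$ad_max),
       ts = link$ts * tscale,
       dtd = clamp(link$dtd0 - link$dtd_age * (age - 50),
                   link$dtd_min, link$dtd_max) * tscale,
       wd = link$wd * tscale)
}

## Run code under a local RNG state, restoring the caller's afterwards.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## Deterministic per-subject seed below 2^31.
subject_seed <- function(base_seed, subject_id) {
  idx <- suppressWarnings(as.integer(gsub("\\D", "", subject_id)))
  if (is.na(idx)) idx <- sum(utf8ToInt(subject_id))
  (abs(base_seed) * 100003L + idx * 7919L) %% 2147483629L
}

#' Draw a cohort of subject profiles
#'
#' Ages mix a young-adult mode (ages 20-34) with a uniform spread over
#' 15-94.  Systolic pressure is a normotensive base
#' `105 + 0.45 (age - 15)` mmHg (SD 12) plus, for an age-increasing
#' fraction of hypertensive subjects, a right-skewed gamma elevation;
#' diastolic pressure peaks near age 60 and declines after.  Gender
#' (0 = female, 1 = male) carries a small additive offset.  All readings
#' are clamped to SBP 80-250 / DBP 40-150 mmHg with SBP > DBP enforced.
#'
#' @param config a [synthetic_config()]
#' @return a data.frame with columns `subject_id`, `age`, `gender`,
#'   `sbp_true`, `dbp_true`, `heart_rate`
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_subjects
  with_local_seed(config$seed, {
    young <- stats::runif(n) < 0.35
    age <- ifelse(young, sample(20:34, n, replace = TRUE),
                  sample(15:94, n, replace = TRUE))
    gender <- stats::rbinom(n, 1L, 0.5)
    p_hyper <- pmin(pmax(0.06 + 0.005 * (age - 30), 0.06), 0.40)
    hyper <- stats::runif(n) < p_hyper

    sbp <- 105 + 0.45 * (age - 15) + 4 * gender + stats::rnorm(n, 0, 12) +
      ifelse(hyper, stats::rgamma(n, shape = 2, scale = 16), 0)
    dbp_mean <- ifelse(age <= 60, 65 + 0.25 * (age - 15),
                       65 + 0.25 * 45 - 0.20 * (age - 60))
    dbp <- dbp_mean + 2 * gender + stats::rnorm(n, 0, 8) +
      ifelse(hyper, stats::rgamma(n, shape = 2, scale = 5), 0)

    sbp <- pmin(pmax(sbp, 80), 250)
    dbp <- pmin(pmax(dbp, 40), 150)
    dbp <- pmin(dbp, sbp - 15)
    dbp <- pmax(dbp, 40)
    sbp <- pmax(sbp, dbp + 15)

    hr <- round(pmin(pmax(stats::rnorm(n, 74, 9), 50), 110))
    data.frame(subject_id = sprintf("S%04d", seq_len(n)),
               age = as.integer(age), gender = as.integer(gender),
               sbp_true = round(sbp, 1), dbp_true = round(dbp, 1),
               heart_rate = as.numeric(hr), stringsAsFactors = FALSE)
  })
}

## Noise-free periodic pulse train evaluated at times t (seconds).
pulse_train <- function(t, shape, heart_rate, n_beats, t0 = 0) {
  rr <- 60 / heart_rate
  centers <- t0 + rr * (seq_len(n_beats) - 1L)
  sys_c <- centers + shape$ts
  dia_c <- sys_c + shape$dtd
  y <- numeric(length(t))
  for (k in seq_len(n_beats)) {
    y <- y + exp(-(t - sys_c[k])^2 / (2 * shape$ws^2)) +
      shape$ad * exp(-(t - dia_c[k])^2 / (2 * shape$wd^2))
  }
  y
}

#' Synthesize a raw PPG record for one subject
#'
#' @param profile one row of a [sample_cohort()] data.frame (or an
#'   equivalent list with the same fields)
#' @param config a [synthetic_config()]
#' @return a `ppg_record`: list with `samples`, `sampling_rate`,
#'   `activity_counts` (zeros, one per full 15-s window; the generator
#'   emulates the at-rest protocol) and `subject_id`
#' @export
synthesize_ppg <- function(profile, config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_profile(profile)
  fs <- config$sampling_rate
  n_samp <- round(config$duration * fs)
  t <- (seq_len(n_samp) - 1L) / fs
  shape <- pulse_shape(profile$sbp_true, profile$dbp_true, profile$age,
                       profile$heart_rate, config$morphology_link)
  rr <- 60 / profile$heart_rate
  n_beats <- ceiling(config$duration / rr) + 1L
  clean <- pulse_train(t, shape, profile$heart_rate, n_beats)

  sd_seed <- subject_seed(config$seed, profile$subject_id)
  noisy <- with_local_seed(sd_seed, {
    wf <- clean
    if (config$baseline_wander_amplitude > 0) {
      f_w <- stats::runif(1, 0.15, 0.39)       # below 0.4 Hz
      ph <- stats::runif(1, 0, 2 * pi)
      wf <- wf + config$baseline_wander_amplitude * sin(2 * pi * f_w * t + ph)
    }
    if (config$noise_sd > 0)
      wf <- wf + stats::rnorm(n_samp, 0, config$noise_sd)
    wf
  })
  n_windows <- floor(config$duration / 15)
  ppg_record(noisy, fs, activity_counts = rep(0, max(n_windows, 0L)),
             subject_id = profile$subject_id)
}

validate_profile <- function(profile) {
  need <- c("subject_id", "age", "gender", "sbp_true", "dbp_true", "heart_rate")
  miss <- setdiff(need, names(profile))
  if (length(miss)) stop("invalid profile: missing ", paste(miss, collapse = ", "))
  if (!profile$gender %in% c(0L, 1L)) stop("invalid profile: gender must be 0 or 1")
  if (profile$age < 15 || profile$age > 94) stop("invalid profile: age outside 15-94")
  if (profile$sbp_true <= profile$dbp_true) stop("invalid profile: SBP must exceed DBP")
  if (profile$heart_rate < 40 || profile$heart_rate > 180)
    stop("invalid profile: heart rate outside 40-180")
  invisible(profile)
}

#' Ground-truth morphology features of the ideal pulse
#'
#' Computes the noise-free feature vector implied by the morphology link
#' for a subject, by dense numerical analysis of the periodic ideal pulse:
#' the waveform and its analytic derivative are evaluated at 2048 Hz over
#' one central beat, the pulse foot taken as the minimum between
#' consecutive systolic peaks, areas by the trapezoid rule against the
#' onset-to-end chord, and the maximal slope from the analytic derivative.
#' This is the oracle the feature-extraction module is tested against.
#'
#' @param profile a subject profile row
#' @param config a [synthetic_config()]
#' @return named numeric vector with the ten model inputs:
#'   `a1_ratio`, `a2_ratio`, `a1_over_ac`, `a2_over_ac`, `max_slope`,
#'   `systolic_time`, `diastolic_time`, `mean_rr`, `age`, `gender`
#' @export
ground_truth_features <- function(profile, config = synthetic_config()) {
  validate_profile(profile)
  shape <- pulse_shape(profile$sbp_true, profile$dbp_true, profile$age,
                       profile$heart_rate, config$morphology_link)
  fs_hi <- 2048
  rr <- 60 / profile$heart_rate
  n_beats <- 7L
  t <- seq(0, rr * n_beats, by = 1 / fs_hi)
  y <- pulse_train(t, shape, profile$heart_rate, n_beats)

  ## analytic derivative of the Gaussian mixture
  centers <- rr * (seq_len(n_beats) - 1L)
  dy <- numeric(length(t))
  for (k in seq_len(n_beats)) {
    cs <- centers[k] + shape$ts
    cd <- cs + shape$dtd
    dy <- dy - (t - cs) / shape$ws^2 * exp(-(t - cs)^2 / (2 * shape$ws^2)) -
      shape$ad * (t - cd) / shape$wd^2 * exp(-(t - cd)^2 / (2 * shape$wd^2))
  }

  ## central beat: systolic peak nearest the middle, feet = minima between
  ## this peak and its neighbours' peaks
  mid <- 4L
  peak_idx <- vapply(c(mid - 1L, mid, mid + 1L), function(k) {
    lo <- which.min(abs(t - (centers[k] + shape$ts - 2 * shape$ws)))
    hi <- which.min(abs(t - (centers[k] + shape$ts + 2 * shape$ws)))
    lo + which.max(y[lo:hi]) - 1L
  }, integer(1))
  onset <- peak_idx[1] + which.min(y[peak_idx[1]:peak_idx[2]]) - 1L
  endi  <- peak_idx[2] + which.min(y[peak_idx[2]:peak_idx[3]]) - 1L
  peak <- peak_idx[2]

  seg <- onset:endi
  base <- y[onset] + (y[endi] - y[onset]) * (seg - onset) / (endi - onset)
  dev <- y[seg] - base
  dt <- 1 / fs_hi
  trap <- function(v) if (length(v) < 2) 0 else sum((v[-1] + v[-length(v)]) / 2) * dt
  i_peak <- peak - onset + 1L
  a1 <- trap(dev[1:i_peak])
  a2 <- trap(dev[i_peak:length(dev)])
  ac <- y[peak] - y[onset]
  max_slope <- max(dy[seg])
  c(a1_ratio = a1 / (a1 + a2), a2_ratio = a2 / (a1 + a2),
    a1_over_ac = a1 / ac, a2_over_ac = a2 / ac,
    max_slope = max_slope,
    systolic_time = (peak - onset) * dt, diastolic_time = (endi - peak) * dt,
    mean_rr = rr, age = as.numeric(profile$age),
    gender = as.numeric(profile$gender))
}
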