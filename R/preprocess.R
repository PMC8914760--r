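#' PPG preprocessing: filtering, pulse delineation, activity gating
#'
#' Raw reflective PPG mixes the pulsatile (AC) arterial component with a
#' large quasi-static (DC) level and baseline wander.  Analysis therefore
#' starts with a 0.5-10 Hz zero-phase band-pass, followed by beat
#' delineation (systolic peaks, then pulse feet as the minima between
#' them) and optional rejection of 15-s analysis windows whose activity
#' count exceeds a threshold, emulating steady-state gating from a
#' wrist-worn accelerometer.
#'
#' @name preprocess
NULL

#' Construct a PPG record
#'
#' @param samples numeric waveform (arbitrary amplitude units)
#' @param sampling_rate sampling rate, Hz (> 0)
#' @param activity_counts optional numeric vector, one count per 15-s
#'   analysis window
#' @param subject_id identifier string
#' @return an object of class `ppg_record`
#' @export
ppg_record <- function(samples, sampling_rate, activity_counts = NULL,
                       subject_id = "") {
  if (length(samples) == 0) stop("samples must be non-empty")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 activity_counts = activity_counts,
                 subject_id = subject_id),
            class = "ppg_record")
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so the passband sees unit gain, stopbands are
#' attenuated twice over, and beat timing is not shifted.  The -3 dB
#' corners are placed just outside the nominal band (0.8 low, 1.15 high)
#' so the whole 0.5-10 Hz analysis band lies in the flat region of the
#' response; a slow beat's fundamental is then passed at unit gain
#' rather than sitting on the corner.
#'
#' @param record a `ppg_record`
#' @param low,high nominal band edges in Hz (default 0.5-10)
#' @return the filtered `ppg_record`
#' @export
bandpass_filter <- function(record, low = 0.5, high = 10) {
  stopifnot(inherits(record, "ppg_record"))
  fs <- record$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band edges: need 0 < low < high < sampling_rate/2")
  corners <- c(0.8 * low, min(1.15 * high, 0.99 * fs / 2))
  bf <- signal::butter(4, corners / (fs / 2), type = "pass")
  x <- record$samples
  n <- length(x)
  ## odd-reflection padding absorbs the IIR start-up transient (the
  ## 0.5 Hz edge has a multi-second settling time)
  pad <- min(n - 1L, ceiling(6 * fs / low))
  if (pad > 0) {
    head_pad <- 2 * x[1L] - x[seq(pad + 1L, 2L)]
    tail_pad <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    y <- as.numeric(signal::filtfilt(bf, c(head_pad, x, tail_pad)))
    record$samples <- y[pad + seq_len(n)]
  } else {
    record$samples <- as.numeric(signal::filtfilt(bf, x))
  }
  record
}

## Local maxima above `min_height`, greedily enforcing a minimum spacing
## (samples), tallest first.
find_peaks <- function(x, min_dist, min_height) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_dist)) keep <- c(keep, i)
  }
  sort(keep)
}

## Dominant beat frequency (Hz) from the periodogram over 0.5-3.2 Hz,
## preferring the subharmonic when the waveform's fundamental is weaker
## than its first harmonic.
dominant_beat_frequency <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  if (n < fs * 4) return(1.2)                 # too short to resolve; ~72 bpm
  sp <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1L) * fs / n
  band <- freq >= 0.5 & freq <= 3.2
  if (!any(band)) return(1.2)
  f0 <- freq[band][which.max(sp[band])]
  half <- f0 / 2
  if (half >= 0.5) {
    at <- function(f) sp[which.min(abs(freq - f))]
    if (at(half) >= 0.5 * at(f0)) f0 <- half
  }
  f0
}

#' Delineate cardiac pulses
#'
#' Finds systolic peaks on a lightly smoothed copy of the signal (25-ms
#' moving average) with a minimum inter-peak distance of 0.33 s (180 bpm)
#' and a prominence floor at 30% of the upper-amplitude range.  Pulse feet
#' (onsets) are the minima between consecutive peaks; the segment for each
#' beat runs foot -> peak -> next foot, with the first onset and last end
#' searched within one median beat of the edge peaks.
#'
#' @param record a filtered `ppg_record`
#' @return a data.frame with integer columns `onset_index`, `peak_index`,
#'   `end_index`, one row per delineated beat (possibly empty)
#' @export
detect_pulses <- function(record) {
  stopifnot(inherits(record, "ppg_record"))
  x <- record$samples
  fs <- record$sampling_rate
  empty <- data.frame(onset_index = integer(0), peak_index = integer(0),
                      end_index = integer(0))
  k <- max(1L, round(0.025 * fs))
  if (k > 1) {
    sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
    sm[is.na(sm)] <- x[is.na(sm)]
  } else sm <- x
  rng <- range(sm)
  if (diff(rng) < 1e-12) return(empty)
  min_h <- rng[1] + 0.3 * diff(rng)
  ## minimum inter-peak spacing: 70% of the dominant beat period (so the
  ## diastolic wave of slow beats is not double-counted), floored at
  ## 0.33 s (180 bpm)
  f0 <- dominant_beat_frequency(sm, fs)
  min_dist <- max(round(0.33 * fs), round(0.7 * fs / f0))
  peaks <- find_peaks(sm, min_dist = min_dist, min_height = min_h)
  if (length(peaks) < 2) return(empty)

  ## refine each peak to the raw-signal maximum nearby
  half <- max(1L, round(0.05 * fs))
  peaks <- vapply(peaks, function(p) {
    lo <- max(1L, p - half); hi <- min(length(x), p + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) < 2) return(empty)

  feet <- vapply(seq_len(length(peaks) - 1L), function(i) {
    span <- peaks[i]:peaks[i + 1L]
    span[which.min(x[span])]
  }, integer(1))

  ## edge beats whose foot search would be clipped by the record boundary
  ## are dropped rather than emitted truncated
  med_rr <- stats::median(diff(peaks))
  lo0 <- peaks[1] - round(0.8 * med_rr)
  first_foot <- if (lo0 >= 1L) {
    span <- lo0:peaks[1]; span[which.min(x[span])]
  } else NA_integer_
  hiN <- peaks[length(peaks)] + round(0.8 * med_rr)
  last_end <- if (hiN <= length(x)) {
    span <- peaks[length(peaks)]:hiN; span[which.min(x[span])]
  } else NA_integer_

  onsets <- c(first_foot, feet)
  ends <- c(feet, last_end)
  seg <- data.frame(onset_index = as.integer(onsets),
                    peak_index = as.integer(peaks),
                    end_index = as.integer(ends))
  seg <- seg[!is.na(seg$onset_index) & !is.na(seg$end_index) &
               seg$onset_index < seg$peak_index &
               seg$peak_index < seg$end_index, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Gate analysis windows by activity count
#'
#' Accepts 15-s windows whose activity count is at or below the threshold
#' (boundary inclusive).  Records without activity counts are accepted in
#' full, with a warning, since gating cannot be applied.
#'
#' @param record a `ppg_record`
#' @param threshold maximum tolerated activity count (>= 0)
#' @return integer vector of accepted window indices (1-based)
#' @export
gate_by_activity <- function(record, threshold) {
  stopifnot(inherits(record, "ppg_record"))
  if (!is.numeric(threshold) || threshold < 0)
    stop("invalid config: activity threshold must be >= 0")
  n_win <- floor(length(record$samples) / record$sampling_rate / 15)
  if (is.null(record$activity_counts)) {
    warning("no activity counts on record '", record$subject_id,
            "'; accepting all windows")
    return(seq_len(n_win))
  }
  which(record$activity_counts <= threshold)
}
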