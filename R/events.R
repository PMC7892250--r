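#' Detect auditory stimulus onsets from the audio channel
#'
#' Trials are time-locked to the sound the subject actually hears, so stimulus
#' events are marked on the audio recording channel rather than the electrical
#' trigger (which leads the sound by the delivery delay). An event is placed at
#' the first sample where the rectified envelope (running maximum of `|x|` over
#' a short trailing window) crosses `threshold_frac` times the envelope
#' maximum; subsequent crossings are suppressed for `refractory` seconds.
#'
#' @param audio numeric vector, the audio channel.
#' @param rate sampling rate in Hz.
#' @param threshold_frac fraction of the envelope maximum in (0, 1),
#'   default 0.5.
#' @param refractory suppression window in seconds, default 0.5.
#' @param envelope_window trailing rectification window in seconds,
#'   default 0.01.
#' @return an [event_list()] of kind `"stimulus"`.
#' @export
detect_stimulus_events <- function(audio, rate, threshold_frac = 0.5,
                                   refractory = 0.5, envelope_window = 0.01) {
  if (anyNA(audio)) stop("audio channel contains NA/NaN")
  assert_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  assert_scalar(threshold_frac, "threshold_frac", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar(refractory, "refractory", lower = 0, strict_lower = TRUE)
  env <- running_max(abs(audio), max(1L, round(envelope_window * rate)))
  peak <- max(env)
  if (peak == 0) return(event_list())
  above <- env >= threshold_frac * peak
  onsets <- integer(0)
  gap <- round(refractory * rate)
  i <- 1L
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      onsets <- c(onsets, i)
      i <- i + gap
    } else {
      i <- i + 1L
    }
  }
  event_list((onsets - 1L) / rate, "stimulus")
}

# trailing running maximum over a window of w samples
running_max <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  out <- x
  for (k in seq_len(w - 1L)) {
    out <- pmax(out, c(rep(x[1L], k), x[seq_len(n - k)]))
  }
  out
}

#' Detect blink and cardiac artifact events
#'
#' Blink events are marked where either EOG channel exceeds `blink_threshold`
#' robust standard deviations (median absolute deviation scaled to the normal)
#' of that channel; cardiac events are R-peak-like local maxima of the ECG
#' exceeding `cardiac_threshold` robust SDs. Events closer than the refractory
#' window are merged onto the largest excursion. A flat channel yields no
#' events of that kind, with a warning.
#'
#' @param eog_v,eog_h,ecg numeric vectors of equal length (any may be `NULL`).
#' @param rate sampling rate in Hz.
#' @param blink_threshold,cardiac_threshold amplitude thresholds in robust-SD
#'   units (defaults 4 and 4).
#' @param refractory minimum separation between events of a kind in seconds
#'   (default 0.25).
#' @return an [event_list()] with kinds `"blink"` and `"cardiac"`.
#' @export
detect_artifact_events <- function(eog_v = NULL, eog_h = NULL, ecg = NULL,
                                   rate, blink_threshold = 4,
                                   cardiac_threshold = 4, refractory = 0.25) {
  assert_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  lens <- vapply(Filter(Negate(is.null), list(eog_v, eog_h, ecg)),
                 length, integer(1))
  if (length(lens) && length(unique(lens)) != 1L) {
    stop("auxiliary channels must have equal length")
  }
  gap <- round(refractory * rate)

  blink_scores <- NULL
  for (ch in list(eog_v, eog_h)) {
    if (is.null(ch)) next
    s <- robust_sd(ch)
    if (s == 0) {
      warning("flat EOG channel: no blink events detected from it")
      next
    }
    sc <- abs(ch) / s
    blink_scores <- if (is.null(blink_scores)) sc else pmax(blink_scores, sc)
  }
  blink_idx <- if (is.null(blink_scores)) integer(0) else {
    threshold_peaks(blink_scores, blink_threshold, gap)
  }

  cardiac_idx <- integer(0)
  if (!is.null(ecg)) {
    s <- robust_sd(ecg)
    if (s == 0) {
      warning("flat ECG channel: no cardiac events detected")
    } else {
      sc <- ecg / s   # R peaks are one-signed local maxima
      cardiac_idx <- threshold_peaks(sc, cardiac_threshold, gap,
                                     local_max = TRUE)
    }
  }

  event_list(
    c((blink_idx - 1L) / rate, (cardiac_idx - 1L) / rate),
    c(rep("blink", length(blink_idx)), rep("cardiac", length(cardiac_idx)))
  )
}

robust_sd <- function(x) stats::mad(x, constant = 1.4826)

# indices of supra-threshold excursions, merged within `gap` samples onto the
# peak sample; optionally require a local maximum
threshold_peaks <- function(score, threshold, gap, local_max = FALSE) {
  above <- which(score > threshold)
  if (!length(above)) return(integer(0))
  # split into runs separated by more than `gap`
  breaks <- c(0L, which(diff(above) > gap), length(above))
  out <- integer(0)
  for (b in seq_len(length(breaks) - 1L)) {
    run <- above[(breaks[b] + 1L):breaks[b + 1L]]
    out <- c(out, run[which.max(score[run])])
  }
  if (local_max) {
    n <- length(score)
    keep <- vapply(out, function(i) {
      lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
      score[i] >= max(score[lo:hi])
    }, logical(1))
    out <- out[keep]
  }
  sort(out)
}
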