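#' Single-trial segment
#'
#' A fixed-length window of MEG channels, time-locked to a stimulus. Length is
#' `round(duration * rate)` samples.
#'
#' @param data numeric matrix, channels x samples.
#' @param onset window start in seconds from recording start.
#' @param rate sampling rate in Hz.
#' @param labels channel labels.
#' @param duration window length in seconds (default 0.3).
#' @return an object of class `trial_segment`.
#' @export
trial_segment <- function(data, onset, rate, labels = NULL, duration = 0.3) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  L <- round(duration * rate)
  if (ncol(data) != L) {
    stop(sprintf("trial window must have round(duration * rate) = %d samples", L))
  }
  if (is.null(labels)) labels <- sprintf("CH%03d", seq_len(nrow(data)))
  structure(
    list(data = data, onset = onset, duration = duration, rate = rate,
         labels = as.character(labels)),
    class = "trial_segment"
  )
}

#' Intercept single-trial windows at stimulus events
#'
#' Cuts one MEG-only window per stimulus event, starting `prestim` seconds
#' before the event (default 0: the window begins at the stimulus, covering
#' the P50/N100/P200 complex within 0.3 s). Events whose window would cross
#' the end of the recording are dropped with a warning.
#'
#' @param rec a [recording()].
#' @param events an [event_list()]; only `"stimulus"` events are used.
#' @param duration window length in seconds (default 0.3).
#' @param prestim pre-stimulus offset in seconds (default 0).
#' @return list of [trial_segment()] objects.
#' @export
segment_trials <- function(rec, events, duration = 0.3, prestim = 0) {
  stopifnot(inherits(rec, "meg_recording"), inherits(events, "event_list"))
  assert_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  stim <- events_of_kind(events, "stimulus")
  if (!nrow(stim)) return(list())
  idx <- meg_idx(rec)
  L <- round(duration * rec$rate)
  n <- ncol(rec$data)
  out <- list()
  dropped <- 0L
  for (t0 in stim$time) {
    s0 <- round((t0 - prestim) * rec$rate) + 1L
    if (s0 < 1L || s0 + L - 1L > n) {
      dropped <- dropped + 1L
      next
    }
    out[[length(out) + 1L]] <- trial_segment(
      rec$data[idx, s0:(s0 + L - 1L), drop = FALSE],
      onset = (s0 - 1L) / rec$rate, rate = rec$rate,
      labels = rec$channel_labels[idx], duration = duration
    )
  }
  if (dropped > 0L) {
    warning(sprintf("%d stimulus window(s) crossed the recording boundary and were dropped",
                    dropped))
  }
  out
}

#' Cut fixed-length non-overlapping segments from a recording
#'
#' Used to draw noise segments from an empty-room session: the recording is
#' partitioned into consecutive `duration`-long slots and `n` of them are
#' sampled without replacement (seeded), mirroring random non-overlapping
#' interception.
#'
#' @param rec a [recording()].
#' @param n number of segments (or `NULL` for all slots in order).
#' @param duration window length in seconds (default 0.3).
#' @param seed integer seed for the slot sampling.
#' @return list of [trial_segment()] objects.
#' @export
segment_fixed <- function(rec, n = NULL, duration = 0.3, seed = 0L) {
  stopifnot(inherits(rec, "meg_recording"))
  L <- round(duration * rec$rate)
  n_slots <- floor(ncol(rec$data) / L)
  if (is.null(n)) n <- n_slots
  if (n > n_slots) stop(sprintf("only %d non-overlapping slots available", n_slots))
  slots <- if (n == n_slots) seq_len(n_slots) else {
    sort(with_seed(seed, sample.int(n_slots, n)))
  }
  idx <- meg_idx(rec)
  lapply(slots, function(s) {
    s0 <- (s - 1L) * L + 1L
    trial_segment(rec$data[idx, s0:(s0 + L - 1L), drop = FALSE],
                  onset = (s0 - 1L) / rec$rate, rate = rec$rate,
                  labels = rec$channel_labels[idx], duration = duration)
  })
}

#' Screen out power-polluted trials
#'
#' A trial heavily contaminated by a transient (e.g. a sensor glitch) shows
#' extreme power on at least one channel. Per trial the statistic is the
#' maximum over channels of the channel mean-square; trials whose statistic
#' exceeds `median + k * MAD` (literal median absolute deviation) across
#' trials are rejected. If the MAD is zero (e.g. identical trials) nothing is
#' rejected.
#'
#' @param trials list of [trial_segment()] (at least 4).
#' @param k rejection multiplier (default 10).
#' @return list with integer vectors `kept` and `rejected` (ascending), and
#'   `statistic` (per-trial values).
#' @export
screen_trials <- function(trials, k = 10) {
  if (length(trials) < 4L) stop("screening needs at least 4 trials")
  assert_scalar(k, "k", lower = 0, strict_lower = TRUE)
  stat <- vapply(trials, function(tr) max(rowMeans(tr$data^2)), numeric(1))
  med <- stats::median(stat)
  dev <- stats::mad(stat, constant = 1)
  if (dev == 0) {
    rejected <- integer(0)
  } else {
    rejected <- which(stat > med + k * dev)
  }
  list(kept = setdiff(seq_along(trials), rejected),
       rejected = rejected, statistic = stat)
}
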