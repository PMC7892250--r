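#' Design a second-order IIR notch filter
#'
#' Constrained biquad with unit gain at DC and Nyquist, a null at `freq`, and
#' an exact -3 dB bandwidth of `bandwidth_3db` (single pass). Used to remove
#' narrowband alpha/beta rhythms before single-trial analysis.
#'
#' @param freq notch centre frequency in Hz (must be below Nyquist).
#' @param rate sampling rate in Hz.
#' @param bandwidth_3db -3 dB bandwidth in Hz (default 2).
#' @return list with numerator `b` and denominator `a` coefficient vectors.
#' @export
design_notch <- function(freq, rate, bandwidth_3db = 2) {
  assert_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  assert_scalar(freq, "freq", lower = 0, upper = rate / 2,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_scalar(bandwidth_3db, "bandwidth_3db", lower = 0, strict_lower = TRUE)
  w0 <- 2 * pi * freq / rate
  beta <- tan(pi * bandwidth_3db / rate)
  gain <- 1 / (1 + beta)
  list(
    b = gain * c(1, -2 * cos(w0), 1),
    a = c(1, -2 * gain * cos(w0), 2 * gain - 1)
  )
}

#' Complex frequency response of a rational filter
#'
#' @param b,a coefficient vectors (FIR: `a = 1`).
#' @param freqs frequencies in Hz at which to evaluate.
#' @param rate sampling rate in Hz.
#' @return complex vector of H(e^{i 2 pi f / rate}).
#' @export
filter_response <- function(b, a = 1, freqs, rate) {
  w <- 2 * pi * freqs / rate
  z <- exp(-1i * outer(w, seq_along(b) - 1L))
  num <- drop(z %*% b)
  zd <- exp(-1i * outer(w, seq_along(a) - 1L))
  den <- drop(zd %*% a)
  num / den
}

#' Measure the -3 dB bandwidth of a notch design
#'
#' Evaluates the single-pass magnitude response on a fine grid around `freq`
#' and returns the width between the two -3 dB crossings (linear
#' interpolation between grid points).
#'
#' @param notch list with `b`, `a` (from [design_notch()]).
#' @param freq notch centre frequency in Hz.
#' @param rate sampling rate in Hz.
#' @param span half-width of the search interval in Hz (default 5).
#' @return bandwidth in Hz.
#' @export
measure_notch_bandwidth <- function(notch, freq, rate, span = 5) {
  f <- seq(max(freq - span, 1e-3), min(freq + span, rate / 2 - 1e-3),
           length.out = 20001L)
  mag <- abs(filter_response(notch$b, notch$a, f, rate))
  thr <- 1 / sqrt(2)
  below <- mag < thr
  if (!any(below)) stop("no -3 dB region found around the notch frequency")
  runs <- range(which(below))
  cross <- function(i0, i1) {
    # linear interpolation of the crossing between grid points i0 and i1
    f[i0] + (thr - mag[i0]) * (f[i1] - f[i0]) / (mag[i1] - mag[i0])
  }
  lo <- if (runs[1] > 1L) cross(runs[1] - 1L, runs[1]) else f[1]
  hi <- if (runs[2] < length(f)) cross(runs[2] + 1L, runs[2]) else f[length(f)]
  abs(hi - lo)
}

#' Notch-filter the MEG channels of a recording
#'
#' Applies a cascade of second-order IIR notches (one per frequency), each with
#' the requested single-pass -3 dB bandwidth, forward-backward (zero phase) so
#' the evoked peak latencies are not shifted. Defaults remove the 10, 11, 20
#' and 21 Hz alpha/beta rhythms. Auxiliary channels are untouched.
#'
#' @param rec a [recording()].
#' @param freqs notch frequencies in Hz (default `c(10, 11, 20, 21)`).
#' @param bandwidth_3db single-pass -3 dB bandwidth in Hz (default 2).
#' @return the filtered [recording()].
#' @export
notch_filter <- function(rec, freqs = c(10, 11, 20, 21), bandwidth_3db = 2) {
  stopifnot(inherits(rec, "meg_recording"))
  if (any(freqs >= rec$rate / 2)) stop("notch frequency at or above Nyquist")
  designs <- lapply(freqs, design_notch, rate = rec$rate,
                    bandwidth_3db = bandwidth_3db)
  idx <- meg_idx(rec)
  meg <- rec$data[idx, , drop = FALSE]
  n <- ncol(meg)
  # reflection padding: the notch poles sit close to the unit circle, so the
  # forward-backward transient decays over ~rate/bandwidth samples
  pad <- min(n - 1L, ceiling(3 * rec$rate / bandwidth_3db))
  for (d in designs) {
    flt <- signal::Arma(b = d$b, a = d$a)
    for (i in seq_len(nrow(meg))) {
      x <- meg[i, ]
      xp <- c(2 * x[1L] - x[seq(pad + 1L, 2L)], x,
              2 * x[n] - x[seq(n - 1L, n - pad)])
      meg[i, ] <- signal::filtfilt(flt, xp)[pad + seq_len(n)]
    }
  }
  assert_finite(meg, "filtered data")
  set_meg_data(rec, meg)
}

#' Design the even-order linear-phase FIR low-pass filter
#'
#' Type-I (even order, odd tap count, symmetric) Kaiser-window design. The
#' Kaiser beta and order are chosen for `stopband_atten` plus a 5 dB design
#' margin so the measured minimum stopband attenuation meets the nominal
#' figure with slack.
#'
#' @param rate sampling rate in Hz.
#' @param cutoff passband edge in Hz (default 40).
#' @param stopband_atten nominal stopband attenuation in dB (default 60).
#' @param stopband_edge stopband edge in Hz (default 55); attenuation is
#'   measured from here to Nyquist.
#' @param max_order largest acceptable filter order (default 2000).
#' @return numeric vector of taps (length order + 1) with attributes
#'   `"order"`, `"cutoff"`, `"stopband_edge"`, `"rate"`.
#' @export
design_lowpass_fir <- function(rate, cutoff = 40, stopband_atten = 60,
                               stopband_edge = 55, max_order = 2000) {
  assert_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  assert_scalar(cutoff, "cutoff", lower = 0, upper = rate / 2,
                strict_lower = TRUE, strict_upper = TRUE)
  if (stopband_edge <= cutoff || stopband_edge >= rate / 2) {
    stop("`stopband_edge` must lie between `cutoff` and Nyquist")
  }
  a_design <- stopband_atten + 5
  dw <- 2 * pi * (stopband_edge - cutoff) / rate
  n <- ceiling((a_design - 7.95) / (2.285 * dw))
  if (n %% 2L == 1L) n <- n + 1L      # type-I linear phase: even order
  if (n > max_order) {
    achieved <- 2.285 * dw * max_order + 7.95 - 5
    stop(sprintf(
      "FIR spec unattainable at max order %d: achievable attenuation ~%.1f dB",
      max_order, achieved
    ))
  }
  beta <- if (a_design > 50) {
    0.1102 * (a_design - 8.7)
  } else if (a_design >= 21) {
    0.5842 * (a_design - 21)^0.4 + 0.07886 * (a_design - 21)
  } else {
    0
  }
  fc <- (cutoff + stopband_edge) / 2   # band centre, half-amplitude point
  h <- signal::fir1(n, fc / (rate / 2), type = "low",
                    window = signal::kaiser(n + 1L, beta))
  h <- as.numeric(h)
  attr(h, "order") <- n
  attr(h, "cutoff") <- cutoff
  attr(h, "stopband_edge") <- stopband_edge
  attr(h, "rate") <- rate
  h
}

#' Measure the minimum stopband attenuation of an FIR design
#'
#' Evaluates the magnitude response on a dense grid from the stopband edge to
#' Nyquist and returns the minimum attenuation in dB relative to the passband
#' (DC) gain.
#'
#' @param h FIR taps (from [design_lowpass_fir()]).
#' @param rate sampling rate in Hz (default taken from the design attribute).
#' @param stopband_edge stopband edge in Hz (default from the design
#'   attribute).
#' @return minimum stopband attenuation in dB (positive number).
#' @export
measure_fir_stopband <- function(h, rate = attr(h, "rate"),
                                 stopband_edge = attr(h, "stopband_edge")) {
  f <- seq(stopband_edge, rate / 2, length.out = 8192L)
  mag <- abs(filter_response(h, 1, f, rate))
  dc <- abs(filter_response(h, 1, 0, rate))
  -20 * log10(max(mag) / dc)
}

# zero-phase application of a symmetric odd-length FIR: group delay (order/2
# samples) is compensated by trimming; edges are reflection-padded
apply_fir_zerophase <- function(h, x) {
  n_ord <- length(h) - 1L
  half <- n_ord %/% 2L
  n <- length(x)
  if (half >= n) stop("signal shorter than half the FIR length")
  pad_l <- if (half > 0L) 2 * x[1L] - x[seq(half + 1L, 2L)] else numeric(0)
  pad_r <- if (half > 0L) 2 * x[n] - x[seq(n - 1L, n - half)] else numeric(0)
  xp <- c(pad_l, x, pad_r, rep(0, n_ord))
  y <- signal::fftfilt(h, xp)
  y[(half + length(pad_l) + 1L):(half + length(pad_l) + n)]
}

#' Low-pass the MEG channels with the linear-phase FIR filter
#'
#' Applies the Kaiser-window low-pass of [design_lowpass_fir()] with group
#' delay compensated, so the output is time-aligned with the input and the
#' P50/N100/P200 latencies are preserved. Verifies at design time that every
#' requested line frequency falls inside the stopband at the nominal
#' attenuation, so no separate line filter is needed. Auxiliary channels are
#' untouched.
#'
#' @param rec a [recording()].
#' @param cutoff passband edge in Hz (default 40).
#' @param stopband_atten nominal stopband attenuation in dB (default 60).
#' @param line_freqs line frequencies that must fall in the stopband
#'   (default `c(60, 120, 180)`).
#' @param stopband_edge stopband edge in Hz (default 55).
#' @return the filtered [recording()].
#' @export
lowpass_fir <- function(rec, cutoff = 40, stopband_atten = 60,
                        line_freqs = c(60, 120, 180), stopband_edge = 55) {
  stopifnot(inherits(rec, "meg_recording"))
  line_freqs <- line_freqs[line_freqs < rec$rate / 2]
  h <- design_lowpass_fir(rec$rate, cutoff = cutoff,
                          stopband_atten = stopband_atten,
                          stopband_edge = stopband_edge)
  if (length(line_freqs)) {
    if (any(line_freqs < stopband_edge)) {
      stop("a line frequency lies below the stopband edge")
    }
    att <- -20 * log10(abs(filter_response(h, 1, line_freqs, rec$rate)))
    if (any(att < stopband_atten)) {
      stop(sprintf("line-frequency attenuation %.1f dB below the nominal %g dB",
                   min(att), stopband_atten))
    }
  }
  idx <- meg_idx(rec)
  meg <- rec$data[idx, , drop = FALSE]
  for (i in seq_len(nrow(meg))) {
    meg[i, ] <- apply_fir_zerophase(h, meg[i, ])
  }
  assert_finite(meg, "filtered data")
  set_meg_data(rec, meg)
}
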