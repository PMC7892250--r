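rate <- 600

test_that("stimulus detection finds tone-burst onsets from the audio channel", {
  expect_identical(nrow(detect_stimulus_events(numeric(6000), rate)), 0L)

  # five bursts one second apart: onsets recovered within one sample
  audio <- numeric(6 * rate)
  onsets <- (1:5) * rate
  burst <- cos(2 * pi * 75 * (0:29) / rate)
  for (s in onsets) audio[s + 1:30] <- burst
  ev <- detect_stimulus_events(audio, rate, threshold_frac = 0.5)
  expect_identical(nrow(ev), 5L)
  expect_true(all(abs(ev$time - onsets / rate) <= 1 / rate))

  # refractory suppression merges close bursts
  audio2 <- numeric(2 * rate)
  audio2[rate + 1:30] <- burst
  audio2[rate + 60 + 1:30] <- burst    # 0.1 s later
  ev2 <- detect_stimulus_events(audio2, rate, refractory = 0.5)
  expect_identical(nrow(ev2), 1L)

  expect_error(detect_stimulus_events(c(1, NaN, 0), rate), "NA")
})

test_that("artifact detection is quiet on plain noise and recovers injected blinks", {
  set.seed(7)
  n <- 1e4
  quiet <- detect_artifact_events(eog_v = rnorm(n), eog_h = rnorm(n),
                                  rate = rate, blink_threshold = 8)
  expect_identical(nrow(quiet), 0L)

  # blinks injected at known times: full recall at threshold 4
  tgrid <- (0:(n - 1)) / rate
  truth <- c(3, 7, 11)
  eog <- rnorm(n, sd = 1)
  for (b in truth) eog <- eog + 60 * exp(-(tgrid - b)^2 / (2 * 0.05^2))
  ev <- detect_artifact_events(eog_v = eog, rate = rate, blink_threshold = 4)
  ev <- ev[ev$kind == "blink", ]
  expect_true(all(vapply(truth, function(b) any(abs(ev$time - b) < 0.1),
                         logical(1))))

  none <- suppressWarnings(
    detect_artifact_events(ecg = numeric(n), rate = rate)
  )
  expect_identical(sum(none$kind == "cardiac"), 0L)
  expect_warning(detect_artifact_events(ecg = numeric(n), rate = rate),
                 "flat")
})

test_that("SSP estimates a rank-1 artifact pattern and annihilates it", {
  set.seed(21)
  n_ch <- 30
  n <- 6000
  pattern <- rnorm(n_ch)
  pattern <- pattern / sqrt(sum(pattern^2))
  tgrid <- (0:(n - 1)) / rate
  times <- c(2, 5, 8)
  wave <- numeric(n)
  for (b in times) wave <- wave + exp(-(tgrid - b)^2 / (2 * 0.04^2))
  artifact <- 50 * pattern %o% wave
  rec <- toy_recording(artifact + matrix(rnorm(n_ch * n, sd = 0.01), n_ch, n),
                       rate = rate)
  ev <- event_list(times, "blink")
  u <- compute_ssp_projectors(rec, ev, n_components = 1)
  expect_gt(abs(sum(u[, 1] * pattern)), 0.999)

  # full-rank basis spans the channel space
  uf <- compute_ssp_projectors(rec, ev, n_components = n_ch)
  expect_equal(crossprod(uf), diag(n_ch), tolerance = 1e-9)

  # exact annihilation of the pure rank-1 artifact
  pure <- toy_recording(artifact, rate = rate)
  u_pure <- compute_ssp_projectors(pure, ev, n_components = 1)
  clean <- apply_ssp(pure, u_pure)
  expect_lt(sum(clean$data[1:n_ch, ]^2), 1e-10 * sum(artifact^2))

  # idempotence on the noisy recording, and the zero-projector identity
  once <- apply_ssp(rec, u)
  twice <- apply_ssp(once, u)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
  same <- apply_ssp(rec, NULL)
  expect_identical(same$data, rec$data)
  expect_error(apply_ssp(rec, matrix(0, n_ch + 1, 1)), "dimension")
})

test_that("white-noise-only epochs have no dominant SSP component", {
  set.seed(3)
  n_ch <- 40
  rec <- toy_recording(matrix(rnorm(n_ch * 12000), n_ch, 12000), rate = rate)
  u <- compute_ssp_projectors(rec, event_list(c(4, 8, 12), "blink"),
                              n_components = 1)
  expl <- attr(u, "explained")
  # eigenvalue spread of a pure-noise covariance stays near uniform
  expect_lt(expl[1], 5 / n_ch)
})

test_that("notch filter has unit DC gain and suppresses its target frequencies", {
  t <- (0:(4 * rate - 1)) / rate
  dc <- toy_recording(matrix(1, 2, length(t)), rate = rate)
  out <- notch_filter(dc)
  mid0 <- seq(rate, 3 * rate)   # away from the filter's edge transients
  expect_equal(out$data[1:2, mid0], dc$data[1:2, mid0], tolerance = 1e-6)

  for (f0 in c(10, 11, 20, 21)) {
    rec <- toy_recording(matrix(sin(2 * pi * f0 * t), 1, length(t)),
                         rate = rate)
    out <- notch_filter(rec, freqs = f0)
    mid <- seq(rate, 3 * rate)   # steady state
    atten <- 20 * log10(max(abs(out$data[1, mid])) /
                        max(abs(rec$data[1, mid])))
    expect_lt(atten, -20)
  }
  expect_error(notch_filter(dc, freqs = 300), "Nyquist")
})

test_that("designed notch bandwidth is 2 Hz at each default frequency", {
  for (f0 in c(10, 11, 20, 21)) {
    d <- design_notch(f0, rate, bandwidth_3db = 2)
    expect_equal(measure_notch_bandwidth(d, f0, rate), 2, tolerance = 0.01)
    expect_lt(abs(filter_response(d$b, d$a, f0, rate)), 1e-10)
  }
})

test_that("FIR low-pass meets its stopband and passband specification", {
  h <- design_lowpass_fir(rate)
  expect_equal(attr(h, "order") %% 2, 0)                  # even order
  expect_equal(as.numeric(h), rev(as.numeric(h)),
               tolerance = 1e-12)                         # linear phase
  expect_gte(measure_fir_stopband(h), 60)
  att_line <- -20 * log10(abs(filter_response(h, 1, c(60, 120, 180), rate)))
  expect_true(all(att_line >= 60))
  gain5 <- 20 * log10(abs(filter_response(h, 1, 5, rate)))
  expect_lt(abs(gain5), 0.1)
  expect_error(design_lowpass_fir(rate, stopband_atten = 200, max_order = 50),
               "unattainable")
})

test_that("FIR filtering is time-aligned and attenuates line frequency in-signal", {
  t <- (0:(4 * rate - 1)) / rate
  bump <- exp(-(t - 2)^2 / (2 * 0.02^2))
  rec <- toy_recording(rbind(bump, sin(2 * pi * 60 * t)), rate = rate)
  out <- lowpass_fir(rec)
  expect_equal(which.max(out$data[1, ]), which.max(bump))  # delay compensated
  mid <- seq(rate, 3 * rate)
  expect_lt(max(abs(out$data[2, mid])), 10^(-60 / 20) * 1.5)
})

test_that("the filter chain is linear and preserves zeros and aux channels", {
  set.seed(5)
  n <- 3000
  a <- matrix(rnorm(3 * n), 3, n)
  b <- matrix(rnorm(3 * n), 3, n)
  chain <- function(m) {
    r <- lowpass_fir(notch_filter(toy_recording(m, rate = rate)))
    r$data[1:3, ]
  }
  expect_equal(chain(a + b), chain(a) + chain(b), tolerance = 1e-9)
  expect_identical(chain(matrix(0, 3, n)), matrix(0, 3, n))

  rec <- toy_recording(a, rate = rate)
  rec$data[4, ] <- sin(2 * pi * 60 * (1:n) / rate)   # audio channel
  out <- lowpass_fir(notch_filter(rec))
  expect_identical(out$data[4, ], rec$data[4, ])
})

test_that("trial interception yields fixed windows and drops boundary events", {
  set.seed(8)
  rec <- toy_recording(matrix(rnorm(2 * 3 * rate), 2, 3 * rate), rate = rate)
  ev <- event_list(c(0.5, 1.5), "stimulus")
  trials <- segment_trials(rec, ev, duration = 0.3)
  expect_length(trials, 2L)
  expect_true(all(vapply(trials, function(tr) ncol(tr$data), integer(1)) ==
                    180L))
  expect_identical(segment_trials(rec, event_list(), 0.3), list())

  late <- event_list(2.9, "stimulus")    # 0.1 s before the end
  expect_warning(out <- segment_trials(rec, late, duration = 0.3), "dropped")
  expect_length(out, 0L)
})

test_that("power screening rejects exactly the spiked trial", {
  set.seed(12)
  trials <- lapply(1:20, function(i) {
    toy_trial(matrix(rnorm(30 * 180), 30, 180))
  })
  expect_identical(screen_trials(trials)$rejected, integer(0))

  trials[[7]]$data[13, ] <- trials[[7]]$data[13, ] * 100
  scr <- screen_trials(trials, k = 10)
  expect_identical(scr$rejected, 7L)
  expect_identical(scr$kept, setdiff(1:20, 7L))

  same <- lapply(1:20, function(i) toy_trial(matrix(1, 4, 180)))
  expect_identical(screen_trials(same)$rejected, integer(0))
  expect_error(screen_trials(trials[1:3]), "at least 4")
})
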