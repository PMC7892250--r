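test_that("scenario defaults encode the study's recording parameters", {
  sc <- synth_scenario()
  expect_identical(sc$n_sensors, 274)
  expect_identical(sc$rate, 600)
  expect_identical(sc$session_length, 360)
  expect_identical(round(sc$session_length * sc$rate), 216000)
  expect_identical(sc$n_stimuli, 200)
  expect_identical(sc$noise_length, 120)
  expect_identical(round(sc$noise_length * sc$rate), 72000)
  expect_identical(sc$audio_delay, 0.13)
  lats <- vapply(sc$peak_params, `[[`, numeric(1), "latency")
  expect_equal(unname(lats), c(0.068, 0.108, 0.193))
  expect_error(synth_scenario(trial_duration = 0.1), "latencies")
  expect_error(synth_scenario(snr = 0), "snr")
})

test_that("the sensor lattice is deterministic and cap-shaped", {
  one <- make_sensor_array(1)
  expect_equal(one$positions[1, ], c(0, 0, 0.11), ignore_attr = TRUE)

  a <- make_sensor_array(274)
  b <- make_sensor_array(274)
  expect_identical(a$positions, b$positions)
  expect_identical(length(a$labels), 274L)
  expect_setequal(unique(a$region_tags),
                  c("vertex", "frontal", "occipital",
                    "temporal-left", "temporal-right"))
  # minimum pairwise spacing from an exhaustive scan, stable across calls
  d <- as.matrix(dist(a$positions))
  diag(d) <- Inf
  expect_identical(min(d), min(as.matrix(dist(b$positions)) + diag(Inf, 274)))
  expect_gt(min(d), 0.005)
})

test_that("the dipole field matches an independent arithmetic evaluation", {
  # hand-specified case, evaluated step by step
  q <- c(0, 1e-8, 0)
  rq <- c(0.05, 0, 0.05)
  s <- c(0.07, 0.03, 0.08)
  d <- s - rq
  cross <- c(q[2] * d[3] - q[3] * d[2],
             q[3] * d[1] - q[1] * d[3],
             q[1] * d[2] - q[2] * d[1])
  oracle <- 1e-7 * sum(cross * s / sqrt(sum(s^2))) / sqrt(sum(d^2))^3
  got <- dipole_radial_field(rq, q, matrix(s, 1, 3))
  expect_equal(got, oracle, tolerance = 1e-12)

  # a radial dipole is magnetically silent
  arr <- make_sensor_array(100)
  silent <- dipole_radial_field(c(0, 0, 0.05), c(0, 0, 1e-8) * 0.9,
                                arr$positions)
  expect_true(all(abs(silent) < 1e-20))

  # a tangential dipole produces a bipolar field of comparable extremes
  pat <- dipole_radial_field(c(0, -0.06, 0.04), c(2e-8, 0, 0),
                             arr$positions)
  expect_lt(max(pat) * min(pat), 0)
  ratio <- max(pat) / abs(min(pat))
  expect_gt(ratio, 1 / 3)
  expect_lt(ratio, 3)

  expect_error(dipole_radial_field(c(0, 0, 0.2), q, arr$positions),
               "inside")
})

test_that("the evoked waveform matches a direct three-Gaussian evaluation", {
  sc <- synth_scenario()
  pp <- sc$peak_params
  direct <- function(t) {
    raw <- function(tt) {
      pp$p50[["amplitude"]] * exp(-(tt - pp$p50[["latency"]])^2 /
                                    (2 * pp$p50[["width"]]^2)) +
      pp$n100[["amplitude"]] * exp(-(tt - pp$n100[["latency"]])^2 /
                                     (2 * pp$n100[["width"]]^2)) +
      pp$p200[["amplitude"]] * exp(-(tt - pp$p200[["latency"]])^2 /
                                     (2 * pp$p200[["width"]]^2))
    }
    raw(t) * abs(pp$n100[["amplitude"]]) / abs(raw(pp$n100[["latency"]]))
  }
  t <- seq(0, 0.3, by = 1 / 600)
  expect_equal(aef_waveform(t, pp), direct(t), tolerance = 1e-12)
  # N100 extremum magnitude equals the configured amplitude at the latency
  expect_equal(abs(aef_waveform(0.108, pp)), 1.5, tolerance = 1e-9)
  # tails vanish far beyond the peaks
  expect_lt(abs(aef_waveform(0.5, pp)), 1e-6 * 1.5)
  expect_error(aef_waveform(-0.1, pp), "nonnegative")
})

test_that("sessions are fully deterministic in the seed", {
  sc <- tiny_scenario(n_sensors = 30, session_length = 8, n_stimuli = 3,
                      noise_length = 4)
  a <- simulate_session(sc)
  b <- simulate_session(sc)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$events, b$events)
  na <- simulate_noise_session(sc)
  nb <- simulate_noise_session(sc)
  expect_identical(na$recording$data, nb$recording$data)

  sc2 <- tiny_scenario(n_sensors = 30, session_length = 8, n_stimuli = 3,
                       noise_length = 4, seed = 43)
  c <- simulate_session(sc2)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("a session with no sources and zero noise is silent", {
  sc <- tiny_scenario(n_sensors = 20, session_length = 8, n_stimuli = 3,
                      sources = list(),
                      noise = list(white = 0, pink = 0, line = 0, alpha = 0,
                                   blink = 0, cardiac = 0))
  sess <- simulate_session(sc)
  meg <- sess$recording$data[sess$recording$roles == "meg", ]
  expect_true(all(meg == 0))
  # while the audio channel still carries the stimuli
  expect_gt(max(abs(sess$recording$data[sess$recording$roles == "audio", ])), 0)
})

test_that("session structure matches the scenario counts", {
  sc <- tiny_scenario(n_sensors = 40, session_length = 20, n_stimuli = 8,
                      noise_length = 5)
  sess <- simulate_session(sc)
  expect_identical(ncol(sess$recording$data), 20L * 600L)
  expect_identical(sum(sess$events$kind == "stimulus"), 8L)
  expect_identical(sess$trial_labels, rep("aef", 8))
  nz <- simulate_noise_session(sc)
  expect_identical(ncol(nz$recording$data), 5L * 600L)
})

test_that("detected stimulus onsets agree with the ground truth within a sample", {
  sc <- tiny_scenario(n_sensors = 30, session_length = 20, n_stimuli = 8)
  sess <- simulate_session(sc)
  audio <- sess$recording$data[sess$recording$roles == "audio", ]
  det <- detect_stimulus_events(audio, 600)
  truth <- sess$events$time[sess$events$kind == "stimulus"]
  expect_identical(nrow(det), length(truth))
  expect_true(all(abs(det$time - truth) <= 1 / 600))
})

test_that("realized SNR tracks the scenario's target", {
  ratios <- vapply(1:4, function(seed) {
    sc <- tiny_scenario(n_sensors = 60, session_length = 30, n_stimuli = 12,
                        seed = seed)
    src <- simulate_session(sc, include_noise = FALSE)
    nz <- simulate_session(sc, include_sources = FALSE)
    tem <- grepl("^temporal", src$array$region_tags)
    stim <- src$events$time[src$events$kind == "stimulus"]
    win <- unlist(lapply(round(stim * 600) + 1, function(s) s:(s + 179)))
    meg <- which(src$recording$roles == "meg")
    mean(src$recording$data[meg[tem], win]^2) /
      mean(nz$recording$data[meg[tem], win]^2)
  }, numeric(1))
  expect_true(all(abs(ratios / 2 - 1) < 0.2))   # target snr = 2, within 20%
})

test_that("white-noise-only sessions show weak neighbour correlations", {
  sc <- tiny_scenario(
    n_sensors = 60, session_length = 10, n_stimuli = 3, noise_length = 6,
    sources = list(),
    noise = list(white = 1, pink = 0, line = 0, alpha = 0,
                 blink = 0, cardiac = 0)
  )
  nz <- simulate_noise_session(sc)
  g <- build_neighbourhoods(nz$array, 0.022 * 1.7)
  meg <- nz$recording$data[nz$recording$roles == "meg", 1:180]
  cs <- c()
  for (i in seq_along(g$neighbors)) {
    for (j in g$neighbors[[i]]) {
      if (j > i) cs <- c(cs, abs(pearson_correlation(meg[i, ], meg[j, ])))
    }
  }
  expect_lt(mean(cs), 0.1)
})

test_that("enhancement concentrates trial energy over the temporal sources", {
  sc <- tiny_scenario(n_sensors = 80, session_length = 40, n_stimuli = 16,
                      seed = 2)
  sess <- simulate_session(sc)
  rec <- lowpass_fir(notch_filter(sess$recording))
  trials <- segment_trials(rec, sess$events)
  g <- build_neighbourhoods(sess$array, 0.022 * 1.7)
  tem <- grepl("^temporal", sess$array$region_tags)
  frac <- function(e) sum(e[tem]) / sum(e)
  gains <- vapply(trials, function(tr) {
    enh <- suppressWarnings(enhance_trial(tr, g))
    frac(trial_energy(enh)) - frac(trial_energy(tr))
  }, numeric(1))
  # paired over trials: enhancement raises the temporal energy share
  expect_gt(mean(gains > 0), 0.8)
  expect_gt(mean(gains), 0)
})
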