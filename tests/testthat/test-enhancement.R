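# independent oracle: correlation from two-pass population moments, written
# out term by term
moment_corr <- function(x, y) {
  n <- length(x)
  exy <- sum(x * y) / n
  ex <- sum(x) / n
  ey <- sum(y) / n
  vx <- sum((x - ex)^2) / n
  vy <- sum((y - ey)^2) / n
  (exy - ex * ey) / sqrt(vx * vy)
}

test_that("pearson correlation matches brute-force moment arithmetic", {
  x <- c(1, 2, 3)
  y <- c(1, 2, 4)
  expect_equal(pearson_correlation(x, y), moment_corr(x, y),
               tolerance = 1e-12)

  set.seed(100)
  for (i in 1:200) {
    n <- sample(3:50, 1)
    a <- rnorm(n)
    b <- rnorm(n) + runif(1, -1, 1) * a
    expect_equal(pearson_correlation(a, b), moment_corr(a, b),
                 tolerance = 1e-12)
  }
})

test_that("pearson correlation honours its contract at the extremes", {
  x <- c(0.3, -1, 2, 5)
  expect_equal(pearson_correlation(x, x), 1, tolerance = 1e-14)
  expect_equal(pearson_correlation(x, -x), -1, tolerance = 1e-14)
  expect_error(pearson_correlation(x, rep(1, 4)), "variance")
  expect_error(pearson_correlation(x, c(1, 2)), "length")
  expect_true(abs(pearson_correlation(rnorm(10), rnorm(10))) <= 1)
})

test_that("enhancement leaves uncorrelated channels untouched (n = 0 branch)", {
  set.seed(31)
  arr <- random_array(12, seed = 31)
  g <- build_neighbourhoods(arr, 0.2)   # everyone neighbours everyone
  tr <- toy_trial(matrix(rnorm(12 * 180), 12, 180))
  tr$labels <- arr$labels
  enh <- enhance_trial(tr, g, threshold = 0.8)
  expect_identical(enh$data, tr$data)    # bit-exact identity
  expect_true(all(enh$n_qualified == 0L))
})

test_that("three identical neighbouring channels triple under the adopted rule", {
  x <- sin(2 * pi * 5 * (0:179) / 600)
  tr <- toy_trial(rbind(x, x, x))
  arr <- sensor_array(c("a", "b", "c"),
                      0.11 * rbind(c(0, 0, 1), c(0.1, 0, 0.995),
                                   c(-0.1, 0, 0.995)),
                      head_radius = 0.11)
  tr$labels <- arr$labels
  g <- build_neighbourhoods(arr, 0.1)
  enh <- enhance_trial(tr, g, threshold = 0.8)
  expect_true(all(enh$n_qualified == 2L))
  for (i in 1:3) expect_equal(enh$data[i, ], 3 * x, tolerance = 1e-12)

  # n = 1: output is the channel plus its single weighted neighbour
  tr2 <- toy_trial(rbind(x, x))
  arr2 <- sensor_array(c("a", "b"), 0.11 * rbind(c(0, 0, 1), c(0.1, 0, 0.995)),
                       head_radius = 0.11)
  tr2$labels <- arr2$labels
  enh2 <- enhance_trial(tr2, build_neighbourhoods(arr2, 0.1))
  expect_equal(enh2$data[1, ], 2 * x, tolerance = 1e-12)

  # alternative denominator conventions remain selectable
  enh3 <- enhance_trial(tr, g, rule = "nplus1")
  expect_equal(enh3$data[1, ], (x + 2 * x) / 3, tolerance = 1e-12)
  enh4 <- enhance_trial(tr, g, rule = "n")
  expect_equal(enh4$data[1, ], x + x, tolerance = 1e-12)
})

test_that("anticorrelated neighbours contribute constructively via signed weights", {
  x <- sin(2 * pi * 5 * (0:179) / 600)
  tr <- toy_trial(rbind(x, -x))
  arr <- sensor_array(c("a", "b"), 0.11 * rbind(c(0, 0, 1), c(0.1, 0, 0.995)),
                      head_radius = 0.11)
  tr$labels <- arr$labels
  enh <- enhance_trial(tr, build_neighbourhoods(arr, 0.1), threshold = 0.8)
  # c = -1, so channel a gains (-1) * (-x) = +x
  expect_equal(enh$data[1, ], 2 * x, tolerance = 1e-12)
  expect_equal(enh$weights_used[[1]][, "correlation"], -1,
               ignore_attr = TRUE)
})

test_that("enhancement is equivariant to global channel scaling", {
  set.seed(55)
  sc <- tiny_scenario(n_sensors = 40, session_length = 12, n_stimuli = 4)
  sess <- simulate_session(sc)
  ev <- sess$events[sess$events$kind == "stimulus", ]
  trials <- segment_trials(sess$recording, sess$events)
  g <- build_neighbourhoods(sess$array, 0.022 * 1.7)
  tr <- trials[[1]]
  enh <- enhance_trial(tr, g)
  tr_scaled <- tr
  tr_scaled$data <- 3.7 * tr$data
  enh_scaled <- enhance_trial(tr_scaled, g)
  expect_equal(enh_scaled$data, 3.7 * enh$data, tolerance = 1e-9)
  expect_identical(enh_scaled$n_qualified, enh$n_qualified)
})

test_that("recorded weights respect the qualification threshold", {
  sc <- tiny_scenario(n_sensors = 60, session_length = 15, n_stimuli = 5)
  sess <- simulate_session(sc)
  trials <- segment_trials(sess$recording, sess$events)
  g <- build_neighbourhoods(sess$array, 0.022 * 1.7)
  enh <- enhance_trial(trials[[2]], g, threshold = 0.8)
  for (i in seq_along(enh$weights_used)) {
    w <- enh$weights_used[[i]]
    expect_identical(nrow(w), enh$n_qualified[i])
    if (nrow(w)) {
      expect_true(all(abs(w[, "correlation"]) >= 0.8))
      expect_true(all(w[, "neighbor"] %in% g$neighbors[[i]]))
    }
    if (enh$n_qualified[i] == 0L) {
      expect_identical(enh$data[i, ], trials[[2]]$data[i, ])
    }
  }
})

test_that("zero-variance channels are left alone with a warning", {
  set.seed(77)
  dat <- matrix(rnorm(3 * 180), 3, 180)
  dat[2, ] <- 0
  tr <- toy_trial(dat)
  arr <- sensor_array(c("a", "b", "c"),
                      0.11 * rbind(c(0, 0, 1), c(0.1, 0, 0.995),
                                   c(-0.1, 0, 0.995)),
                      head_radius = 0.11)
  tr$labels <- arr$labels
  expect_warning(enh <- enhance_trial(tr, build_neighbourhoods(arr, 0.1)),
                 "zero-variance")
  expect_identical(enh$data[2, ], dat[2, ])
})

test_that("trial energy follows the sum-of-squares definition", {
  tr <- toy_trial(rbind(c(1, 1), c(2, 2)), rate = 600)
  tr$duration <- 2 / 600
  raw <- trial_energy(tr, normalize = FALSE)
  expect_equal(as.numeric(raw), c(2, 8))
  norm <- trial_energy(tr, normalize = TRUE)
  expect_equal(as.numeric(norm), c(0.25, 1))
  expect_identical(max(norm), 1)

  # homogeneity: scaling by alpha scales raw energies by alpha^2
  tr2 <- tr
  tr2$data <- 3 * tr$data
  expect_equal(as.numeric(trial_energy(tr2, FALSE)), 9 * c(2, 8))
  expect_equal(as.numeric(trial_energy(tr2, TRUE)), c(0.25, 1))

  zero <- toy_trial(matrix(0, 2, 180))
  expect_error(trial_energy(zero, normalize = TRUE), "all-zero")
})

test_that("enhancement converges to a no-op on white noise as the threshold rises", {
  set.seed(91)
  arr <- random_array(40, seed = 91)
  g <- build_neighbourhoods(arr, default_radius(arr))
  tr <- toy_trial(matrix(rnorm(40 * 180), 40, 180))
  tr$labels <- arr$labels
  deltas <- vapply(c(0.5, 0.75, 0.95), function(th) {
    mean(abs(enhance_trial(tr, g, threshold = th)$data - tr$data))
  }, numeric(1))
  expect_true(all(diff(deltas) <= 0))
  expect_equal(deltas[3], 0)
})
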