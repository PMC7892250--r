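# small, fast scenario for unit tests; full-scale runs live in the
# acceptance tests
tiny_scenario <- function(..., n_sensors = 80, session_length = 25,
                          n_stimuli = 10, noise_length = 6, seed = 42) {
  synth_scenario(n_sensors = n_sensors, session_length = session_length,
                 n_stimuli = n_stimuli, noise_length = noise_length,
                 seed = seed, ...)
}

# random cap-like array with distinct positions
random_array <- function(n, seed = 1, head_radius = 0.11) {
  pos <- with(list(s = seed), {
    set.seed(s)
    z <- runif(n, 0.2, 1)
    phi <- runif(n, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    head_radius * cbind(r * cos(phi), r * sin(phi), z)
  })
  sensor_array(sprintf("S%03d", seq_len(n)), pos, head_radius = head_radius)
}

# brute-force neighbourhood oracle: naive double loop
brute_neighbours <- function(array, radius) {
  pos <- array$positions
  n <- nrow(pos)
  lapply(seq_len(n), function(i) {
    out <- integer(0)
    for (j in seq_len(n)) {
      if (j != i && sqrt(sum((pos[i, ] - pos[j, ])^2)) <= radius) {
        out <- c(out, j)
      }
    }
    out
  })
}

# simple multichannel recording around a given MEG matrix
toy_recording <- function(meg, rate = 600, array = NULL) {
  n <- ncol(meg)
  labels <- if (!is.null(array)) array$labels else
    sprintf("M%03d", seq_len(nrow(meg)))
  recording(
    rbind(meg, matrix(0, 2, n)),
    rate = rate,
    channel_labels = c(labels, "AUDIO", "ECG"),
    roles = c(rep("meg", nrow(meg)), "audio", "ecg"),
    array = array
  )
}

# trial filled with the given channels x L matrix
toy_trial <- function(data, rate = 600) {
  trial_segment(data, onset = 0, rate = rate,
                duration = ncol(data) / rate)
}

# normalized energy vector helper
as_energy <- function(e, labels = NULL) {
  e <- e / max(e)
  names(e) <- labels %||% sprintf("S%03d", seq_along(e))
  structure(e, normalized = TRUE, class = "energy_vector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
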