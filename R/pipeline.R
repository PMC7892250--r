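#' Default pipeline configuration
#'
#' One nested configuration object drives the whole pipeline, with the
#' standard defaults at every stage: the synthetic scenario (600 Hz, 360 s,
#' 200 stimuli, right-dominant bilateral sources), the preprocessing chain
#' (SSP, 10/11/20/21 Hz notches of 2 Hz bandwidth, 40 Hz FIR low-pass at
#' 60 dB covering the 60/120/180 Hz line frequencies, 0.3 s interception,
#' power screening at k = 10), the enhancement (radius 0.022 x 1.7 m,
#' correlation threshold 0.8), 224 x 224 imaging, and the classifier settings
#' (dropout 0.6, learning rate 1e-4, 10 epochs, 80/20 split).
#'
#' @param ... named overrides of top-level sections, each a named list merged
#'   into the defaults; unknown keys are rejected.
#' @param seed master seed stamped into every stage (default 0).
#' @return an object of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(enhancement = list(threshold = 0.9), seed = 1)
#' cfg$enhancement$threshold
#' @export
pipeline_config <- function(..., seed = 0L) {
  defaults <- list(
    scenario = list(
      n_sensors = 274, head_radius = 0.11, cap_angle = 105, rate = 600,
      session_length = 360, n_stimuli = 200, n_stimuli_second = 199,
      trial_duration = 0.3, snr = 2, noise_length = 120, audio_delay = 0.13
    ),
    preprocessing = list(
      stim_threshold_frac = 0.5, stim_refractory = 0.5,
      blink_threshold = 4, cardiac_threshold = 4, artifact_refractory = 0.25,
      ssp_window = 0.2, ssp_components = 1,
      notch_freqs = c(10, 11, 20, 21), notch_bandwidth = 2,
      fir_cutoff = 40, fir_stopband_atten = 60, fir_stopband_edge = 55,
      line_freqs = c(60, 120, 180),
      trial_duration = 0.3, prestim = 0, screening_k = 10
    ),
    enhancement = list(radius = 0.022 * 1.7, threshold = 0.8,
                       rule = "nminus1"),
    topomap = list(size = 224, colormap = "viridis"),
    classifier = list(
      enabled = TRUE, backbone = "compact-scratch", dropout_prob = 0.6,
      learning_rate = 1e-4, epochs = 10, val_fraction = 0.2,
      batch_size = 16, momentum = 0.9,
      n_noise_train = NULL, n_noise_test = NULL
    ),
    seed = 0L
  )
  overrides <- list(...)
  if (!missing(seed)) overrides$seed <- as.integer(seed)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  }
  for (sec in names(overrides)) {
    if (is.list(defaults[[sec]])) {
      if (!is.list(overrides[[sec]])) {
        stop(sprintf("section '%s' must be a named list", sec))
      }
      bad_keys <- setdiff(names(overrides[[sec]]), names(defaults[[sec]]))
      if (length(bad_keys)) {
        stop(sprintf("unknown key(s) in '%s': %s", sec,
                     paste(bad_keys, collapse = ", ")))
      }
      defaults[[sec]][names(overrides[[sec]])] <- overrides[[sec]]
    } else {
      defaults[[sec]] <- overrides[[sec]]
    }
  }
  structure(defaults, class = "pipeline_config")
}

#' Configuration file round trip
#'
#' Configurations serialize to YAML and read back losslessly; unknown keys in
#' a file are rejected on read.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 0L
  raw$seed <- NULL
  do.call(pipeline_config, c(raw, list(seed = seed)))
}

#' Stable hash of a configuration
#'
#' @param config a [pipeline_config()].
#' @return md5 hex string of the canonical YAML serialization.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_pipeline_config(config, tmp)
  unname(tools::md5sum(tmp))
}

config_scenario <- function(config, second = FALSE) {
  sc <- config$scenario
  synth_scenario(
    n_sensors = sc$n_sensors, head_radius = sc$head_radius,
    cap_angle = sc$cap_angle, rate = sc$rate,
    session_length = sc$session_length,
    n_stimuli = if (second) sc$n_stimuli_second else sc$n_stimuli,
    trial_duration = sc$trial_duration, snr = sc$snr,
    noise_length = sc$noise_length, audio_delay = sc$audio_delay,
    seed = if (second) sub_seed(config$seed, 1000L) else config$seed
  )
}

#' Simulate and write the study sessions
#'
#' Writes two AEF sessions (the second with one fewer stimulus, as the
#' training/testing pair) and one empty-room noise session, with ground-truth
#' event files and a JSON truth manifest, all reproducible from the
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return named list of file paths, invisibly.
#' @export
cmd_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    session1 = file.path(out_dir, "session1.meg.rds"),
    session2 = file.path(out_dir, "session2.meg.rds"),
    noise = file.path(out_dir, "noise.meg.rds"),
    events1 = file.path(out_dir, "events_session1.txt"),
    events2 = file.path(out_dir, "events_session2.txt"),
    truth = file.path(out_dir, "truth.json"),
    config = file.path(out_dir, "config.yaml")
  )
  truth <- list(config_hash = config_hash(config), seed = config$seed)
  for (which in 1:2) {
    sess <- simulate_session(config_scenario(config, second = which == 2L))
    write_recording(sess$recording, paths[[paste0("session", which)]])
    write_events(sess$events, paths[[paste0("events", which)]])
    truth[[paste0("session", which)]] <- list(
      n_stimuli = sum(sess$events$kind == "stimulus"),
      stimulus_times = sess$events$time[sess$events$kind == "stimulus"],
      trial_labels = sess$trial_labels,
      noise_scale = sess$noise_scale
    )
    rm(sess)
    gc(verbose = FALSE)
  }
  noise <- simulate_noise_session(config_scenario(config))
  write_recording(noise$recording, paths$noise)
  truth$noise <- list(duration = noise$recording$duration,
                      noise_scale = noise$noise_scale)
  rm(noise)
  gc(verbose = FALSE)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  write_pipeline_config(config, paths$config)
  invisible(paths)
}

# preprocess one AEF session: events -> SSP -> notch -> FIR -> trials
preprocess_session <- function(rec, config, log) {
  pp <- config$preprocessing
  audio <- rec$data[rec$roles == "audio", ]
  events <- detect_stimulus_events(audio, rec$rate,
                                   threshold_frac = pp$stim_threshold_frac,
                                   refractory = pp$stim_refractory)
  arte <- detect_artifact_events(
    eog_v = rec$data[rec$roles == "eog-v", ],
    eog_h = rec$data[rec$roles == "eog-h", ],
    ecg = rec$data[rec$roles == "ecg", ],
    rate = rec$rate, blink_threshold = pp$blink_threshold,
    cardiac_threshold = pp$cardiac_threshold,
    refractory = pp$artifact_refractory
  )
  log("events", stimuli = nrow(events),
      blinks = sum(arte$kind == "blink"),
      cardiac = sum(arte$kind == "cardiac"))
  proj <- NULL
  for (kind in c("blink", "cardiac")) {
    ev <- events_of_kind(arte, kind)
    if (nrow(ev)) {
      u <- compute_ssp_projectors(rec, ev, window = pp$ssp_window,
                                  n_components = pp$ssp_components)
      proj <- if (is.null(proj)) u else cbind(proj, u)
    }
  }
  rec <- apply_ssp(rec, proj)
  rec <- notch_filter(rec, freqs = pp$notch_freqs,
                      bandwidth_3db = pp$notch_bandwidth)
  rec <- lowpass_fir(rec, cutoff = pp$fir_cutoff,
                     stopband_atten = pp$fir_stopband_atten,
                     line_freqs = pp$line_freqs,
                     stopband_edge = pp$fir_stopband_edge)
  trials <- segment_trials(rec, events, duration = pp$trial_duration,
                           prestim = pp$prestim)
  scr <- screen_trials(trials, k = pp$screening_k)
  log("screening", total = length(trials), kept = length(scr$kept),
      rejected = length(scr$rejected))
  list(trials = trials[scr$kept], events = events, screened = scr,
       array = rec$array)
}

# trials -> enhanced energies -> rendered images
render_trials <- function(trials, graph, renderer, config) {
  en <- config$enhancement
  lapply(trials, function(tr) {
    enh <- enhance_trial(tr, graph, threshold = en$threshold, rule = en$rule)
    render_topomap(trial_energy(enh, normalize = TRUE), renderer = renderer)
  })
}

#' Run the full recognition pipeline on simulated or ingested sessions
#'
#' Executes event marking, SSP artifact removal, the notch and FIR filter
#' chain, 0.3 s trial interception, power screening, neighbourhood-correlation
#' enhancement, normalized-energy imaging, and (unless disabled) the
#' train/evaluate cycle: the first session's AEF images plus empty-room noise
#' images form the training source (80/20 split internally), the second
#' session's AEF images plus unseen noise images form the testing source.
#' Writes the image datasets, the model checkpoint and a metrics JSON with
#' stage counts, and returns the metrics.
#'
#' @param config a [pipeline_config()].
#' @param session_paths named list with `session1`, `session2`, `noise` file
#'   paths (from [cmd_simulate()]).
#' @param out_dir output directory.
#' @return metrics list (stage counts, accuracies, confusion matrices),
#'   invisibly.
#' @export
cmd_run_pipeline <- function(config, session_paths, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  log <- function(stage, ...) {
    entry <- list(...)
    stages[[stage]] <<- c(stages[[stage]], list(entry))
    message(sprintf("[%s] %s", stage,
                    paste(names(entry), unlist(entry), sep = "=",
                          collapse = " ")))
  }

  sessions <- list()
  for (which in 1:2) {
    rec <- read_recording(session_paths[[paste0("session", which)]])
    sessions[[which]] <- preprocess_session(rec, config, log)
    rm(rec)
    gc(verbose = FALSE)
  }
  array <- sessions[[1]]$array
  graph <- build_neighbourhoods(array, radius = config$enhancement$radius)
  renderer <- topomap_renderer(project_to_plane(array),
                               size = config$topomap$size,
                               colormap = config$topomap$colormap)

  pp <- config$preprocessing
  noise_rec <- read_recording(session_paths$noise)
  noise_rec <- notch_filter(noise_rec, freqs = pp$notch_freqs,
                            bandwidth_3db = pp$notch_bandwidth)
  noise_rec <- lowpass_fir(noise_rec, cutoff = pp$fir_cutoff,
                           stopband_atten = pp$fir_stopband_atten,
                           line_freqs = pp$line_freqs,
                           stopband_edge = pp$fir_stopband_edge)
  noise_trials <- segment_fixed(noise_rec, duration = pp$trial_duration)
  rm(noise_rec)
  gc(verbose = FALSE)

  cl <- config$classifier
  n_half <- as.integer(length(noise_trials) %/% 2)
  n_tr <- as.integer(min(cl$n_noise_train %||% n_half, n_half))
  n_te <- as.integer(min(cl$n_noise_test %||% (length(noise_trials) - n_half),
                         length(noise_trials) - n_tr))
  slot_order <- with_seed(sub_seed(config$seed, 77L),
                          sample.int(length(noise_trials)))
  noise_train <- noise_trials[slot_order[seq_len(n_tr)]]
  noise_test <- noise_trials[slot_order[n_tr + seq_len(n_te)]]
  log("noise_segments", total = length(noise_trials),
      train = n_tr, test = n_te)

  images_train <- c(render_trials(sessions[[1]]$trials, graph, renderer, config),
                    render_trials(noise_train, graph, renderer, config))
  labels_train <- c(rep("aef", length(sessions[[1]]$trials)),
                    rep("noise", length(noise_train)))
  images_test <- c(render_trials(sessions[[2]]$trials, graph, renderer, config),
                   render_trials(noise_test, graph, renderer, config))
  labels_test <- c(rep("aef", length(sessions[[2]]$trials)),
                   rep("noise", length(noise_test)))
  manifest_train <- write_image_dataset(
    images_train, labels_train, file.path(out_dir, "train"),
    ids = sprintf("train_%04d", seq_along(images_train))
  )
  manifest_test <- write_image_dataset(
    images_test, labels_test, file.path(out_dir, "test"),
    ids = sprintf("test_%04d", seq_along(images_test))
  )
  log("images", train = nrow(manifest_train), test = nrow(manifest_test))

  metrics <- list(
    config_hash = config_hash(config), seed = config$seed, stages = stages,
    counts = list(
      trials_session1 = length(sessions[[1]]$trials),
      trials_session2 = length(sessions[[2]]$trials),
      noise_train = n_tr, noise_test = n_te,
      images_train = nrow(manifest_train), images_test = nrow(manifest_test)
    )
  )

  if (isTRUE(cl$enabled)) {
    spec <- classifier_spec(
      backbone = cl$backbone, dropout_prob = cl$dropout_prob,
      learning_rate = cl$learning_rate, epochs = cl$epochs,
      val_fraction = cl$val_fraction, seed = config$seed,
      batch_size = cl$batch_size, momentum = cl$momentum
    )
    parts <- split_dataset(manifest_train, val_fraction = spec$val_fraction,
                           seed = spec$seed)
    model <- train_classifier(parts$train, parts$val, spec)
    save_classifier(model, file.path(out_dir, "model.rds"))
    ev_train <- evaluate_classifier(model, manifest_train)
    ev_test <- evaluate_classifier(model, manifest_test)
    log("evaluate", train_accuracy = ev_train$accuracy,
        test_accuracy = ev_test$accuracy)
    metrics$split <- list(train = nrow(parts$train), val = nrow(parts$val))
    metrics$validation_history <- model$history
    metrics$train_source <- ev_train
    metrics$test_source <- ev_test
  }

  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(metrics)
}
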