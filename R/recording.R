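#' Multichannel MEG recording
#'
#' Container for a continuous multichannel recording: MEG channels in tesla
#' plus auxiliary channels (audio, stimulus trigger, bipolar EOG and ECG) in
#' volts, all sampled at a common rate.
#'
#' @param data numeric matrix, channels x samples.
#' @param rate sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `data`.
#' @param roles character vector aligned with `channel_labels`; each element
#'   one of `"meg"`, `"audio"`, `"stim"`, `"eog-v"`, `"eog-h"`, `"ecg"`.
#' @param array optional [sensor_array()]; MEG labels must be a subset of its
#'   labels.
#' @return an object of class `meg_recording` with elements `data`, `rate`,
#'   `channel_labels`, `roles`, `array`, and `duration` (seconds).
#' @export
recording <- function(data, rate, channel_labels, roles, array = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  assert_scalar(rate, "rate", lower = 0, strict_lower = TRUE)
  channel_labels <- as.character(channel_labels)
  roles <- as.character(roles)
  if (nrow(data) != length(channel_labels) || nrow(data) != length(roles)) {
    stop("`channel_labels` and `roles` must match the rows of `data`")
  }
  if (anyDuplicated(channel_labels)) stop("channel labels must be unique")
  ok_roles <- c("meg", "audio", "stim", "eog-v", "eog-h", "ecg")
  if (!all(roles %in% ok_roles)) {
    stop("roles must be one of: ", paste(ok_roles, collapse = ", "))
  }
  if (!is.null(array)) {
    stopifnot(inherits(array, "sensor_array"))
    meg_labels <- channel_labels[roles == "meg"]
    if (!all(meg_labels %in% array$labels)) {
      stop("MEG channel labels must be a subset of the sensor array labels")
    }
  }
  structure(
    list(data = data, rate = rate, channel_labels = channel_labels,
         roles = roles, array = array,
         duration = ncol(data) / rate),
    class = "meg_recording"
  )
}

#' @export
print.meg_recording <- function(x, ...) {
  cat(sprintf("<meg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, x$duration))
  print(table(x$roles))
  invisible(x)
}

# indices of MEG channels
meg_idx <- function(rec) which(rec$roles == "meg")

# replace MEG rows of a recording, leaving aux untouched
set_meg_data <- function(rec, new_meg) {
  idx <- meg_idx(rec)
  stopifnot(nrow(new_meg) == length(idx), ncol(new_meg) == ncol(rec$data))
  rec$data[idx, ] <- new_meg
  rec
}

#' Session container I/O
#'
#' Recordings are serialized as a single-file container holding the data
#' matrix, rate, labels, roles and sensor positions. The same
#' `read_recording()` surface is the adapter point for external session
#' sources.
#'
#' @param rec a [recording()].
#' @param path file path (conventional extension `.meg.rds`).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the [recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "meg_recording"))
  payload <- list(
    data = rec$data, rate = rec$rate, labels = rec$channel_labels,
    roles = rec$roles,
    sensor_labels = rec$array$labels,
    sensor_positions = rec$array$positions,
    sensor_regions = rec$array$region_tags,
    head_radius = rec$array$head_radius
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  p <- readRDS(path)
  array <- if (!is.null(p$sensor_positions)) {
    sensor_array(p$sensor_labels, p$sensor_positions,
                 region_tags = p$sensor_regions, head_radius = p$head_radius)
  }
  recording(p$data, p$rate, p$labels, p$roles, array = array)
}

#' Event list
#'
#' Timestamped events of kind `"stimulus"`, `"blink"` or `"cardiac"`, in
#' seconds from recording start. Times must be strictly increasing within a
#' kind.
#'
#' @param times numeric vector of event times in seconds.
#' @param kinds character vector of event kinds, recycled if length 1.
#' @return a `data.frame` of class `event_list` with columns `time`, `kind`.
#' @export
event_list <- function(times = numeric(0), kinds = character(0)) {
  if (length(kinds) == 1L) kinds <- rep(kinds, length(times))
  if (length(times) != length(kinds)) stop("`times` and `kinds` lengths differ")
  ok <- c("stimulus", "blink", "cardiac")
  if (!all(kinds %in% ok)) stop("kinds must be one of: ", paste(ok, collapse = ", "))
  if (length(times)) {
    assert_finite(times, "times")
    if (any(times < 0)) stop("event times must be nonnegative")
    for (k in unique(kinds)) {
      tk <- times[kinds == k]
      if (is.unsorted(tk, strictly = TRUE)) {
        stop(sprintf("event times must be strictly increasing within kind '%s'", k))
      }
    }
  }
  structure(data.frame(time = as.numeric(times), kind = as.character(kinds),
                       stringsAsFactors = FALSE),
            class = c("event_list", "data.frame"))
}

#' Read and write events as a two-column text file
#'
#' Plain-text exchange format: header `time_s kind`, one event per row.
#'
#' @param events an [event_list()].
#' @param path file path.
#' @return `read_events()` returns an [event_list()].
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_list"))
  tab <- data.frame(time_s = events$time, kind = events$kind)
  utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  event_list(tab$time_s, tab$kind)
}

# subset an event list by kind, preserving class
events_of_kind <- function(events, kind) {
  events[events$kind == kind, , drop = FALSE]
}
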