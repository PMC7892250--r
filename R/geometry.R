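#' Sensor array on a spherical cap
#'
#' A labelled set of 3-D MEG sensor positions in the head frame (origin at the
#' sphere centre, +z toward the vertex, +x anterior, +y toward the left ear),
#' optionally tagged with coarse anatomical regions. Positions are expected to
#' lie on a spherical cap: all radii must fall within 10% of `head_radius`.
#'
#' @param labels character vector of unique sensor identifiers.
#' @param positions numeric matrix, one row per sensor, columns x, y, z in
#'   meters.
#' @param region_tags optional character vector of anatomical tags
#'   (e.g. `"temporal-right"`), one per sensor.
#' @param head_radius cap radius in meters; defaults to the median sensor
#'   radius.
#' @return an object of class `sensor_array` with elements `labels`,
#'   `positions`, `region_tags`, `head_radius`.
#' @examples
#' arr <- sensor_array(c("A", "B"),
#'                     rbind(c(0, 0, 0.11), c(0.11, 0, 0)))
#' arr$head_radius
#' @export
sensor_array <- function(labels, positions, region_tags = NULL,
                         head_radius = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop("`positions` must have 3 columns (x, y, z)")
  n <- nrow(positions)
  if (n < 1L) stop("sensor array must contain at least one sensor")
  labels <- as.character(labels)
  if (length(labels) != n) stop("`labels` length must match rows of `positions`")
  if (anyDuplicated(labels)) stop("sensor labels must be unique")
  assert_finite(positions, "positions")
  radii <- sqrt(rowSums(positions^2))
  if (is.null(head_radius)) head_radius <- stats::median(radii)
  assert_scalar(head_radius, "head_radius", lower = 0, strict_lower = TRUE)
  if (!is.null(region_tags)) {
    region_tags <- as.character(region_tags)
    if (length(region_tags) != n) stop("`region_tags` length must match sensors")
  }
  structure(
    list(labels = labels, positions = positions, region_tags = region_tags,
         head_radius = head_radius),
    class = "sensor_array"
  )
}

#' Check the spherical-cap assumption of a sensor array
#'
#' Verifies that every sensor radius lies within `tol` (fractional) of the
#' array's `head_radius`. Layouts used for forward simulation and scalp
#' projection should satisfy this; ad-hoc test arrays need not.
#'
#' @param array a [sensor_array()].
#' @param tol allowed fractional deviation from `head_radius` (default 0.1).
#' @return `array`, invisibly; errors if the cap assumption is violated.
#' @export
validate_sensor_array <- function(array, tol = 0.1) {
  stopifnot(inherits(array, "sensor_array"))
  radii <- sqrt(rowSums(array$positions^2))
  bad <- radii < (1 - tol) * array$head_radius |
    radii > (1 + tol) * array$head_radius
  if (any(bad)) {
    stop(sprintf(
      "%d sensor(s) deviate more than %.0f%% from head_radius %.3f m",
      sum(bad), 100 * tol, array$head_radius
    ))
  }
  invisible(array)
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d sensors, head radius %.3f m\n",
              length(x$labels), x$head_radius))
  if (!is.null(x$region_tags)) {
    print(table(x$region_tags))
  }
  invisible(x)
}

#' Read and write plain-text sensor layouts
#'
#' The layout format is a whitespace-separated table with a header and columns
#' `label`, `x`, `y`, `z` (meters) and optionally `region`. This is also the
#' adapter surface for importing positions exported from standard M/EEG
#' software: any tool that can emit such a table can feed the pipeline.
#'
#' @param path file path.
#' @return `read_sensor_layout()` returns a [sensor_array()];
#'   `write_sensor_layout()` returns `path` invisibly.
#' @export
read_sensor_layout <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("layout file must have columns label, x, y, z")
  }
  sensor_array(tab$label, as.matrix(tab[, c("x", "y", "z")]),
               region_tags = tab$region)
}

#' @rdname read_sensor_layout
#' @param array a [sensor_array()].
#' @export
write_sensor_layout <- function(array, path) {
  stopifnot(inherits(array, "sensor_array"))
  tab <- data.frame(label = array$labels,
                    x = array$positions[, 1],
                    y = array$positions[, 2],
                    z = array$positions[, 3])
  if (!is.null(array$region_tags)) tab$region <- array$region_tags
  utils::write.table(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the sensor neighbourhood graph
#'
#' Each sensor's neighbourhood is the set of other sensors within a straight
#' Euclidean distance `radius` (closed ball: ties at exactly the radius are
#' included). With the default radius of 0.022 x 1.7 m on a CTF-like 274
#' sensor cap, each sensor acquires on the order of 5 to 8 neighbours.
#'
#' @param array a [sensor_array()].
#' @param radius neighbourhood radius in meters (default `0.022 * 1.7`).
#' @return an object of class `neighbourhood_graph`: list with `radius`,
#'   `neighbors` (per-sensor integer vectors, ascending), `degrees`, `labels`.
#' @examples
#' arr <- sensor_array(letters[1:3],
#'                     cbind(c(0, 0.03, 0.06), 0, 0), head_radius = 0.045)
#' g <- build_neighbourhoods(arr, 0.0374)
#' g$degrees
#' @export
build_neighbourhoods <- function(array, radius = 0.022 * 1.7) {
  stopifnot(inherits(array, "sensor_array"))
  assert_scalar(radius, "radius", lower = 0, strict_lower = TRUE)
  pos <- array$positions
  n <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  if (n > 1L && any(d[upper.tri(d)] == 0)) {
    message("duplicate sensor positions present in array")
  }
  adj <- d <= radius
  diag(adj) <- FALSE
  neighbors <- lapply(seq_len(n), function(i) which(adj[i, ]))
  structure(
    list(radius = radius,
         neighbors = neighbors,
         degrees = vapply(neighbors, length, integer(1)),
         labels = array$labels),
    class = "neighbourhood_graph"
  )
}

#' @export
print.neighbourhood_graph <- function(x, ...) {
  cat(sprintf("<neighbourhood_graph> %d sensors, radius %.4f m, degrees %d..%d\n",
              length(x$neighbors), x$radius, min(x$degrees), max(x$degrees)))
  invisible(x)
}

#' Default neighbourhood radius for an arbitrary array
#'
#' Generalizes the fixed CTF-cap radius (mean inter-sensor distance times 1.7)
#' to any layout: `factor` times the mean nearest-neighbour distance.
#'
#' @param array a [sensor_array()] with at least 2 sensors.
#' @param factor positive multiplier (default 1.7).
#' @return radius in meters.
#' @export
default_radius <- function(array, factor = 1.7) {
  stopifnot(inherits(array, "sensor_array"))
  assert_scalar(factor, "factor", lower = 0, strict_lower = TRUE)
  n <- nrow(array$positions)
  if (n < 2L) stop("`default_radius()` needs at least 2 sensors")
  d <- as.matrix(stats::dist(array$positions))
  diag(d) <- Inf
  factor * mean(apply(d, 1L, min))
}

#' Azimuthal-equidistant projection of cap sensors to the plane
#'
#' Projects sensors from the vertex: planar radius is proportional to the
#' polar angle (angle from +z), azimuth is preserved, and the cap rim (the
#' maximum polar angle present in the array) maps to the unit circle. The
#' vertex maps to (0, 0). Sensors must sit on the upper cap; a sensor at or
#' near the antipode of the projection centre is rejected.
#'
#' @param array a [sensor_array()].
#' @return numeric matrix with columns `px`, `py`, rows aligned to sensors.
#' @export
project_to_plane <- function(array) {
  stopifnot(inherits(array, "sensor_array"))
  pos <- array$positions
  r <- sqrt(rowSums(pos^2))
  theta <- acos(pmin(1, pmax(-1, pos[, 3] / r)))
  if (any(theta >= 5 * pi / 6)) {
    stop("sensor at or near the projection antipode (polar angle >= 150 degrees)")
  }
  phi <- atan2(pos[, 2], pos[, 1])
  rim <- max(theta)
  rad <- if (rim > 0) theta / rim else theta * 0
  out <- cbind(px = rad * cos(phi), py = rad * sin(phi))
  rownames(out) <- array$labels
  out
}
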