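# thin-plate-spline kernel; k(0) = 0
tps_kernel <- function(r) {
  out <- r * r * log(r)
  out[r == 0] <- 0
  out
}

#' Precompute a topographic renderer for a fixed sensor layout
#'
#' Rendering interpolates per-sensor energies over the projected scalp disc
#' with a thin-plate spline (exact at sensor sites, smooth everywhere). The
#' interpolation system and its evaluation matrix depend only on the planar
#' sensor coordinates, so for repeated rendering they are factored once here.
#'
#' @param coords2d numeric matrix, sensors x 2, planar coordinates inside the
#'   unit disc (from [project_to_plane()]).
#' @param size image side in pixels (default 224).
#' @param colormap name of a [grDevices::hcl.colors()] palette
#'   (default `"viridis"`, dark-to-bright, dark background).
#' @return an object of class `topomap_renderer`.
#' @export
topomap_renderer <- function(coords2d, size = 224, colormap = "viridis") {
  coords2d <- as.matrix(coords2d)
  n <- nrow(coords2d)
  if (n < 3L) stop("interpolation needs at least 3 sensors")
  if (ncol(coords2d) != 2L) stop("`coords2d` must have 2 columns")
  rad <- sqrt(rowSums(coords2d^2))
  if (any(rad > 1 + 1e-9)) stop("planar coordinates must lie within the unit disc")
  assert_scalar(size, "size", lower = 8)

  d <- as.matrix(stats::dist(coords2d))
  K <- tps_kernel(d)
  P <- cbind(1, coords2d)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  M_inv <- solve(M)

  # pixel grid: row 1 = py +1 (top), col 1 = px -1 (left)
  ax <- -1 + (2 * seq_len(size) - 1) / size
  gx <- rep(ax, each = size)
  gy <- rep(rev(ax), times = size)
  inside <- gx^2 + gy^2 <= 1
  gxi <- gx[inside]
  gyi <- gy[inside]
  dg <- sqrt(outer(gxi, coords2d[, 1], "-")^2 +
             outer(gyi, coords2d[, 2], "-")^2)
  E <- cbind(tps_kernel(dg), 1, gxi, gyi)

  structure(
    list(coords2d = coords2d, size = as.integer(size), colormap = colormap,
         M_inv = M_inv, E = E, inside = inside,
         lut = t(grDevices::col2rgb(
           grDevices::hcl.colors(256L, colormap)
         )) / 255),
    class = "topomap_renderer"
  )
}

#' Render a normalized energy vector as a scalp topography image
#'
#' Produces a `size x size` RGB image: the normalized per-sensor energies are
#' interpolated over the unit disc (thin-plate spline, exact at sensor sites),
#' clipped to `[0, 1]`, mapped through a fixed perceptually-uniform colormap,
#' and set to the black background outside the disc. The default 224 x 224
#' size matches the input contract of standard image-classification networks.
#'
#' @param energy a normalized [trial_energy()] vector (max 1, values in
#'   `[0, 1]`).
#' @param coords2d planar sensor coordinates (ignored when `renderer` given).
#' @param size image side in pixels (default 224).
#' @param renderer a precomputed [topomap_renderer()]; pass this when
#'   rendering many trials on one layout.
#' @return an object of class `topo_image`: list with `pixels`
#'   (`size x size x 3` array in `[0, 1]`, 8-bit quantized) and `meta`
#'   (colormap, mask radius, source energy checksum).
#' @export
render_topomap <- function(energy, coords2d = NULL, size = 224,
                           renderer = NULL) {
  if (!isTRUE(attr(energy, "normalized")) ||
      any(energy < 0) || any(energy > 1) || max(energy) != 1) {
    stop("`energy` must be a normalized energy vector (max 1, values in [0, 1])")
  }
  if (is.null(renderer)) {
    if (is.null(coords2d)) stop("provide `coords2d` or a `renderer`")
    renderer <- topomap_renderer(coords2d, size = size)
  }
  n <- nrow(renderer$coords2d)
  if (length(energy) != n) stop("energy length does not match the renderer layout")

  w <- renderer$M_inv %*% c(as.numeric(energy), 0, 0, 0)
  field <- as.numeric(renderer$E %*% w)
  field <- pmin(1, pmax(0, field))

  size <- renderer$size
  idx <- 1L + as.integer(round(field * 255))
  pixels <- array(0, dim = c(size, size, 3L))
  inside <- renderer$inside
  for (ch in 1:3) {
    plane <- matrix(0, size, size)
    plane[inside] <- renderer$lut[idx, ch]
    pixels[, , ch] <- plane
  }
  pixels <- round(pixels * 255) / 255
  structure(
    list(pixels = pixels,
         meta = list(colormap = renderer$colormap, mask_radius = 1,
                     energy_checksum = sprintf("%.12e", sum(energy)))),
    class = "topo_image"
  )
}

#' @export
print.topo_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<topo_image> %d x %d x %d, colormap %s\n",
              d[1], d[2], d[3], x$meta$colormap))
  invisible(x)
}

# scalar interpolated field value at one planar coordinate (diagnostics/tests)
evaluate_topofield <- function(renderer, energy, at) {
  w <- renderer$M_inv %*% c(as.numeric(energy), 0, 0, 0)
  r <- sqrt((at[1] - renderer$coords2d[, 1])^2 +
            (at[2] - renderer$coords2d[, 2])^2)
  sum(c(tps_kernel(r), 1, at[1], at[2]) * w)
}

#' Write a labelled topographic image dataset to disk
#'
#' Images are written as lossless PNG files into one subdirectory per class,
#' with a manifest CSV (`path`, `label`, `source_trial_id`) at the dataset
#' root.
#'
#' @param images list of [render_topomap()] images.
#' @param labels character vector of class tags, `"aef"` or `"noise"`.
#' @param dir output directory (created if missing).
#' @param ids optional per-image provenance identifiers.
#' @return the manifest `data.frame`, invisibly; also written to
#'   `dir/manifest.csv`.
#' @export
write_image_dataset <- function(images, labels, dir, ids = NULL) {
  if (length(images) != length(labels)) stop("images/labels length mismatch")
  if (!all(labels %in% c("aef", "noise"))) {
    stop('labels must be "aef" or "noise"')
  }
  if (is.null(ids)) ids <- sprintf("img_%04d", seq_along(images))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cls in c("aef", "noise")) {
    dir.create(file.path(dir, cls), showWarnings = FALSE)
  }
  paths <- character(length(images))
  for (i in seq_along(images)) {
    paths[i] <- file.path(dir, labels[i], paste0(ids[i], ".png"))
    png::writePNG(images[[i]]$pixels, paths[i])
  }
  manifest <- data.frame(path = paths, label = labels, source_trial_id = ids,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read one topographic image back from PNG
#'
#' @param path PNG file path.
#' @return numeric array `H x W x 3` in `[0, 1]`.
#' @export
read_topomap_png <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3L))
  px[, , 1:3, drop = FALSE]
}
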