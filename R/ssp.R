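#' Estimate signal-space projection (SSP) components from artifact epochs
#'
#' Blink and cardiac artifacts occupy a low-dimensional spatial subspace that
#' is stable across occurrences. SSP estimates that subspace as the leading
#' eigenvectors of the channel covariance of event-locked epochs; projecting
#' the data onto its orthogonal complement removes the artifact while leaving
#' brain signal with different topographies largely intact.
#'
#' @param rec a [recording()].
#' @param events an [event_list()]; all rows are used (pre-filter by kind with
#'   one call per artifact type).
#' @param window half-width of the epoch around each event in seconds
#'   (default 0.2, i.e. epochs of +/- 0.2 s).
#' @param n_components number of spatial components to retain (default 1).
#' @return numeric matrix `channels x n_components`, orthonormal columns
#'   ordered by explained variance, with attribute `"explained"` holding the
#'   per-component explained-variance fractions.
#' @export
compute_ssp_projectors <- function(rec, events, window = 0.2,
                                   n_components = 1L) {
  stopifnot(inherits(rec, "meg_recording"), inherits(events, "event_list"))
  idx <- meg_idx(rec)
  n_ch <- length(idx)
  assert_scalar(n_components, "n_components", lower = 1, upper = n_ch)
  if (nrow(events) < 1L) stop("at least one artifact event is required")
  half <- round(window * rec$rate)
  n <- ncol(rec$data)
  centers <- round(events$time * rec$rate) + 1L
  usable <- centers - half >= 1L & centers + half <= n
  if (!any(usable)) stop("no artifact epoch fits inside the recording")
  segs <- lapply(centers[usable], function(c0) {
    rec$data[idx, (c0 - half):(c0 + half), drop = FALSE]
  })
  epochs <- do.call(cbind, segs)
  epochs <- epochs - rowMeans(epochs)
  cv <- tcrossprod(epochs) / ncol(epochs)
  eg <- eigen(cv, symmetric = TRUE)
  u <- eg$vectors[, seq_len(n_components), drop = FALSE]
  attr(u, "explained") <- eg$values / sum(eg$values)
  u
}

#' Apply SSP projectors to a recording
#'
#' Replaces each time sample's MEG channel vector by its component orthogonal
#' to the span of the projector columns. Auxiliary channels are untouched.
#' Applying the same projectors twice is a no-op (orthogonal projection is
#' idempotent).
#'
#' @param rec a [recording()].
#' @param projectors matrix `meg_channels x k` (e.g. from
#'   [compute_ssp_projectors()]), or `NULL` / zero-column matrix for identity.
#' @return the projected [recording()].
#' @export
apply_ssp <- function(rec, projectors) {
  stopifnot(inherits(rec, "meg_recording"))
  if (is.null(projectors) || NCOL(projectors) == 0L) return(rec)
  projectors <- as.matrix(projectors)
  idx <- meg_idx(rec)
  if (nrow(projectors) != length(idx)) {
    stop("projector dimension does not match the MEG channel count")
  }
  # re-orthonormalize so stacked projectors from several artifact kinds work
  qr_u <- qr(projectors)
  u <- qr.Q(qr_u)[, seq_len(qr_u$rank), drop = FALSE]
  meg <- rec$data[idx, , drop = FALSE]
  set_meg_data(rec, meg - u %*% crossprod(u, meg))
}
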