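#' Pearson correlation coefficient (population moments)
#'
#' The correlation between a selected channel and one of its neighbours,
#' computed from population (1/N) moments:
#' `(E[xy] - E[x]E[y]) / sqrt(Var(x) Var(y))`, clamped to `[-1, 1]` against
#' rounding. The 1/N vs 1/(N-1) choice cancels in the ratio; population
#' moments are used for definiteness.
#'
#' @param x,y numeric vectors of equal length (>= 2), each with nonzero
#'   variance.
#' @return scalar correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 2L) stop("need at least 2 samples")
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  vx <- sum(x^2) / n - mx^2
  vy <- sum(y^2) / n - my^2
  if (vx <= 0 || vy <= 0) stop("zero variance input to pearson_correlation()")
  cxy <- sum(x * y) / n - mx * my
  min(1, max(-1, cxy / sqrt(vx * vy)))
}

#' Neighbourhood-correlation enhancement of a single trial
#'
#' The core single-trial operation: for each channel `i`, correlations with
#' its spatial neighbours are computed over the trial window; neighbours whose
#' correlation magnitude reaches `threshold` are superposed onto the channel
#' with their (signed) correlations as weights. With `n` qualifying
#' neighbours the default rule yields
#' `X_i + sum(c_ij * X_j) / (n - 1)` for `n >= 2`, `X_i + c_j * X_j` for
#' `n = 1`, and the unchanged channel for `n = 0`. All outputs are computed
#' from the original (pre-enhancement) channels; there is no sequential
#' update. Channels over an active source share the evoked waveform and are
#' reinforced; channels seeing independent noise are left alone.
#'
#' @param trial a [trial_segment()].
#' @param graph a [build_neighbourhoods()] graph over the same sensors.
#' @param threshold correlation-magnitude threshold in (0, 1], default 0.8;
#'   comparison is `>=` (ties qualify).
#' @param rule denominator convention for the neighbour sum: `"nminus1"`
#'   (default, as above), `"nplus1"` (divide the whole superposition by
#'   `n + 1`), or `"n"` (divide the neighbour sum by `n`).
#' @return an object of class `enhanced_trial` (extends `trial_segment`), with
#'   `weights_used` (per channel, matrix of neighbour index and correlation)
#'   and `n_qualified` (per-channel count).
#' @export
enhance_trial <- function(trial, graph, threshold = 0.8,
                          rule = c("nminus1", "nplus1", "n")) {
  stopifnot(inherits(trial, "trial_segment"),
            inherits(graph, "neighbourhood_graph"))
  rule <- match.arg(rule)
  assert_scalar(threshold, "threshold", lower = 0, upper = 1,
                strict_lower = TRUE)
  x <- trial$data
  n_ch <- nrow(x)
  if (n_ch != length(graph$neighbors)) {
    stop("trial channel count does not match the neighbourhood graph")
  }
  if (!is.null(graph$labels) && !identical(trial$labels, graph$labels)) {
    stop("trial channel labels do not match the neighbourhood graph sensors")
  }
  mu <- rowMeans(x)
  xc <- x - mu
  ss <- rowSums(xc^2)
  flat <- ss <= 0
  if (any(flat)) {
    warning(sprintf("%d zero-variance channel(s) left unenhanced", sum(flat)))
  }
  out <- x
  weights_used <- vector("list", n_ch)
  n_qualified <- integer(n_ch)
  for (i in seq_len(n_ch)) {
    weights_used[[i]] <- cbind(neighbor = integer(0), correlation = numeric(0))
    if (flat[i]) next
    nb <- graph$neighbors[[i]]
    nb <- nb[!flat[nb]]
    if (!length(nb)) next
    cc <- as.numeric(xc[nb, , drop = FALSE] %*% xc[i, ]) /
      sqrt(ss[nb] * ss[i])
    cc <- pmin(1, pmax(-1, cc))
    q <- abs(cc) >= threshold
    n <- sum(q)
    n_qualified[i] <- n
    if (n == 0L) next
    nbq <- nb[q]
    ccq <- cc[q]
    weights_used[[i]] <- cbind(neighbor = nbq, correlation = ccq)
    contrib <- drop(crossprod(x[nbq, , drop = FALSE], ccq))
    out[i, ] <- switch(rule,
      nminus1 = if (n == 1L) x[i, ] + contrib else x[i, ] + contrib / (n - 1),
      nplus1  = (x[i, ] + contrib) / (n + 1),
      n       = x[i, ] + contrib / n
    )
  }
  structure(
    c(unclass(trial)[c("onset", "duration", "rate", "labels")],
      list(data = out, weights_used = weights_used,
           n_qualified = n_qualified, threshold = threshold, rule = rule)),
    class = c("enhanced_trial", "trial_segment")
  )
}

#' Per-channel signal energy of a trial
#'
#' Energy of channel `i` is the sum of squared samples over the window. With
#' `normalize = TRUE` (the form used for imaging) the vector is divided by its
#' maximum, so values lie in `[0, 1]` with the strongest channel at 1.
#'
#' @param trial a [trial_segment()] or [enhance_trial()] result.
#' @param normalize divide by the maximum energy (default `TRUE`).
#' @return an object of class `energy_vector`: numeric vector named by channel
#'   labels, with attribute `"normalized"`.
#' @export
trial_energy <- function(trial, normalize = TRUE) {
  stopifnot(inherits(trial, "trial_segment"))
  e <- rowSums(trial$data^2)
  if (normalize) {
    m <- max(e)
    if (m == 0) stop("cannot normalize the energy of an all-zero trial")
    e <- e / m
  }
  names(e) <- trial$labels
  structure(e, normalized = normalize, class = "energy_vector")
}

#' Write an energy vector as a two-column text table
#'
#' @param energy an [trial_energy()] result.
#' @param path file path.
#' @export
write_energy <- function(energy, path) {
  stopifnot(inherits(energy, "energy_vector"))
  utils::write.table(
    data.frame(label = names(energy), energy = as.numeric(energy)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
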