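# Compact convolutional network internals.
#
# Architecture (input 224 x 224 x 3 in [0, 1]):
#   fixed 8x8 average pooling       -> 28 x 28 x 3
#   conv 8 filters 5x5 (valid), ReLU -> 24 x 24 x 8
#   max pool 4x4 stride 4            -> 6 x 6 x 8 = 288
#   dropout (train only, inverted scaling)
#   fully connected 288 -> 2, softmax
# Trained with momentum SGD and cross-entropy. The classifier head is
# zero-initialized so the decision direction is entirely data-driven; the
# convolutional bank is He-initialized from the seed.

CNN_IN <- 224L
CNN_POOL0 <- 8L
CNN_GRID <- CNN_IN %/% CNN_POOL0          # 28
CNN_K <- 5L                               # conv kernel
CNN_CONVOUT <- CNN_GRID - CNN_K + 1L      # 24
CNN_FILTERS <- 8L
CNN_POOL1 <- 4L
CNN_POOLOUT <- CNN_CONVOUT %/% CNN_POOL1  # 6
CNN_FEAT <- CNN_FILTERS * CNN_POOLOUT^2   # 288

# 224 -> 28 block-average projection matrix
cnn_pool_matrix <- function() {
  P <- matrix(0, CNN_IN, CNN_GRID)
  P[cbind(seq_len(CNN_IN), rep(seq_len(CNN_GRID), each = CNN_POOL0))] <-
    1 / CNN_POOL0
  P
}

# linear indices into the pooled 28 x 28 x 3 vector for each 5x5x3 patch;
# matrix (75 x 576), one column per conv output position (column-major grid)
cnn_im2col_index <- function() {
  g <- CNN_GRID
  out <- CNN_CONVOUT
  offs <- as.vector(outer(seq_len(CNN_K) - 1L,
                          (seq_len(CNN_K) - 1L) * g, "+"))
  offs <- as.vector(outer(offs, (seq_len(3L) - 1L) * g * g, "+"))
  base <- as.vector(outer(seq_len(out), (seq_len(out) - 1L) * g, "+"))
  matrix(rep(base, each = length(offs)) + offs, nrow = length(offs))
}

# column groups of the 24 x 24 conv grid for 4x4 max pooling (list of 36)
cnn_maxpool_groups <- function() {
  out <- CNN_CONVOUT
  idx <- matrix(seq_len(out * out), out, out)
  groups <- vector("list", CNN_POOLOUT^2)
  k <- 1L
  for (cj in seq_len(CNN_POOLOUT)) {
    for (ci in seq_len(CNN_POOLOUT)) {
      rows <- ((ci - 1L) * CNN_POOL1 + 1L):(ci * CNN_POOL1)
      cols <- ((cj - 1L) * CNN_POOL1 + 1L):(cj * CNN_POOL1)
      groups[[k]] <- as.vector(idx[rows, cols])
      k <- k + 1L
    }
  }
  groups
}

cnn_geometry <- function() {
  list(P = cnn_pool_matrix(), im2col = cnn_im2col_index(),
       groups = cnn_maxpool_groups())
}

# image array (224 x 224 x 3) -> patch matrix (75 x 576)
cnn_features <- function(pixels, geom) {
  if (!identical(dim(pixels)[1:2], c(CNN_IN, CNN_IN)) ||
      dim(pixels)[3] != 3L) {
    stop(sprintf("classifier input must be %d x %d x 3", CNN_IN, CNN_IN))
  }
  pooled <- vapply(1:3, function(ch) {
    crossprod(geom$P, pixels[, , ch] %*% geom$P)
  }, matrix(0, CNN_GRID, CNN_GRID))
  v <- as.vector(pooled) - 0.5        # centre the pixel scale
  matrix(v[geom$im2col], nrow = nrow(geom$im2col))
}

cnn_init <- function(seed) {
  fan_in <- CNN_K * CNN_K * 3L
  with_seed(seed, {
    list(
      W = matrix(stats::rnorm(CNN_FILTERS * fan_in, sd = sqrt(2 / fan_in)),
                 CNN_FILTERS, fan_in),
      b = numeric(CNN_FILTERS),
      V = matrix(0, 2L, CNN_FEAT),
      c = numeric(2L)
    )
  })
}

# forward pass on one patch matrix; returns activations for backprop.
# `norm` is a frozen standardization of the pooled feature vector (mean/sd
# estimated once on the training set before SGD), which removes the common
# mode of the nonnegative ReLU features so the zero-initialized head learns a
# class-contrast direction rather than overall brightness.
cnn_forward <- function(par, xcol, geom, drop_mask = NULL, norm = par$norm) {
  z <- par$W %*% xcol + par$b           # 8 x 576
  a <- z * (z > 0)
  feat <- numeric(CNN_FEAT)
  argmax <- integer(CNN_FILTERS * length(geom$groups))
  k <- 1L
  for (g in seq_along(geom$groups)) {
    cols <- geom$groups[[g]]
    sub <- a[, cols, drop = FALSE]
    j <- max.col(sub, ties.method = "first")
    for (f in seq_len(CNN_FILTERS)) {
      feat[(g - 1L) * CNN_FILTERS + f] <- sub[f, j[f]]
      argmax[k] <- cols[j[f]]
      k <- k + 1L
    }
  }
  feat_raw <- feat
  if (!is.null(norm)) feat <- (feat - norm$mean) / norm$sd
  if (!is.null(drop_mask)) feat <- feat * drop_mask
  logits <- as.numeric(par$V %*% feat + par$c)
  m <- max(logits)
  p <- exp(logits - m)
  p <- p / sum(p)
  list(z = z, feat = feat, feat_raw = feat_raw, argmax = argmax, probs = p)
}

# gradient of the cross-entropy loss for one sample
cnn_backward <- function(par, xcol, fwd, y_idx, geom, drop_mask = NULL) {
  dlog <- fwd$probs
  dlog[y_idx] <- dlog[y_idx] - 1
  dV <- dlog %o% fwd$feat
  dc <- dlog
  dfeat <- as.numeric(crossprod(par$V, dlog))
  if (!is.null(drop_mask)) dfeat <- dfeat * drop_mask
  if (!is.null(par$norm)) dfeat <- dfeat / par$norm$sd
  dA <- matrix(0, CNN_FILTERS, CNN_CONVOUT^2)
  k <- 1L
  for (g in seq_along(geom$groups)) {
    for (f in seq_len(CNN_FILTERS)) {
      col <- fwd$argmax[k]
      dA[f, col] <- dA[f, col] + dfeat[(g - 1L) * CNN_FILTERS + f]
      k <- k + 1L
    }
  }
  dZ <- dA * (fwd$z > 0)
  list(W = dZ %*% t(xcol), b = rowSums(dZ), V = dV, c = dc)
}

# momentum SGD over cached patch matrices
cnn_train <- function(par, xcols, y_idx, spec, val_xcols = NULL,
                      val_y = NULL) {
  n <- length(xcols)
  geom <- cnn_geometry()
  # freeze the feature standardization on the training set
  raw <- vapply(xcols, function(xc) {
    cnn_forward(par, xc, geom, norm = NULL)$feat_raw
  }, numeric(CNN_FEAT))
  par$norm <- list(mean = rowMeans(raw),
                   sd = pmax(apply(raw, 1L, stats::sd), 1e-8))
  vel <- lapply(par[c("W", "b", "V", "c")], function(p) p * 0)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_accuracy = numeric(0))
  if (spec$epochs == 0L) return(list(par = par, history = history))
  with_seed(sub_seed(spec$seed, 17L), {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = spec$batch_size)) {
        batch <- ord[start:min(start + spec$batch_size - 1L, n)]
        grad <- NULL
        for (i in batch) {
          mask <- if (spec$dropout_prob > 0) {
            (stats::runif(CNN_FEAT) >= spec$dropout_prob) /
              (1 - spec$dropout_prob)
          }
          fwd <- cnn_forward(par, xcols[[i]], geom, mask)
          losses <- c(losses, -log(max(fwd$probs[y_idx[i]], 1e-12)))
          g <- cnn_backward(par, xcols[[i]], fwd, y_idx[i], geom, mask)
          grad <- if (is.null(grad)) g else Map(`+`, grad, g)
        }
        grad <- lapply(grad, `/`, length(batch))
        for (nm in names(vel)) {
          vel[[nm]] <- spec$momentum * vel[[nm]] -
            spec$learning_rate * grad[[nm]]
          par[[nm]] <- par[[nm]] + vel[[nm]]
        }
      }
      val_acc <- NA_real_
      if (!is.null(val_xcols) && length(val_xcols)) {
        pred <- vapply(val_xcols, function(xc) {
          which.max(cnn_forward(par, xc, geom)$probs)
        }, integer(1))
        val_acc <- mean(pred == val_y)
      }
      history <- rbind(history, data.frame(
        epoch = ep, loss = mean(losses), val_accuracy = val_acc
      ))
    }
  })
  list(par = par, history = history)
}
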