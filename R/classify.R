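#' Classifier configuration
#'
#' Training configuration for the AEF-vs-noise image classifier. The defaults
#' are the recognition settings used throughout: final-layer dropout 0.6,
#' learning rate 1e-4, 10 epochs, 80/20 train/validation split. Two backbones
#' share one input/output contract (224 x 224 x 3 images in `[0, 1]`, two
#' classes): `"compact-scratch"` is a small convolutional network trained from
#' random initialization, CPU-trainable in minutes and the default;
#' `"pretrained-inception"` denotes fine-tuning a large pretrained
#' inception-style network (final dropout, new 2-output fully-connected layer,
#' rebuilt classification layer) and requires an external deep-learning
#' runtime with downloaded weights, so constructing it here raises an error
#' pointing at the compact backbone.
#'
#' @param backbone `"compact-scratch"` or `"pretrained-inception"`.
#' @param dropout_prob dropout probability of the final feature layer
#'   (default 0.6).
#' @param learning_rate SGD learning rate (default 1e-4).
#' @param epochs training epochs (default 10).
#' @param val_fraction validation fraction for [split_dataset()]
#'   (default 0.2).
#' @param seed integer seed controlling split, init, shuffling and dropout
#'   (default 0).
#' @param class_labels ordered pair of class tags
#'   (default `c("aef", "noise")`).
#' @param batch_size minibatch size (default 16).
#' @param momentum SGD momentum (default 0.9).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(backbone = c("compact-scratch",
                                         "pretrained-inception"),
                            dropout_prob = 0.6, learning_rate = 1e-4,
                            epochs = 10L, val_fraction = 0.2, seed = 0L,
                            class_labels = c("aef", "noise"),
                            batch_size = 16L, momentum = 0.9) {
  backbone <- match.arg(backbone)
  assert_scalar(dropout_prob, "dropout_prob", lower = 0, upper = 1,
                strict_upper = TRUE)
  assert_scalar(learning_rate, "learning_rate", lower = 0, strict_lower = TRUE)
  assert_scalar(epochs, "epochs", lower = 0)
  assert_scalar(val_fraction, "val_fraction", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  if (length(class_labels) != 2L || anyDuplicated(class_labels)) {
    stop("`class_labels` must be two distinct tags")
  }
  structure(
    list(backbone = backbone, dropout_prob = dropout_prob,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         val_fraction = val_fraction, seed = as.integer(seed),
         class_labels = as.character(class_labels),
         batch_size = as.integer(batch_size), momentum = momentum),
    class = "classifier_spec"
  )
}

#' Stratified train/validation split of an image manifest
#'
#' Splits the manifest by class: within each class,
#' `round(val_fraction * n)` items (at least 1) go to validation, the rest to
#' training. Deterministic given the seed; the two parts partition the input
#' exactly.
#'
#' @param manifest `data.frame` with at least a `label` column (e.g. from
#'   [write_image_dataset()]).
#' @param val_fraction validation fraction in (0, 1), default 0.2.
#' @param seed integer seed.
#' @return list with `train` and `val` manifests.
#' @export
split_dataset <- function(manifest, val_fraction = 0.2, seed = 0L) {
  if (!nrow(manifest)) stop("empty manifest")
  assert_scalar(val_fraction, "val_fraction", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  val_idx <- integer(0)
  classes <- unique(manifest$label)
  for (ci in seq_along(classes)) {
    in_cls <- which(manifest$label == classes[ci])
    if (length(in_cls) < 2L) {
      stop(sprintf("class '%s' has fewer than 2 items", classes[ci]))
    }
    n_val <- max(1L, round(val_fraction * length(in_cls)))
    picked <- with_seed(sub_seed(seed, 23L + ci), sample(in_cls, n_val))
    val_idx <- c(val_idx, picked)
  }
  val_idx <- sort(val_idx)
  list(train = manifest[setdiff(seq_len(nrow(manifest)), val_idx), ,
                        drop = FALSE],
       val = manifest[val_idx, , drop = FALSE])
}

# a dataset is either a manifest data.frame (path + label) or a list with
# elements `images` (topo_image list) and `labels`
dataset_to_xcols <- function(dataset, geom, class_labels) {
  if (is.data.frame(dataset)) {
    labels <- dataset$label
    pix <- lapply(dataset$path, read_topomap_png)
  } else {
    labels <- dataset$labels
    pix <- lapply(dataset$images, function(im) {
      if (inherits(im, "topo_image")) im$pixels else im
    })
  }
  if (!all(labels %in% class_labels)) {
    stop("dataset labels outside the classifier's class labels")
  }
  list(xcols = lapply(pix, cnn_features, geom = geom),
       y = match(labels, class_labels))
}

#' Train the AEF-vs-noise image classifier
#'
#' Fits the backbone selected in `spec` on the training images, tracking
#' validation accuracy per epoch. With `epochs = 0` the untrained (but valid)
#' model is returned.
#'
#' @param train,val datasets: either manifest `data.frame`s with `path` and
#'   `label` columns, or lists with `images` ([render_topomap()] objects or
#'   pixel arrays) and `labels`. `val` may be `NULL`.
#' @param spec a [classifier_spec()].
#' @return an object of class `aef_classifier` with the fitted parameters,
#'   `spec` and per-epoch `history` (loss, validation accuracy).
#' @export
train_classifier <- function(train, val = NULL, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$backbone == "pretrained-inception") {
    stop(paste(
      "the pretrained-inception backbone needs an external deep-learning",
      "runtime and downloaded weights; use backbone = \"compact-scratch\""
    ))
  }
  geom <- cnn_geometry()
  tr <- dataset_to_xcols(train, geom, spec$class_labels)
  if (!all(seq_along(spec$class_labels) %in% tr$y)) {
    stop("training data must contain at least one item of each class")
  }
  va <- if (!is.null(val)) dataset_to_xcols(val, geom, spec$class_labels)
  par <- cnn_init(sub_seed(spec$seed, 11L))
  fit <- cnn_train(par, tr$xcols, tr$y, spec,
                   val_xcols = va$xcols, val_y = va$y)
  structure(
    list(par = fit$par, spec = spec, history = fit$history,
         classes = spec$class_labels),
    class = "aef_classifier"
  )
}

#' @export
print.aef_classifier <- function(x, ...) {
  cat(sprintf("<aef_classifier> %s backbone, classes %s/%s, %d epoch(s)\n",
              x$spec$backbone, x$classes[1], x$classes[2],
              nrow(x$history)))
  if (nrow(x$history)) {
    cat(sprintf("final loss %.4f, validation accuracy %s\n",
                tail(x$history$loss, 1),
                format(tail(x$history$val_accuracy, 1))))
  }
  invisible(x)
}

#' Classify one topographic image
#'
#' Deterministic inference (no dropout): returns the argmax class and both
#' class probabilities (softmax outputs summing to 1).
#'
#' @param model an [train_classifier()] result.
#' @param image a [render_topomap()] object or a `224 x 224 x 3` array.
#' @return list with `label` and named `probabilities`.
#' @export
classify <- function(model, image) {
  stopifnot(inherits(model, "aef_classifier"))
  pix <- if (inherits(image, "topo_image")) image$pixels else image
  geom <- cnn_geometry()
  fwd <- cnn_forward(model$par, cnn_features(pix, geom), geom)
  probs <- as.numeric(fwd$probs)
  names(probs) <- model$classes
  list(label = model$classes[which.max(probs)], probabilities = probs)
}

#' Evaluate the classifier on a labelled set
#'
#' @param model an [train_classifier()] result.
#' @param dataset manifest `data.frame` or `list(images =, labels =)`.
#' @return list with `accuracy`, 2 x 2 `confusion` (rows = truth,
#'   columns = prediction) and `n`.
#' @export
evaluate_classifier <- function(model, dataset) {
  stopifnot(inherits(model, "aef_classifier"))
  geom <- cnn_geometry()
  ds <- dataset_to_xcols(dataset, geom, model$classes)
  if (!length(ds$y)) stop("empty evaluation set")
  pred <- vapply(ds$xcols, function(xc) {
    which.max(cnn_forward(model$par, xc, geom)$probs)
  }, integer(1))
  confusion <- table(
    truth = factor(model$classes[ds$y], levels = model$classes),
    prediction = factor(model$classes[pred], levels = model$classes)
  )
  list(accuracy = mean(pred == ds$y),
       confusion = unclass(confusion),
       n = length(ds$y))
}

#' Save and load a trained classifier
#'
#' The checkpoint embeds the full [classifier_spec()] alongside the fitted
#' parameters and training history.
#'
#' @param model an `aef_classifier`.
#' @param path file path.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "aef_classifier"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  structure(readRDS(path), class = "aef_classifier")
}
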