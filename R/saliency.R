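# Score-CAM saliency maps and the projection-direction ablation.

#' Score-CAM saliency map
#'
#' Gradient-free attribution: for every filter of the designated encoder
#' activation layer (an 8x8 map by default), the activation is upsampled
#' to the input resolution, min-max normalized to `[0, 1]`, multiplied
#' elementwise with the input to form a masked image, and the masked image
#' is re-input to the model; the predicted probability of the target class
#' weights that normalized map in the final sum over filters. Filters with
#' constant activation contribute zero (with a warning).
#'
#' @param model trained [morphovae_model()].
#' @param triplet a [projection_triplet()] or `(H, W, 3)` array.
#' @param target_class class index (or label string); defaults to the
#'   model's predicted class for the input.
#' @param layer encoder layer index supplying the activation maps
#'   (default `config$scorecam_layer`).
#' @return object of class `saliency_map`: spatial `map` (H x W, >= 0),
#'   per-channel maps (`map` times each input channel), the filter
#'   weights, and the explained class.
#' @export
score_cam <- function(model, triplet, target_class = NULL, layer = NULL) {
  cfg <- model$config
  x <- as_batch_array(triplet, cfg)
  layer <- layer %||% cfg$scorecam_layer
  fw <- encoder_only_forward(model, x, keep_acts = TRUE)
  if (is.null(target_class)) {
    target_class <- which.max(classify(model, drop(fw$mu)))
  } else if (is.character(target_class)) {
    target_class <- match(target_class, model$label_levels)
  }
  A <- fw$acts[[layer]] # (Hs, Ws, F, 1)
  nf <- dim(A)[3]
  H <- cfg$img_size

  norm_maps <- array(0, c(H, H, nf))
  valid <- logical(nf)
  for (k in seq_len(nf)) {
    up <- bilinear_resize(A[, , k, 1], H, H)
    rng <- max(up) - min(up)
    if (rng < 1e-12) next
    norm_maps[, , k] <- (up - min(up)) / rng
    valid[k] <- TRUE
  }
  if (!all(valid)) {
    warning(sum(!valid), " constant activation map(s) contribute zero")
  }
  weights <- numeric(nf)
  map <- matrix(0, H, H)
  if (any(valid)) {
    vk <- which(valid)
    masked <- array(0, c(H, H, cfg$in_channels, length(vk)))
    for (m in seq_along(vk)) {
      masked[, , , m] <- x[, , , 1] * array(norm_maps[, , vk[m]], c(H, H, cfg$in_channels))
    }
    z <- encode_batch(model, masked)$mu
    probs <- classify(model, z)
    if (is.null(dim(probs))) probs <- matrix(probs, ncol = 1)
    weights[vk] <- probs[target_class, ]
    for (m in seq_along(vk)) {
      map <- map + weights[vk[m]] * norm_maps[, , vk[m]]
    }
  }
  channel_maps <- array(0, dim(x)[1:3])
  for (c in seq_len(cfg$in_channels)) {
    channel_maps[, , c] <- map * x[, , c, 1]
  }
  structure(
    list(
      map = map, channel_maps = channel_maps, target_class = target_class,
      n_filters = nf, weights = weights
    ),
    class = "saliency_map"
  )
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf(
    "<saliency_map> class %s, %d filters, total mass %.3f\n",
    x$target_class, x$n_filters, sum(x$map)
  ))
  invisible(x)
}

#' Mean per-class Score-CAM maps
#'
#' Averages per-sample saliency maps (each explained at its true label)
#' within each class.
#'
#' @param model trained model.
#' @param x4 images `(H, W, 3, N)` (or a `morphovae_dataset`).
#' @param labels true labels.
#' @return named list of H x W matrices, one per class level.
#' @export
score_cam_class_maps <- function(model, x4, labels = NULL) {
  if (inherits(x4, "morphovae_dataset")) {
    labels <- labels %||% x4$labels
    x4 <- x4$triplets
  }
  labels <- factor(labels)
  out <- list()
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    acc <- 0
    for (i in idx) {
      sm <- score_cam(model, x4[, , , i, drop = FALSE],
        target_class = match(lv, levels(labels))
      )
      acc <- acc + sm$map
    }
    out[[lv]] <- acc / length(idx)
  }
  out
}

#' Classification accuracy with blanked projection directions
#'
#' Replaces the channels *not* in `kept` by all-zero images and measures
#' classification accuracy, quantifying how much each projection direction
#' contributes.
#'
#' @param model trained model.
#' @param x4 images `(H, W, 3, N)` or a `morphovae_dataset`.
#' @param labels true labels.
#' @param kept non-empty subset of `c("x", "y", "z")`.
#' @return accuracy in `[0, 1]`.
#' @export
direction_ablation <- function(model, x4, labels = NULL, kept = c("x", "y", "z")) {
  if (inherits(x4, "morphovae_dataset")) {
    labels <- labels %||% x4$labels
    x4 <- x4$triplets
  }
  if (!length(kept)) stop("kept directions must be non-empty")
  kept <- match.arg(kept, c("x", "y", "z"), several.ok = TRUE)
  drop_ch <- setdiff(1:3, match(kept, c("x", "y", "z")))
  if (length(drop_ch)) x4[, , drop_ch, ] <- 0
  model_accuracy(model, x4, labels)
}

#' Direction-ablation table over all non-empty channel subsets
#'
#' @inheritParams direction_ablation
#' @return data frame with `kept` (e.g. `"xy"`) and `accuracy`, ordered by
#'   subset size.
#' @export
direction_ablation_table <- function(model, x4, labels = NULL) {
  if (inherits(x4, "morphovae_dataset")) {
    labels <- labels %||% x4$labels
    x4 <- x4$triplets
  }
  subsets <- list(
    "x", "y", "z", c("x", "y"), c("x", "z"), c("y", "z"),
    c("x", "y", "z")
  )
  data.frame(
    kept = vapply(subsets, paste, "", collapse = ""),
    accuracy = vapply(
      subsets,
      function(s) direction_ablation(model, x4, labels, kept = s), 0
    )
  )
}
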