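# The missing-segment experiment: crop half-specimen volumes at stated
# crop rates, re-project them onto the unchanged canvas, reconstruct
# through the trained model, and trace loss/accuracy versus crop rate.

#' Crop specification
#'
#' `crop_rate` is the fraction of the object's *occupied* extent removed
#' along the axis (not a fraction of the canvas). Vertical crops remove a
#' slab from the base/teeth side (-z) upward; horizontal crops remove from
#' the anterior tip (+y) backward.
#'
#' @param axis `"vertical"` (z) or `"horizontal"` (y).
#' @param crop_rate fraction in `[0, 1)`.
#' @return object of class `crop_spec`.
#' @export
crop_spec <- function(axis = c("vertical", "horizontal"), crop_rate) {
  axis <- match.arg(axis)
  stopifnot(crop_rate >= 0, crop_rate < 1)
  structure(list(axis = axis, crop_rate = crop_rate), class = "crop_spec")
}

#' Remove a slab from a half specimen
#'
#' Voxels inside the removed slab are set empty; the slab thickness is
#' `round(crop_rate * occupied_extent)` along the crop axis. Re-cropping
#' with an identical specification is a no-op (the original extent and
#' anchor are remembered), and projections of the cropped half are meant
#' to be regenerated through [rasterize_with_transform()] so the canvas
#' geometry stays that of the uncropped parent.
#'
#' @param half a [half_specimen()].
#' @param spec a [crop_spec()].
#' @return the cropped [half_specimen()].
#' @export
crop_volume <- function(half, spec) {
  stopifnot(inherits(spec, "crop_spec"))
  occ <- half$occupancy
  if (!any(occ)) stop("empty half specimen")
  dim_i <- if (spec$axis == "vertical") 1L else 2L # z rows / y cols

  prev <- half$crop_history
  if (!is.null(prev) && prev$axis == spec$axis) {
    ext <- prev$extent
    anchor <- prev$anchor
  } else {
    idx <- which(occ, arr.ind = TRUE)[, dim_i]
    ext <- max(idx) - min(idx) + 1
    anchor <- if (spec$axis == "vertical") min(idx) else max(idx)
  }
  th <- round(spec$crop_rate * ext)
  if (th >= ext) stop("crop removes the entire occupied extent")
  if (th > 0) {
    if (spec$axis == "vertical") {
      occ[anchor:(anchor + th - 1), , ] <- FALSE
    } else {
      occ[, (anchor - th + 1):anchor, ] <- FALSE
    }
    if (!any(occ)) stop("crop removed all voxels")
  }
  out <- half
  out$occupancy <- occ
  out$crop_history <- list(axis = spec$axis, extent = ext, anchor = anchor,
                           crop_rate = spec$crop_rate)
  out
}

#' Reconstruction loss / accuracy versus crop rate
#'
#' For every rate, each half specimen is cropped, re-projected with its
#' stored canvas transform, reconstructed through the model, scored by the
#' binary cross-entropy against its *original* (uncropped) triplet, and
#' classified (by default the reconstruction is re-input for
#' classification, as in the reconstruction-quality analysis). Rate 0
#' reproduces the uncropped baseline exactly.
#'
#' @param model trained [morphovae_model()].
#' @param dataset a `morphovae_dataset` built with `keep_volumes = TRUE`.
#' @param axis `"vertical"` or `"horizontal"`.
#' @param rates ascending crop rates starting at 0.
#' @param classify_on `"reconstruction"` (re-input the reconstruction) or
#'   `"input"` (classify the cropped input's latent directly).
#' @param indices optional subset of half indices (e.g. the test halves).
#' @return data frame `rate`, `mean_loss`, `sd_loss`, `accuracy`, `n`;
#'   skipped samples (per-sample failures) are recorded in attribute
#'   `"skipped"`.
#' @export
crop_response_curve <- function(model, dataset, axis = "vertical",
                                rates = seq(0, 0.8, 0.1),
                                classify_on = c("reconstruction", "input"),
                                indices = NULL) {
  classify_on <- match.arg(classify_on)
  stopifnot(!is.unsorted(rates), rates[1] == 0)
  indices <- indices %||% seq_along(dataset$halves)
  cfg <- model$config
  levels_ <- model$label_levels
  n <- length(indices)
  skipped <- list()
  rows <- vector("list", length(rates))

  for (ri in seq_along(rates)) {
    rate <- rates[ri]
    xs <- array(0, c(cfg$img_size, cfg$img_size, cfg$in_channels, n))
    ok <- logical(n)
    for (m in seq_len(n)) {
      i <- indices[m]
      rec <- dataset$halves[[i]]
      res <- try(
        {
          if (rate == 0) {
            dataset$triplets[, , , i]
          } else {
            ch <- crop_volume(rec$half, crop_spec(axis, rate))
            raw <- project_volume(ch)
            as_input_array(rasterize_with_transform(
              raw, rec$triplet$transform,
              canvas = cfg$img_size
            ))
          }
        },
        silent = TRUE
      )
      if (inherits(res, "try-error")) {
        skipped[[length(skipped) + 1]] <- list(index = i, rate = rate,
                                               message = as.character(res))
        next
      }
      xs[, , , m] <- res
      ok[m] <- TRUE
    }
    xs <- xs[, , , ok, drop = FALSE]
    labs <- as.character(dataset$labels[indices[ok]])
    orig <- dataset$triplets[, , , indices[ok], drop = FALSE]
    z <- encode_batch(model, xs)$mu
    recon <- decode_batch(model, z)
    nn <- sum(ok)
    losses <- vapply(seq_len(nn), function(m) {
      compute_losses(orig[, , , m], recon[, , , m], alpha = 0)$e_rec
    }, 0)
    if (classify_on == "reconstruction") {
      z_cls <- encode_batch(model, recon)$mu
    } else {
      z_cls <- z
    }
    pred <- levels_[max.col(t(classify(model, z_cls)))]
    rows[[ri]] <- data.frame(
      rate = rate, mean_loss = mean(losses), sd_loss = sd(losses),
      accuracy = mean(pred == labs), n = nn
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}
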