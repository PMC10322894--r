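# Preprocessing: canonical orientation, sagittal split + mirroring,
# silhouette projection, and size-normalized rasterization to the
# 128 x 128 canvas the network consumes.

#' Half specimen
#'
#' One side of a sagittally split volume. Exactly two halves are produced
#' per specimen and exactly one of them is mirror-inverted so both present
#' the same chirality; both carry the parent specimen id, which the
#' split-leakage rule in [make_splits()] relies on.
#'
#' @param occupancy logical `(z, y, x)` array.
#' @param side `"left"` or `"right"`.
#' @param mirrored logical.
#' @param parent_id parent specimen id.
#' @param landmarks landmarks in the half's own (x, y, z) frame.
#' @return object of class `half_specimen`.
#' @export
half_specimen <- function(occupancy, side, mirrored, parent_id, landmarks = NULL) {
  structure(
    list(
      occupancy = occupancy != 0, side = side, mirrored = isTRUE(mirrored),
      parent_id = parent_id, landmarks = landmarks
    ),
    class = "half_specimen"
  )
}

#' Projection triplet
#'
#' Three 128x128 binary images: the x-projection (onto the yz plane, the
#' lateral silhouette), y-projection (onto xz) and z-projection (onto xy).
#' Images are stored row = vertical axis of the source volume (z for the
#' x/y projections, y for the z projection), column = the remaining axis.
#'
#' @param x_proj,y_proj,z_proj binary matrices (values 0/1).
#' @param reference_length_px pixel length the landmark segment was
#'   normalized to.
#' @param parent_id,side provenance.
#' @param transform per-image rasterization transforms (kept so cropped
#'   volumes can be re-projected onto the identical canvas).
#' @return object of class `projection_triplet`.
#' @export
projection_triplet <- function(x_proj, y_proj, z_proj, reference_length_px,
                               parent_id = NA_character_, side = NA_character_,
                               transform = NULL) {
  for (img in list(x_proj, y_proj, z_proj)) {
    stopifnot(all(img %in% c(0, 1)))
  }
  structure(
    list(
      x_proj = x_proj, y_proj = y_proj, z_proj = z_proj,
      reference_length_px = reference_length_px,
      parent_id = parent_id, side = side, transform = transform
    ),
    class = "projection_triplet"
  )
}

#' Stack a projection triplet into the network input array
#'
#' @param triplet a [projection_triplet()] (or a plain list with the three
#'   images).
#' @return numeric array `(H, W, 3)`, channels ordered x, y, z.
#' @export
as_input_array <- function(triplet) {
  h <- nrow(triplet$x_proj)
  out <- array(0, c(h, ncol(triplet$x_proj), 3))
  out[, , 1] <- triplet$x_proj
  out[, , 2] <- triplet$y_proj
  out[, , 3] <- triplet$z_proj
  out
}

rotation_from_landmarks <- function(condyle_left, condyle_right, tip) {
  m <- (condyle_left + condyle_right) / 2
  d <- tip - m
  nd <- sqrt(sum(d^2))
  if (nd < 1e-8) {
    stop("invalid landmarks: condyle midpoint coincides with the tip")
  }
  yax <- d / nd
  u <- condyle_right - condyle_left
  u <- u - sum(u * yax) * yax
  nu <- sqrt(sum(u^2))
  if (nu < 1e-8) {
    stop("invalid landmarks: condyle axis parallel to the tip direction")
  }
  xax <- u / nu
  zax <- c(
    xax[2] * yax[3] - xax[3] * yax[2],
    xax[3] * yax[1] - xax[1] * yax[3],
    xax[1] * yax[2] - xax[2] * yax[1]
  )
  rbind(xax, yax, zax) # world -> canonical
}

trilinear_occ <- function(occ, x, y, z) {
  # occ is (z,y,x); physical (x,y,z) -> array index (z+1, y+1, x+1)
  d <- dim(occ)
  i <- z + 1
  j <- y + 1
  k <- x + 1
  i0 <- floor(i); j0 <- floor(j); k0 <- floor(k)
  fi <- i - i0; fj <- j - j0; fk <- k - k0
  val <- function(ii, jj, kk) {
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    out <- numeric(length(ii))
    if (any(ok)) out[ok] <- occ[cbind(ii[ok], jj[ok], kk[ok])]
    out
  }
  (1 - fi) * (1 - fj) * (1 - fk) * val(i0, j0, k0) +
    fi * (1 - fj) * (1 - fk) * val(i0 + 1, j0, k0) +
    (1 - fi) * fj * (1 - fk) * val(i0, j0 + 1, k0) +
    (1 - fi) * (1 - fj) * fk * val(i0, j0, k0 + 1) +
    fi * fj * (1 - fk) * val(i0 + 1, j0 + 1, k0) +
    fi * (1 - fj) * fk * val(i0 + 1, j0, k0 + 1) +
    (1 - fi) * fj * fk * val(i0, j0 + 1, k0 + 1) +
    fi * fj * fk * val(i0 + 1, j0 + 1, k0 + 1)
}

#' Rotate a volume into the canonical anatomical pose
#'
#' Rigidly rotates the volume so that the line from the condylar midpoint to
#' the tip is parallel to +y, the condyle-to-condyle axis is parallel to x,
#' and (for shapes following the generator's convention) the teeth-bearing
#' base faces -z. Resampling is trilinear with a 0.5 occupancy threshold; a
#' volume already in canonical pose is returned voxelwise unchanged.
#'
#' @param volume a [voxel_volume()].
#' @param condyle_points list or 2x3 matrix of the two condylar medial tips
#'   (`c(x, y, z)` each); defaults to the volume's stored landmarks.
#' @param tip_point the mandible-tip point; defaults to stored landmark.
#' @return a canonical [voxel_volume()] with transformed landmarks and
#'   `orientation_checked = TRUE`.
#' @export
canonicalize_orientation <- function(volume, condyle_points = NULL, tip_point = NULL) {
  lm <- volume$landmarks
  if (is.null(condyle_points)) {
    condyle_points <- list(lm$condyle_left, lm$condyle_right)
  }
  if (is.null(tip_point)) tip_point <- lm$tip
  if (is.null(condyle_points[[1]]) || is.null(tip_point)) {
    stop("landmarks required for orientation")
  }
  cl <- as.numeric(condyle_points[[1]])
  cr <- as.numeric(condyle_points[[2]])
  tp <- as.numeric(tip_point)
  R <- rotation_from_landmarks(cl, cr, tp)

  if (max(abs(R - diag(3))) < 1e-9) {
    out <- volume
    out$orientation_checked <- TRUE
    return(out)
  }

  m <- (cl + cr) / 2
  occ <- volume$occupancy
  pts <- occupied_coords(occ) # (x,y,z) rows
  rot <- sweep(pts, 2, m) %*% t(R)
  lo <- floor(apply(rot, 2, min)) - 1
  hi <- ceiling(apply(rot, 2, max)) + 1
  dims_xyz <- hi - lo + 1
  # output voxel (x,y,z) physical coords: lo .. hi; inverse-map to input
  gx <- seq(lo[1], hi[1])
  gy <- seq(lo[2], hi[2])
  gz <- seq(lo[3], hi[3])
  # build full grid in (z,y,x) array order: z fastest
  Z <- rep(gz, times = length(gy) * length(gx))
  Y <- rep(rep(gy, each = length(gz)), times = length(gx))
  X <- rep(gx, each = length(gz) * length(gy))
  src <- cbind(X, Y, Z) %*% R # R^T applied: p_in - m = R^T p_out
  vals <- trilinear_occ(
    occ, src[, 1] + m[1], src[, 2] + m[2],
    src[, 3] + m[3]
  )
  new_occ <- array(vals >= 0.5, dim = c(length(gz), length(gy), length(gx)))
  n0 <- sum(occ)
  n1 <- sum(new_occ)
  if (abs(n1 - n0) > 0.02 * n0) {
    warning(sprintf(
      "occupancy count changed by %.1f%% during reorientation",
      100 * abs(n1 - n0) / n0
    ))
  }
  new_lm <- lapply(volume$landmarks, function(p) {
    as.numeric(R %*% (as.numeric(p) - m)) - lo
  })
  voxel_volume(new_occ, volume$voxel_size, volume$specimen_id,
    landmarks = new_lm, orientation_checked = TRUE
  )
}

#' Split a canonical volume at the sagittal plane and mirror one half
#'
#' The volume is partitioned at the sagittal (yz) plane through the tip
#' point using 0-based half-open windows: voxels with physical `x < k0` go
#' to the left half, `x >= k0` to the right half, `k0 = round(tip_x)`. The
#' right half is mirror-inverted along x so both halves share chirality.
#'
#' @param volume canonical [voxel_volume()].
#' @param tip_point `c(x, y, z)`; defaults to the stored `tip` landmark.
#' @return list of two [half_specimen()] objects (left, right); the right
#'   one has `mirrored = TRUE`.
#' @export
split_and_mirror <- function(volume, tip_point = NULL) {
  if (is.null(tip_point)) tip_point <- volume$landmarks$tip
  occ <- volume$occupancy
  nx <- dim(occ)[3]
  k0 <- round(as.numeric(tip_point)[1])
  if (k0 < 1 || k0 > nx - 1) stop("empty half: splitting plane outside the volume")
  left <- occ[, , seq_len(k0), drop = FALSE]
  right <- occ[, , (k0 + 1):nx, drop = FALSE]
  if (!any(left) || !any(right)) stop("empty half: no occupied voxels on one side")
  right_m <- right[, , rev(seq_len(dim(right)[3])), drop = FALSE]

  adj_lm <- function(flip, nxh, offset) {
    lapply(volume$landmarks, function(p) {
      p <- as.numeric(p)
      xl <- p[1] - offset
      if (flip) xl <- (nxh - 1) - xl
      c(xl, p[2], p[3])
    })
  }
  list(
    half_specimen(left, "left", FALSE, volume$specimen_id,
      landmarks = adj_lm(FALSE, k0, 0)
    ),
    half_specimen(right_m, "right", TRUE, volume$specimen_id,
      landmarks = adj_lm(TRUE, nx - k0, k0)
    )
  )
}

#' Silhouette projections of a half specimen
#'
#' Each output pixel is 1 iff any occupied voxel lies along the
#' corresponding axis ray (binary silhouette, not a depth map). Image
#' extents equal the volume's face extents; no resizing happens here.
#'
#' @param half a [half_specimen()] (or anything with an `occupancy` array).
#' @return list with binary matrices `x_proj` (z rows, y cols), `y_proj`
#'   (z rows, x cols), `z_proj` (y rows, x cols).
#' @export
project_volume <- function(half) {
  occ <- half$occupancy
  if (!any(occ)) stop("empty half specimen")
  d <- dim(occ)
  x_proj <- matrix(rowSums(matrix(occ, d[1] * d[2], d[3])) > 0, d[1], d[2])
  occ_zxy <- aperm(occ, c(1, 3, 2))
  y_proj <- matrix(rowSums(matrix(occ_zxy, d[1] * d[3], d[2])) > 0, d[1], d[3])
  z_proj <- matrix(colSums(matrix(occ, d[1], d[2] * d[3])) > 0, d[2], d[3])
  list(x_proj = x_proj * 1, y_proj = y_proj * 1, z_proj = z_proj * 1)
}

rasterize_one <- function(img, scale, center_in, canvas) {
  c_out <- (canvas + 1) / 2
  rows_in <- center_in[1] + (seq_len(canvas) - c_out) / scale
  cols_in <- center_in[2] + (seq_len(canvas) - c_out) / scale
  (bilinear_sample(img, rows_in, cols_in, grid = TRUE) >= 0.5) * 1
}

img_bbox_center <- function(img) {
  nz <- which(img != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) stop("empty projection image")
  c(
    (min(nz[, 1]) + max(nz[, 1])) / 2,
    (min(nz[, 2]) + max(nz[, 2])) / 2
  )
}

#' Size-normalize raw projections onto the 128x128 canvas
#'
#' All three images are scaled by the single factor
#' `target_length_px / dist(landmark_a, landmark_b)` (the landmark segment
#' is the angular-process-to-tip reference the size normalization uses),
#' bilinearly interpolated, re-binarized at 0.5 and centered on the canvas
#' by the occupied bounding-box center of each image.
#'
#' @param raw list with `x_proj`, `y_proj`, `z_proj` from [project_volume()].
#' @param landmark_a,landmark_b 2-D points `c(row, col)` in the raw
#'   x-projection image (1-based).
#' @param target_length_px desired landmark distance in output pixels
#'   (must be < `canvas`).
#' @param canvas canvas size in px (default 128).
#' @param parent_id,side provenance carried into the triplet.
#' @return a [projection_triplet()]; its `transform` field records scale and
#'   centers so cropped volumes can be re-rasterized identically.
#' @export
normalize_and_rasterize <- function(raw, landmark_a, landmark_b, target_length_px,
                                    canvas = 128, parent_id = NA_character_,
                                    side = NA_character_) {
  stopifnot(target_length_px < canvas)
  d <- sqrt(sum((as.numeric(landmark_a) - as.numeric(landmark_b))^2))
  if (d < 1e-9) stop("landmark points for normalization coincide")
  scale <- target_length_px / d

  tr <- list()
  out <- list()
  for (nm in c("x_proj", "y_proj", "z_proj")) {
    img <- raw[[nm]]
    ctr <- img_bbox_center(img)
    nz <- which(img != 0, arr.ind = TRUE)
    need <- ceiling(max(
      (max(nz[, 1]) - min(nz[, 1]) + 1),
      (max(nz[, 2]) - min(nz[, 2]) + 1)
    ) * scale)
    if (need > canvas) {
      stop(sprintf(
        "scaled shape exceeds the %dpx canvas: requires at least %dpx",
        canvas, need
      ))
    }
    out[[nm]] <- rasterize_one(img, scale, ctr, canvas)
    tr[[nm]] <- list(scale = scale, center_in = ctr)
  }
  projection_triplet(out$x_proj, out$y_proj, out$z_proj,
    reference_length_px = target_length_px,
    parent_id = parent_id, side = side, transform = tr
  )
}

#' Re-rasterize raw projections with a stored transform
#'
#' Used by the occlusion experiment: a cropped volume is re-projected onto
#' the identical canvas with the identical scale and centering as its
#' uncropped parent, so the crop is not hidden by re-normalization.
#'
#' @param raw list of raw projection images.
#' @param transform the `transform` field of the original
#'   [projection_triplet()].
#' @param canvas canvas size.
#' @inheritParams normalize_and_rasterize
#' @return a [projection_triplet()].
#' @export
rasterize_with_transform <- function(raw, transform, canvas = 128,
                                     reference_length_px = NA,
                                     parent_id = NA_character_,
                                     side = NA_character_) {
  out <- list()
  for (nm in c("x_proj", "y_proj", "z_proj")) {
    tr <- transform[[nm]]
    out[[nm]] <- rasterize_one(raw[[nm]], tr$scale, tr$center_in, canvas)
  }
  projection_triplet(out$x_proj, out$y_proj, out$z_proj,
    reference_length_px = reference_length_px,
    parent_id = parent_id, side = side, transform = transform
  )
}

half_norm_landmarks <- function(half) {
  lm <- half$landmarks
  if (is.null(lm$angular) || is.null(lm$tip)) {
    stop("halves need 'angular' and 'tip' landmarks for size normalization")
  }
  # x_proj raw image coordinates: row = z + 1, col = y + 1
  list(
    a = c(lm$angular[3] + 1, lm$angular[2] + 1),
    b = c(lm$tip[3] + 1, lm$tip[2] + 1)
  )
}

#' Preprocess one specimen volume into two projection triplets
#'
#' Runs the full path: canonical orientation, sagittal split + mirror,
#' silhouette projection and size-normalized rasterization.
#'
#' @param volume a [voxel_volume()] with landmarks.
#' @param target_length_px normalized landmark length in px (default 88).
#' @param canvas canvas size (default 128).
#' @return list of two entries, each `list(half, triplet)`.
#' @export
preprocess_specimen <- function(volume, target_length_px = 88, canvas = 128) {
  vol <- canonicalize_orientation(volume)
  halves <- split_and_mirror(vol)
  lapply(halves, function(h) {
    raw <- project_volume(h)
    lm <- half_norm_landmarks(h)
    tri <- normalize_and_rasterize(raw, lm$a, lm$b, target_length_px,
      canvas = canvas, parent_id = h$parent_id, side = h$side
    )
    list(half = h, triplet = tri)
  })
}

#' Preprocess a labelled set of volumes into a model-ready dataset
#'
#' @param volumes named list of [voxel_volume()] objects (names =
#'   specimen ids) or a vector of paths readable by [read_voxel_volume()].
#' @param manifest data frame with columns `specimen_id` and `label`.
#' @param target_length_px,canvas see [preprocess_specimen()].
#' @param keep_volumes keep the half-specimen volumes inside the dataset
#'   (required by the occlusion experiment; default `TRUE`).
#' @return object of class `morphovae_dataset`: input array
#'   `triplets (canvas, canvas, 3, 2n)`, `labels` factor, `parent_id`,
#'   `side`, and the per-half records in `halves`.
#' @export
preprocess_dataset <- function(volumes, manifest, target_length_px = 88,
                               canvas = 128, keep_volumes = TRUE) {
  if (is.character(volumes)) {
    volumes <- lapply(volumes, read_voxel_volume)
    names(volumes) <- vapply(volumes, function(v) v$specimen_id, "")
  }
  ids <- manifest$specimen_id
  stopifnot(all(ids %in% names(volumes)))
  n <- length(ids)
  x <- array(0, c(canvas, canvas, 3, 2 * n))
  labels <- character(2 * n)
  parent_id <- character(2 * n)
  side <- character(2 * n)
  halves <- vector("list", 2 * n)
  k <- 0
  for (i in seq_len(n)) {
    pp <- preprocess_specimen(volumes[[ids[i]]], target_length_px, canvas)
    for (entry in pp) {
      k <- k + 1
      x[, , , k] <- as_input_array(entry$triplet)
      labels[k] <- as.character(manifest$label[i])
      parent_id[k] <- entry$half$parent_id
      side[k] <- entry$half$side
      if (!keep_volumes) entry$half$occupancy <- NULL
      halves[[k]] <- entry
    }
  }
  structure(
    list(
      triplets = x, labels = factor(labels), parent_id = parent_id,
      side = side, halves = halves, target_length_px = target_length_px,
      canvas = canvas
    ),
    class = "morphovae_dataset"
  )
}

#' @export
print.morphovae_dataset <- function(x, ...) {
  cat(sprintf(
    "<morphovae_dataset> %d half-specimens (%d specimens), %d classes, %dpx canvas\n",
    dim(x$triplets)[4], length(unique(x$parent_id)), nlevels(x$labels), x$canvas
  ))
  print(table(x$labels))
  invisible(x)
}
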