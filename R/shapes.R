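# Synthetic mandible-like shapes: a body ellipsoid plus rod-like
# "processes" (stand-ins for the coronoid, condylar and angular processes)
# whose angles/lengths are drawn from class-specific distributions, so that
# silhouette projections separate by class the way family silhouettes do.
# A special "quadrant" preset confines all class-informative structure to
# one region of one projection, for the saliency/ablation fixtures.

#' Shape class parameters
#'
#' Describes one synthetic class: body ellipsoid semi-axes, the three
#' processes (length, radius, elevation angle in the sagittal yz plane,
#' with within-class standard deviations) and the global size-jitter range
#' (default 0.5-2.5x, emulating the roughly five-fold size spread of real
#' specimens).
#'
#' @param class_id integer id.
#' @param label class label string.
#' @param body semi-axes `c(ax, ay, az)` in voxels at size factor 1.
#' @param processes named list (`condylar`, `coronoid`, `angular`), each
#'   `list(length, radius, angle, angle_sd, length_sd)`; angles in degrees
#'   above (+) or below (-) the -y direction.
#' @param size_jitter `c(min, max)` multiplicative size factor range.
#' @param pattern optional quadrant-pattern description (see
#'   [shape_presets()]); when present the shape is body + connector +
#'   extruded pattern instead of body + processes.
#' @return object of class `shape_class_params`.
#' @export
shape_class_params <- function(class_id, label = paste0("class_", class_id),
                               body = c(4, 6.5, 2.8),
                               processes = list(
                                 condylar = list(
                                   length = 5.5, radius = 1.2, angle = 45,
                                   angle_sd = 3, length_sd = 0.05
                                 ),
                                 coronoid = list(
                                   length = 4.5, radius = 1.0, angle = 78,
                                   angle_sd = 2, length_sd = 0.05
                                 ),
                                 angular = list(
                                   length = 3.5, radius = 1.1, angle = -15,
                                   angle_sd = 2, length_sd = 0.05
                                 )
                               ),
                               size_jitter = c(0.5, 2.5),
                               pattern = NULL) {
  stopifnot(length(body) == 3, all(body > 0), size_jitter[1] > 0,
            size_jitter[2] >= size_jitter[1])
  if (is.null(pattern)) {
    for (p in processes) stopifnot(p$length > 0, p$radius > 0)
  }
  structure(
    list(
      class_id = class_id, label = label, body = body,
      processes = processes, size_jitter = size_jitter, pattern = pattern
    ),
    class = "shape_class_params"
  )
}

#' Preset class-parameter sets
#'
#' `"separable"`: classes differ in condylar-process elevation angle
#' (means spread over 25-70 degrees, within-class sd 3 degrees, i.e. > 3 sd
#' apart) and coronoid length. `"hard"`: overlapping angle distributions
#' (means 40-50, sd 4). `"quadrant"`: identical bodies; the only
#' class-informative structure is a bar pattern (rising diagonal / falling
#' diagonal / cross) extruded along x inside one yz-plane box, so only the
#' x projection - and only one image quadrant - carries label information.
#'
#' @param preset one of `"separable"`, `"hard"`, `"quadrant"`.
#' @param n_classes number of classes (2-3 for `"quadrant"`).
#' @return list of [shape_class_params()].
#' @export
shape_presets <- function(preset = c("separable", "hard", "quadrant"),
                          n_classes = 3) {
  preset <- match.arg(preset)
  if (preset == "quadrant") {
    kinds <- rep(c("diag_up", "diag_down", "cross"), length.out = n_classes)
    return(lapply(seq_len(n_classes), function(i) {
      shape_class_params(
        class_id = i,
        body = c(2.5, 3.5, 2),
        processes = list(),
        size_jitter = c(0.95, 1.05),
        # the body-to-box gap must exceed the box length, otherwise the
        # scaled box straddles the canvas-quadrant boundary
        pattern = list(
          kind = kinds[i], y_off = 14, z_off = 16, len = 14,
          x_half = 7, thickness = 4, connector_radius = 1.0
        )
      )
    }))
  }
  if (preset == "separable") {
    angles <- seq(25, 70, length.out = n_classes)
    # keep class means > 3 within-class sd apart for any class count
    angle_sd <- min(3, (angles[2] - angles[1]) / 3.5)
    cor_len <- seq(3.8, 5.6, length.out = n_classes)
  } else {
    angles <- seq(40, 50, length.out = n_classes)
    angle_sd <- 4
    cor_len <- rep(4.5, n_classes)
  }
  if (n_classes > 1 && preset == "separable") {
    stopifnot(min(diff(angles)) > 3 * angle_sd)
  }
  lapply(seq_len(n_classes), function(i) {
    shape_class_params(
      class_id = i,
      processes = list(
        condylar = list(
          length = 5.5, radius = 1.2, angle = angles[i],
          angle_sd = angle_sd, length_sd = 0.05
        ),
        coronoid = list(
          length = cor_len[i], radius = 1.0, angle = 78,
          angle_sd = 2, length_sd = 0.05
        ),
        angular = list(
          length = 3.5, radius = 1.1, angle = -15,
          angle_sd = 2, length_sd = 0.05
        )
      )
    )
  })
}

# --- voxelization helpers (construction frame, physical x/y/z coords) ----

# occupancy tests get three coordinate arrays Xc, Yc, Zc of identical dim
ellipsoid_mask <- function(Xc, Yc, Zc, center, semi) {
  ((Xc - center[1]) / semi[1])^2 + ((Yc - center[2]) / semi[2])^2 +
    ((Zc - center[3]) / semi[3])^2 <= 1
}

capsule_mask <- function(Xc, Yc, Zc, p0, p1, r) {
  d <- p1 - p0
  dd <- sum(d^2)
  box <- abs(Xc - (p0[1] + p1[1]) / 2) <= abs(d[1]) / 2 + r + 1 &
    abs(Yc - (p0[2] + p1[2]) / 2) <= abs(d[2]) / 2 + r + 1 &
    abs(Zc - (p0[3] + p1[3]) / 2) <= abs(d[3]) / 2 + r + 1
  idx <- which(box)
  out <- array(FALSE, dim(Xc))
  if (!length(idx)) return(out)
  px <- Xc[idx] - p0[1]
  py <- Yc[idx] - p0[2]
  pz <- Zc[idx] - p0[3]
  t <- pmin(pmax((px * d[1] + py * d[2] + pz * d[3]) / dd, 0), 1)
  dist2 <- (px - t * d[1])^2 + (py - t * d[2])^2 + (pz - t * d[3])^2
  out[idx] <- dist2 <= r^2
  out
}

# build one shape; returns list(occ, landmarks) on a cropped grid
build_shape <- function(params, seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  s <- runif(1, params$size_jitter[1], params$size_jitter[2])
  # generous temporary grid; cropped to the occupied bounding box below
  dims <- c(80, 96, 64) # (nz, ny, nx)
  ctr <- c(x = 30, y = 40, z = 32) # body center anchor in the temp grid

  if (!is.null(params$pattern)) {
    res <- build_quadrant_shape(params, s, dims, ctr)
  } else {
    res <- build_process_shape(params, s, dims, ctr)
  }
  occ <- res$occ
  lm <- res$landmarks

  w <- which(occ, arr.ind = TRUE)
  rz <- range(w[, 1]); ry <- range(w[, 2]); rx <- range(w[, 3])
  pad <- 2
  zi <- max(1, rz[1] - pad):min(dims[1], rz[2] + pad)
  yi <- max(1, ry[1] - pad):min(dims[2], ry[2] + pad)
  xi <- max(1, rx[1] - pad):min(dims[3], rx[2] + pad)
  occ <- occ[zi, yi, xi, drop = FALSE]
  off <- c(xi[1] - 1, yi[1] - 1, zi[1] - 1) # physical offset (x,y,z)
  lm <- lapply(lm, function(p) p - off)
  list(occ = occ, landmarks = lm, size_factor = s)
}

build_process_shape <- function(params, s, dims, ctr) {
  b <- params$body * s
  pr <- params$processes
  draw <- function(p) {
    list(
      length = max(0.5, rnorm(1, p$length, p$length * p$length_sd)) * s,
      radius = max(0.8, p$radius * s),
      angle = rnorm(1, p$angle, p$angle_sd) * pi / 180
    )
  }
  dc <- draw(pr$condylar)
  dk <- draw(pr$coronoid)
  da <- draw(pr$angular)

  cx <- unname(ctr["x"]); cy <- unname(ctr["y"]); cz <- unname(ctr["z"])
  xoff <- 0.6 * b[1]
  anchor <- function(fy, fz) c(0, cy + fy * b[2], cz + fz * b[3])
  rod_end <- function(a0, d) a0 + c(0, -cos(d$angle), sin(d$angle)) * d$length
  a_con <- anchor(-0.70, 0.2); e_con <- rod_end(a_con, dc)
  a_cor <- anchor(-0.45, 0.2); e_cor <- rod_end(a_cor, dk)
  a_ang <- anchor(-0.75, -0.1); e_ang <- rod_end(a_ang, da)

  # canonical-pose alignment: rotate (about x, around the condyle midpoint)
  # so the condyle-midpoint -> tip line is parallel to +y
  tip_c <- c(0, cy + b[2], cz)
  m_c <- e_con # midpoint of the two mirrored condyle endpoints has x = 0
  d <- tip_c - m_c
  th <- -atan2(d[3], d[2])
  co <- cos(th); si <- sin(th)
  # grid coords -> construction frame (inverse rotation about m_out = m_c')
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  m_out <- c(0, cy - 8, cz) # where the condyle midpoint lands (y,z part)
  yg <- matrix(rep(0:(ny - 1), each = nz), nz, ny) - m_out[2]
  zg <- matrix(rep(0:(nz - 1), ny), nz, ny) - m_out[3]
  Yc2 <- co * yg + si * zg + m_c[2]
  Zc2 <- -si * yg + co * zg + m_c[3]
  Xc <- array(rep(0:(nx - 1), each = nz * ny), c(nz, ny, nx)) - cx
  Yc <- array(rep(Yc2, nx), c(nz, ny, nx))
  Zc <- array(rep(Zc2, nx), c(nz, ny, nx))

  occ <- ellipsoid_mask(Xc, Yc, Zc, c(0, cy, cz), b)
  for (side in c(-1, 1)) {
    sideways <- function(p) c(side * xoff, p[2], p[3])
    occ <- occ | capsule_mask(Xc, Yc, Zc, sideways(a_con), sideways(e_con), dc$radius)
    occ <- occ | capsule_mask(Xc, Yc, Zc, sideways(a_cor), sideways(e_cor), dk$radius)
    occ <- occ | capsule_mask(Xc, Yc, Zc, sideways(a_ang), sideways(e_ang), da$radius)
  }

  # landmarks in the output (rotated) frame
  rot_out <- function(p) {
    dy <- p[2] - m_c[2]; dz <- p[3] - m_c[3]
    c(p[1] + cx, co * dy - si * dz + m_out[2], si * dy + co * dz + m_out[3])
  }
  landmarks <- list(
    condyle_left = rot_out(c(-xoff, e_con[2], e_con[3])),
    condyle_right = rot_out(c(xoff, e_con[2], e_con[3])),
    tip = rot_out(tip_c),
    angular = rot_out(c(-xoff, e_ang[2], e_ang[3]))
  )
  list(occ = occ, landmarks = landmarks)
}

build_quadrant_shape <- function(params, s, dims, ctr) {
  b <- params$body * s
  pt <- params$pattern
  cx <- unname(ctr["x"]); cy <- unname(ctr["y"]); cz <- unname(ctr["z"])
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]

  Xc <- array(rep(0:(nx - 1), each = nz * ny), c(nz, ny, nx))
  Yc <- array(rep(rep(0:(ny - 1), each = nz), nx), c(nz, ny, nx))
  Zc <- array(rep(rep(0:(nz - 1), ny), nx), c(nz, ny, nx))

  occ <- ellipsoid_mask(Xc, Yc, Zc, c(cx, cy, cz), b)

  # pattern box in the (y, z) plane, extruded along x
  jit <- rnorm(2, 0, 0.5) * s
  y0 <- cy + pt$y_off * s + jit[1]
  z0 <- cz + pt$z_off * s + jit[2]
  len <- pt$len * s
  th <- max(1.2, (pt$thickness + rnorm(1, 0, 0.3)) * s / 2) # half thickness
  inbox <- Yc >= y0 & Yc <= y0 + len & Zc >= z0 & Zc <= z0 + len &
    abs(Xc - cx) <= pt$x_half * s
  u <- Yc - y0
  v <- Zc - z0
  pat <- switch(pt$kind,
    diag_up = abs(v - u) <= th,
    diag_down = abs(v - (len - u)) <= th,
    cross = (abs(u - len / 2) <= th * 0.75) | (abs(v - len / 2) <= th * 0.75),
    stop("unknown pattern kind: ", pt$kind)
  )
  occ <- occ | (inbox & pat)

  # class-shared connector from the body to the pattern-box center
  p0 <- c(cx, cy + 0.6 * b[2], cz + 0.6 * b[3])
  p1 <- c(cx, y0 + len / 2, z0 + len / 2)
  occ <- occ | capsule_mask(Xc, Yc, Zc, p0, p1, max(0.8, pt$connector_radius * s))

  landmarks <- list(
    condyle_left = c(cx - 2 * s, cy - 0.5 * b[2], cz),
    condyle_right = c(cx + 2 * s, cy - 0.5 * b[2], cz),
    tip = c(cx, cy + b[2], cz),
    angular = c(cx, y0 + len, z0 + len) # far pattern corner: size reference
  )
  list(occ = occ, landmarks = landmarks)
}

# 6-connectivity check by iterative region growing on the cropped grid
is_connected6 <- function(occ) {
  w <- which(occ, arr.ind = TRUE)
  if (nrow(w) == 0) return(FALSE)
  occ <- occ[
    min(w[, 1]):max(w[, 1]), min(w[, 2]):max(w[, 2]),
    min(w[, 3]):max(w[, 3]),
    drop = FALSE
  ]
  d <- dim(occ)
  visited <- array(FALSE, d)
  first <- which(occ)[1]
  visited[first] <- TRUE
  shift <- function(a, axis, by) {
    out <- array(FALSE, d)
    if (axis == 1) {
      if (by == 1) out[2:d[1], , ] <- a[1:(d[1] - 1), , ] else out[1:(d[1] - 1), , ] <- a[2:d[1], , ]
    } else if (axis == 2) {
      if (by == 1) out[, 2:d[2], ] <- a[, 1:(d[2] - 1), ] else out[, 1:(d[2] - 1), ] <- a[, 2:d[2], ]
    } else {
      if (by == 1) out[, , 2:d[3]] <- a[, , 1:(d[3] - 1)] else out[, , 1:(d[3] - 1)] <- a[, , 2:d[3]]
    }
    out
  }
  n_prev <- 1L
  repeat {
    grown <- visited
    for (ax in 1:3) {
      grown <- grown | shift(visited, ax, 1) | shift(visited, ax, -1)
    }
    visited <- grown & occ
    n_now <- sum(visited)
    if (n_now == n_prev) break
    n_prev <- n_now
  }
  n_prev == sum(occ)
}

#' Generate one synthetic shape volume
#'
#' Draws the within-class parameters, voxelizes body + processes (or body +
#' quadrant pattern), aligns the shape to the canonical pose analytically
#' (the primitives are rotated before voxelization, so no resampling), and
#' returns the volume together with its two condylar points, tip and
#' angular-process landmarks. Deterministic for a given
#' `(params, sample_seed)`.
#'
#' @param params a [shape_class_params()].
#' @param sample_seed integer seed for this specimen.
#' @param specimen_id id string.
#' @param check verify 6-connectivity and regenerate with jittered seed on
#'   failure (at most 10 attempts).
#' @return a [voxel_volume()] with landmarks.
#' @export
generate_shape_volume <- function(params, sample_seed,
                                  specimen_id = sprintf("c%d_s%d", params$class_id, sample_seed),
                                  check = TRUE) {
  for (attempt in 1:10) {
    res <- build_shape(params, derive_seed(sample_seed, attempt - 1))
    if (!check || is_connected6(res$occ)) {
      return(voxel_volume(res$occ,
        voxel_size = 1, specimen_id = specimen_id,
        landmarks = res$landmarks
      ))
    }
  }
  stop("failed to generate a connected shape in 10 attempts")
}

#' Generate a labelled synthetic dataset
#'
#' @param class_params list of [shape_class_params()] (e.g. from
#'   [shape_presets()]); at least 2 classes.
#' @param n_per_class scalar or one count per class (imbalance supported).
#' @param seed master seed.
#' @param check_connectivity `"first"` (default: verify the first specimen
#'   of each class), `"all"`, or `"none"`.
#' @param out_dir optional directory: volumes and the manifest are written
#'   there in the plain-text formats of [write_voxel_volume()] /
#'   [write_manifest()].
#' @return list with `volumes` (named list of [voxel_volume()]) and
#'   `manifest` (data frame with ids, labels and landmark columns).
#' @export
generate_dataset <- function(class_params, n_per_class, seed,
                             check_connectivity = c("first", "all", "none"),
                             out_dir = NULL) {
  check_connectivity <- match.arg(check_connectivity)
  stopifnot(length(class_params) >= 2)
  n_cls <- length(class_params)
  if (length(n_per_class) == 1) n_per_class <- rep(n_per_class, n_cls)
  stopifnot(length(n_per_class) == n_cls, all(n_per_class >= 1))

  volumes <- list()
  rows <- list()
  for (ci in seq_len(n_cls)) {
    p <- class_params[[ci]]
    for (si in seq_len(n_per_class[ci])) {
      id <- sprintf("c%d_s%03d", p$class_id, si)
      chk <- switch(check_connectivity,
        all = TRUE, none = FALSE, first = si == 1
      )
      vol <- generate_shape_volume(p, derive_seed(seed, 1000 * ci + si),
        specimen_id = id, check = chk
      )
      volumes[[id]] <- vol
      lm <- vol$landmarks
      rows[[length(rows) + 1]] <- data.frame(
        specimen_id = id, label = p$label,
        condyle_left_x = lm$condyle_left[1], condyle_left_y = lm$condyle_left[2],
        condyle_left_z = lm$condyle_left[3],
        condyle_right_x = lm$condyle_right[1], condyle_right_y = lm$condyle_right[2],
        condyle_right_z = lm$condyle_right[3],
        tip_x = lm$tip[1], tip_y = lm$tip[2], tip_z = lm$tip[3],
        angular_x = lm$angular[1], angular_y = lm$angular[2],
        angular_z = lm$angular[3],
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest$path <- file.path(out_dir, paste0(manifest$specimen_id, ".vox.txt"))
    for (i in seq_len(nrow(manifest))) {
      write_voxel_volume(volumes[[manifest$specimen_id[i]]], manifest$path[i])
    }
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  list(volumes = volumes, manifest = manifest)
}

#' Generate and preprocess a synthetic dataset in one call
#'
#' @inheritParams generate_dataset
#' @param preset see [shape_presets()].
#' @param n_classes number of classes.
#' @param target_length_px normalization length (default 52 px: the
#'   synthetic shapes span about 2.2x the landmark segment, which then
#'   fits the 128 px canvas across the whole size-jitter range).
#' @param ... passed to [preprocess_dataset()].
#' @return a `morphovae_dataset`.
#' @export
synthetic_morphovae_dataset <- function(preset = "separable", n_classes = 3,
                                        n_per_class = 20, seed = 1,
                                        target_length_px = 52, ...) {
  gen <- generate_dataset(shape_presets(preset, n_classes), n_per_class, seed)
  preprocess_dataset(gen$volumes, gen$manifest,
    target_length_px = target_length_px, ...
  )
}
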