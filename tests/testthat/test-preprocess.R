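test_that("silhouette projections match a brute-force oracle", {
  occ <- random_volume(c(20, 20, 20), p = 0.08, seed = 3)
  half <- half_specimen(occ, "left", FALSE, "r1")
  pr <- project_volume(half)

  # independent triple-loop oracle
  d <- dim(occ)
  xp <- matrix(0, d[1], d[2])
  yp <- matrix(0, d[1], d[3])
  zp <- matrix(0, d[2], d[3])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        if (occ[i, j, k]) {
          xp[i, j] <- 1
          yp[i, k] <- 1
          zp[j, k] <- 1
        }
      }
    }
  }
  expect_identical(pr$x_proj, xp)
  expect_identical(pr$y_proj, yp)
  expect_identical(pr$z_proj, zp)
})

test_that("projection handles single voxels and full cuboids", {
  occ <- array(FALSE, c(7, 8, 9))
  occ[3, 5, 2] <- TRUE # z=2, y=4, x=1 (physical)
  pr <- project_volume(half_specimen(occ, "left", FALSE, "p"))
  expect_equal(sum(pr$x_proj), 1)
  expect_equal(which(pr$x_proj == 1, arr.ind = TRUE)[1, ], c(row = 3, col = 5))
  expect_equal(which(pr$y_proj == 1, arr.ind = TRUE)[1, ], c(row = 3, col = 2))
  expect_equal(which(pr$z_proj == 1, arr.ind = TRUE)[1, ], c(row = 5, col = 2))

  cub <- array(TRUE, c(4, 5, 6))
  pc <- project_volume(half_specimen(cub, "left", FALSE, "c"))
  expect_equal(pc$x_proj, matrix(1, 4, 5))
  expect_equal(pc$y_proj, matrix(1, 4, 6))
  expect_equal(pc$z_proj, matrix(1, 5, 6))
})

test_that("mirrored projections equal axis-flipped projections", {
  occ <- random_volume(c(12, 14, 16), p = 0.15, seed = 8)
  pr <- project_volume(half_specimen(occ, "left", FALSE, "m"))
  occ_m <- occ[, , rev(seq_len(dim(occ)[3]))]
  pm <- project_volume(half_specimen(occ_m, "right", TRUE, "m"))
  expect_identical(pm$x_proj, pr$x_proj) # projection along x is x-flip invariant
  expect_identical(pm$y_proj, pr$y_proj[, rev(seq_len(ncol(pr$y_proj)))])
  expect_identical(pm$z_proj, pr$z_proj[, rev(seq_len(ncol(pr$z_proj)))])
})

test_that("split_and_mirror partitions, mirrors, and reassembles exactly", {
  # symmetric volume: halves must be voxelwise identical after mirroring
  occ <- random_volume(c(10, 12, 5), p = 0.3, seed = 5)
  occ <- array(c(occ, occ[, , 5:1]), c(10, 12, 10)) # mirror-symmetric, nx=10
  vol <- voxel_volume(occ, specimen_id = "sym")
  hs <- split_and_mirror(vol, tip_point = c(5, 6, 5))
  expect_identical(hs[[1]]$occupancy, hs[[2]]$occupancy)
  expect_true(hs[[2]]$mirrored)
  expect_false(hs[[1]]$mirrored)
  expect_identical(hs[[1]]$parent_id, hs[[2]]$parent_id)

  # asymmetric volume: un-mirroring and concatenating reproduces the input
  occ2 <- random_volume(c(9, 11, 13), p = 0.25, seed = 6)
  occ2[1, 1, 1] <- TRUE
  occ2[9, 11, 13] <- TRUE # both sides non-empty
  vol2 <- voxel_volume(occ2, specimen_id = "asym")
  hs2 <- split_and_mirror(vol2, tip_point = c(6, 5, 4))
  right_unmirrored <- hs2[[2]]$occupancy[, , rev(seq_len(dim(hs2[[2]]$occupancy)[3]))]
  rebuilt <- array(c(hs2[[1]]$occupancy, right_unmirrored), dim(occ2))
  expect_identical(rebuilt, occ2)

  # plane outside the occupied box
  expect_error(split_and_mirror(vol2, tip_point = c(20, 5, 4)), "empty half")
})

test_that("canonicalize_orientation is the identity for canonical volumes", {
  vol <- generate_shape_volume(shape_presets("separable", 3)[[1]], 101)
  out <- canonicalize_orientation(vol)
  expect_identical(out$occupancy, vol$occupancy)
  expect_true(out$orientation_checked)
})

test_that("canonicalize_orientation undoes a known rotation (Dice >= 0.98)", {
  vol <- ellipsoid_volume()
  th <- 30 * pi / 180
  R <- rbind(
    c(cos(th), -sin(th), 0),
    c(sin(th), cos(th), 0),
    c(0, 0, 1)
  ) # rotation about z in the xy plane
  ctr <- c(32, 40, 32)

  # build the rotated volume by the test's own nearest-neighbour resampling
  d <- dim(vol$occupancy)
  idx <- which(rep(TRUE, prod(d)))
  z <- (idx - 1) %% d[1]
  y <- ((idx - 1) %/% d[1]) %% d[2]
  x <- (idx - 1) %/% (d[1] * d[2])
  src <- cbind(x - ctr[1], y - ctr[2], z - ctr[3]) %*% R # R^T applied
  sx <- round(src[, 1] + ctr[1])
  sy <- round(src[, 2] + ctr[2])
  sz <- round(src[, 3] + ctr[3])
  ok <- sx >= 0 & sx < d[3] & sy >= 0 & sy < d[2] & sz >= 0 & sz < d[1]
  rot <- array(FALSE, d)
  rot[idx[ok]] <- vol$occupancy[cbind(sz[ok] + 1, sy[ok] + 1, sx[ok] + 1)]
  rot_lm <- lapply(vol$landmarks, function(p) as.numeric(R %*% (p - ctr)) + ctr)
  vol_rot <- voxel_volume(rot, specimen_id = "rot", landmarks = rot_lm)

  back <- canonicalize_orientation(vol_rot)
  # compare shapes by aligning occupied bounding-box centers
  dice_aligned <- function(a, b) {
    ca <- which(a, arr.ind = TRUE)
    cb <- which(b, arr.ind = TRUE)
    shift <- round(colMeans(cb) - colMeans(ca))
    n_int <- 0
    for (r in seq_len(nrow(ca))) {
      p <- ca[r, ] + shift
      if (all(p >= 1) && all(p <= dim(b)) && b[p[1], p[2], p[3]]) n_int <- n_int + 1
    }
    2 * n_int / (sum(a) + sum(b))
  }
  expect_gt(dice_aligned(vol$occupancy, back$occupancy), 0.98)
})

test_that("degenerate landmarks raise an invalid-landmark error", {
  vol <- ellipsoid_volume()
  expect_error(
    canonicalize_orientation(vol,
      condyle_points = list(c(30, 40, 32), c(34, 40, 32)),
      tip_point = c(32, 40, 32)
    ),
    "invalid landmarks"
  )
})

test_that("normalize_and_rasterize scales, centers and re-binarizes", {
  vol <- ellipsoid_volume()
  raw <- project_volume(half_specimen(vol$occupancy, "left", FALSE, "n"))
  lm <- list(a = c(33, 19), b = c(33, 62)) # (row, col) in x_proj, distance 43

  tri <- normalize_and_rasterize(raw, lm$a, lm$b, target_length_px = 43)
  # scale factor 1: landmark distance preserved exactly
  tr <- tri$transform$x_proj
  expect_equal(tr$scale, 1)
  expect_true(all(tri$x_proj %in% c(0, 1)))
  # half-pixel placement offsets reclassify a thin boundary band
  expect_equal(sum(tri$x_proj), sum(raw$x_proj), tolerance = 0.05)

  # distance 2x the target: output area ~ 1/4 of input (+-10%)
  tri2 <- normalize_and_rasterize(raw, lm$a, lm$b, target_length_px = 21)
  sc <- tri2$transform$x_proj$scale
  d_out <- sqrt(sum(((lm$a - lm$b) * sc)^2))
  expect_lt(abs(d_out - 21), 1)
  expect_equal(sum(tri2$x_proj) / sum(raw$x_proj), sc^2, tolerance = 0.1)

  # overflow: shape would not fit the canvas
  expect_error(
    normalize_and_rasterize(raw, c(33, 40), c(33, 44), target_length_px = 120),
    "exceeds.*canvas"
  )
  # coincident landmarks
  expect_error(
    normalize_and_rasterize(raw, lm$a, lm$a, target_length_px = 40),
    "coincide"
  )
})

test_that("uniformly rescaled shapes map to near-identical triplets", {
  # same ellipsoid geometry at 1x and 5x; >= 95% pixel agreement after
  # size normalization (the five-fold size spread of real specimens)
  small <- ellipsoid_volume(
    dims = c(24, 30, 24), center = c(12, 15, 12),
    semi = c(4.5, 6, 3.5), id = "s"
  )
  big <- ellipsoid_volume(
    dims = c(110, 140, 110), center = c(55, 70, 55),
    semi = c(22.5, 30, 17.5), id = "b"
  )
  pps <- preprocess_specimen(small, target_length_px = 80)
  ppb <- preprocess_specimen(big, target_length_px = 80)
  for (ch in c("x_proj", "y_proj", "z_proj")) {
    agree <- mean(pps[[1]]$triplet[[ch]] == ppb[[1]]$triplet[[ch]])
    expect_gte(agree, 0.95)
  }
})

test_that("voxel volumes and manifests round-trip through the text formats", {
  vol <- generate_shape_volume(shape_presets("separable", 2)[[1]], 55)
  path <- withr::local_tempfile(fileext = ".vox.txt")
  write_voxel_volume(vol, path)
  back <- read_voxel_volume(path)
  expect_identical(back$occupancy, vol$occupancy)
  expect_identical(back$specimen_id, vol$specimen_id)
  expect_equal(back$landmarks, vol$landmarks)

  man <- data.frame(specimen_id = c("a", "b"), label = c("l1", "l2"))
  mp <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, mp)
  expect_equal(read_manifest(mp), man)
})
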