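#' Binary voxel volume
#'
#' The raw shape representation: a 3-D boolean occupancy grid in the
#' anatomical frame. Array index order is `(z, y, x)` and voxel `(i, j, k)`
#' (1-based) sits at physical coordinates `(x, y, z) = (k-1, j-1, i-1)`
#' in voxel units: all landmark coordinates in this package use that
#' physical `(x, y, z)` convention, 0-based. After
#' [canonicalize_orientation()] the teeth-bearing side faces -z and the
#' condylar-midpoint-to-tip line runs along +y.
#'
#' @param occupancy logical 3-D array, index order `(z, y, x)`.
#' @param voxel_size isotropic edge length of one voxel (arbitrary units).
#' @param specimen_id character id.
#' @param landmarks optional named list of 3-D points (`c(x, y, z)`), e.g.
#'   `condyle_left`, `condyle_right`, `tip`, `angular`.
#' @param orientation_checked logical; `TRUE` once the volume is known to be
#'   in the canonical pose.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(occupancy, voxel_size = 1, specimen_id = "specimen",
                         landmarks = NULL, orientation_checked = FALSE) {
  stopifnot(is.array(occupancy), length(dim(occupancy)) == 3)
  occupancy <- occupancy != 0
  if (!any(occupancy)) stop("occupancy contains no occupied voxel")
  structure(
    list(
      occupancy = occupancy, voxel_size = voxel_size,
      specimen_id = specimen_id, landmarks = landmarks,
      orientation_checked = isTRUE(orientation_checked)
    ),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "<voxel_volume '%s'> %d x %d x %d (z,y,x), %d occupied, voxel %.3g%s\n",
    x$specimen_id, d[1], d[2], d[3], sum(x$occupancy), x$voxel_size,
    if (x$orientation_checked) ", canonical" else ""
  ))
  invisible(x)
}

# physical (x,y,z) coordinates of every occupied voxel, rows = voxels
occupied_coords <- function(occupancy) {
  idx <- which(occupancy, arr.ind = TRUE) # (z, y, x) 1-based
  cbind(x = idx[, 3] - 1, y = idx[, 2] - 1, z = idx[, 1] - 1)
}

#' Write / read a voxel volume as plain text
#'
#' A minimal run-length-encoded text container (no binary voxel format has
#' an offline R reader in this stack). Line 1 holds a JSON header with
#' dimensions, voxel size, id and landmarks; line 2 the run-length encoding
#' of the flattened `(z, y, x)` occupancy.
#'
#' @param vol a [voxel_volume()].
#' @param path file path (`.vox.txt` suggested).
#' @return `read_voxel_volume` returns a [voxel_volume()].
#' @export
write_voxel_volume <- function(vol, path) {
  head <- jsonlite::toJSON(
    list(
      dim = dim(vol$occupancy), voxel_size = vol$voxel_size,
      specimen_id = vol$specimen_id, landmarks = vol$landmarks,
      orientation_checked = vol$orientation_checked
    ),
    auto_unbox = TRUE, digits = NA
  )
  r <- rle(as.integer(vol$occupancy))
  body <- paste(paste0(r$lengths, ":", r$values), collapse = " ")
  writeLines(c(as.character(head), body), path)
  invisible(path)
}

#' @rdname write_voxel_volume
#' @export
read_voxel_volume <- function(path) {
  lines <- readLines(path, n = 2)
  head <- jsonlite::fromJSON(lines[1])
  runs <- strsplit(strsplit(lines[2], " ", fixed = TRUE)[[1]], ":", fixed = TRUE)
  lens <- as.integer(vapply(runs, `[`, "", 1))
  vals <- as.integer(vapply(runs, `[`, "", 2))
  occ <- array(inverse.rle(structure(list(lengths = lens, values = vals),
    class = "rle"
  )) == 1L, dim = head$dim)
  lm <- head$landmarks
  if (!is.null(lm)) lm <- lapply(lm, as.numeric)
  voxel_volume(occ, head$voxel_size, head$specimen_id,
    landmarks = lm,
    orientation_checked = isTRUE(head$orientation_checked)
  )
}

#' Write / read a dataset manifest
#'
#' The manifest is a CSV with one row per specimen: `specimen_id`, `label`,
#' `path` (voxel file, optional) and landmark coordinate columns
#' `<name>_x`, `<name>_y`, `<name>_z` for `condyle_left`, `condyle_right`,
#' `tip` and `angular`.
#'
#' @param manifest data frame.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

manifest_landmarks <- function(row) {
  nm <- c("condyle_left", "condyle_right", "tip", "angular")
  out <- list()
  for (n in nm) {
    cols <- paste0(n, c("_x", "_y", "_z"))
    if (all(cols %in% names(row))) out[[n]] <- as.numeric(row[1, cols])
  }
  out
}
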