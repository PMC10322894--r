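# Small numeric helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_cols <- function(z) {
  # z: (n_classes x N) logits; column-wise softmax, numerically shifted
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

clip01 <- function(x, eps = 1e-7) {
  x[x < eps] <- eps
  x[x > 1 - eps] <- 1 - eps
  x
}

activation_fun <- function(name) {
  switch(name,
    relu = relu,
    sigmoid = sigmoid,
    tanh = tanh,
    stop("unknown activation: ", name)
  )
}

# derivative expressed through the post-activation value
activation_deriv <- function(name) {
  switch(name,
    relu = function(a) a > 0, # logical; multiplies as 0/1
    sigmoid = function(a) a * (1 - a),
    tanh = function(a) 1 - a^2,
    stop("unknown activation: ", name)
  )
}

#' Bilinear resize of a 2-D image
#'
#' Resamples `img` (numeric matrix) to `out_h` x `out_w` by bilinear
#' interpolation, aligning image corners with pixel centers. Used for
#' silhouette rescaling and for upsampling Score-CAM activation maps.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return numeric `out_h` x `out_w` matrix.
#' @export
bilinear_resize <- function(img, out_h, out_w) {
  h <- nrow(img)
  w <- ncol(img)
  # map output pixel centers to input pixel centers
  ri <- if (out_h == 1) rep(1, out_h) else (seq_len(out_h) - 1) * (h - 1) / (out_h - 1) + 1
  ci <- if (out_w == 1) rep(1, out_w) else (seq_len(out_w) - 1) * (w - 1) / (out_w - 1) + 1
  bilinear_sample(img, ri, ci, grid = TRUE)
}

# Sample img at (row, col) positions (1-based, fractional). If grid=TRUE,
# rows/cols are axis vectors and the full outer grid is sampled; otherwise
# they are parallel coordinate vectors. Out-of-range samples return 0.
bilinear_sample <- function(img, rows, cols, grid = FALSE) {
  h <- nrow(img)
  w <- ncol(img)
  nr <- nc <- NULL
  if (grid) {
    nr <- length(rows)
    nc <- length(cols)
    rows <- rep(rows, times = nc)
    cols <- rep(cols, each = nr)
  }
  r0 <- floor(rows)
  c0 <- floor(cols)
  fr <- rows - r0
  fc <- cols - c0
  val <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    out <- numeric(length(r))
    out[ok] <- img[cbind(r[ok], c[ok])]
    out
  }
  v <- (1 - fr) * (1 - fc) * val(r0, c0) +
    fr * (1 - fc) * val(r0 + 1, c0) +
    (1 - fr) * fc * val(r0, c0 + 1) +
    fr * fc * val(r0 + 1, c0 + 1)
  if (grid) matrix(v, nr, nc) else v
}

# deterministic integer sub-seed derived from a base seed (kept < 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
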