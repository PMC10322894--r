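# The Morpho-VAE network: convolutional encoder -> reparameterized latent
# -> convolutional decoder, plus a single-layer softmax classifier fed by
# the latent. All layers are implemented directly (im2col convolutions in
# src/); no deep-learning framework is used.

#' Model configuration
#'
#' Architectural and optimization settings for [morphovae_model()]. The
#' defaults reproduce the reference operating point: five stride-2
#' convolutional layers per coder (filters 128,128,32,32,64 encoding and
#' 64,32,32,128,128 decoding, 3x3 kernels), ReLU activations with a
#' logistic decoder output, a 3-dimensional latent with a standard-normal
#' prior, loss weight `alpha = 0.1`, RMSprop, and 100 epochs.
#'
#' @param n_classes number of label classes.
#' @param alpha weight of the classification loss in
#'   `E_total = (1 - alpha) * E_VAE + alpha * E_C`; in `[0, 1]`.
#' @param latent_dim latent dimensionality (>= 2; default 3).
#' @param encoder_filters,decoder_filters integer vectors, one entry per
#'   stride-2 layer.
#' @param activation hidden activation: `"relu"`, `"sigmoid"` or `"tanh"`.
#' @param decoder_activation hidden activation of the decoder (defaults to
#'   `activation`); the decoder *output* is always logistic so pixel values
#'   stay in (0, 1).
#' @param optimizer `"rmsprop"`, `"adam"` or `"sgd"`.
#' @param learning_rate optimizer step size.
#' @param batch_size minibatch size.
#' @param epochs training epochs (fixed; no early stopping).
#' @param seed integer seed from which all randomness (initialization,
#'   sampling, shuffling) is derived.
#' @param img_size input image side in px (default 128).
#' @param in_channels input channels (the three projections; default 3).
#' @param kernel_size convolution kernel side (default 3).
#' @param scorecam_layer encoder layer whose activation feeds Score-CAM;
#'   default: the deepest layer with an 8x8 output map.
#' @param clip_eps clipping bound applied to decoder outputs inside the
#'   cross-entropy (default 1e-7).
#' @param recon_loss_scale,class_loss_scale multipliers applied to the
#'   reconstruction and classification terms inside the *training*
#'   objective. The defaults (`NULL`) use the pixel count for both, i.e.
#'   the canonical sum-scale cross-entropies: reconstruction then
#'   dominates the KL (no posterior collapse) and the alpha-weighted
#'   classification term is commensurate with the VAE term, so it can
#'   shape the latent space — the regime in which the two loss components
#'   visibly trade off as alpha varies. Reported [compute_losses()]
#'   components always use the per-pixel / per-class normalizations.
#'   Setting both to 1 trains the literally normalized objective, which is
#'   KL-dominated and collapses the posterior (see the methods vignette).
#' @return object of class `morphovae_config`.
#' @export
morphovae_config <- function(n_classes,
                             alpha = 0.1,
                             latent_dim = 3,
                             encoder_filters = c(128, 128, 32, 32, 64),
                             decoder_filters = c(64, 32, 32, 128, 128),
                             activation = "relu",
                             decoder_activation = NULL,
                             optimizer = "rmsprop",
                             learning_rate = 1e-3,
                             batch_size = 32,
                             epochs = 100,
                             seed = 1,
                             img_size = 128,
                             in_channels = 3,
                             kernel_size = 3,
                             scorecam_layer = NULL,
                             clip_eps = 1e-7,
                             recon_loss_scale = NULL,
                             class_loss_scale = NULL) {
  stopifnot(
    n_classes >= 2, alpha >= 0, alpha <= 1, latent_dim >= 2,
    length(encoder_filters) >= 1, length(decoder_filters) >= 1,
    all(encoder_filters >= 1), all(decoder_filters >= 1),
    epochs >= 1, batch_size >= 1, learning_rate > 0
  )
  activation <- match.arg(activation, c("relu", "sigmoid", "tanh"))
  decoder_activation <- match.arg(
    decoder_activation %||% activation,
    c("relu", "sigmoid", "tanh")
  )
  optimizer <- match.arg(optimizer, c("rmsprop", "adam", "sgd"))
  le <- length(encoder_filters)
  ld <- length(decoder_filters)
  if (img_size %% 2^le != 0 || img_size %% 2^ld != 0) {
    stop("img_size must be divisible by 2^n_layers for both coders")
  }
  sizes_enc <- img_size / 2^seq_len(le)
  if (is.null(scorecam_layer)) {
    cand <- which(sizes_enc == 8)
    scorecam_layer <- if (length(cand)) max(cand) else le
  }
  structure(
    list(
      n_classes = as.integer(n_classes), alpha = alpha,
      latent_dim = as.integer(latent_dim),
      encoder_filters = as.integer(encoder_filters),
      decoder_filters = as.integer(decoder_filters),
      activation = activation, decoder_activation = decoder_activation,
      optimizer = optimizer, learning_rate = learning_rate,
      batch_size = as.integer(batch_size), epochs = as.integer(epochs),
      seed = as.integer(seed), img_size = as.integer(img_size),
      in_channels = as.integer(in_channels),
      kernel_size = as.integer(kernel_size),
      scorecam_layer = as.integer(scorecam_layer), clip_eps = clip_eps,
      recon_loss_scale = recon_loss_scale %||% (img_size^2 * in_channels),
      class_loss_scale = class_loss_scale %||% (img_size^2 * in_channels)
    ),
    class = "morphovae_config"
  )
}

init_conv <- function(k, cin, cout, gain = 2) {
  W <- array(rnorm(k * k * cin * cout) * sqrt(gain / (k * k * cin)),
    dim = c(k, k, cin, cout)
  )
  list(W = W, b = numeric(cout))
}

init_dense <- function(n_in, n_out, gain = 2) {
  list(
    W = matrix(rnorm(n_out * n_in) * sqrt(gain / n_in), n_out, n_in),
    b = numeric(n_out)
  )
}

#' Construct an (untrained) Morpho-VAE model
#'
#' Weights are initialized with a seeded fan-in scheme derived from
#' `config$seed`.
#'
#' @param config a [morphovae_config()].
#' @return object of class `morphovae_model`.
#' @export
morphovae_model <- function(config) {
  stopifnot(inherits(config, "morphovae_config"))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(config$seed, 1))

  k <- config$kernel_size
  le <- length(config$encoder_filters)
  ld <- length(config$decoder_filters)
  s_enc <- config$img_size / 2^le
  s_dec <- config$img_size / 2^ld
  flat_dim <- s_enc^2 * config$encoder_filters[le]
  c0 <- config$decoder_filters[1]

  enc <- vector("list", le)
  cin <- config$in_channels
  for (l in seq_len(le)) {
    enc[[l]] <- init_conv(k, cin, config$encoder_filters[l])
    cin <- config$encoder_filters[l]
  }
  dec <- vector("list", ld)
  cin <- c0
  for (l in seq_len(ld)) {
    dec[[l]] <- init_conv(k, cin, config$decoder_filters[l])
    cin <- config$decoder_filters[l]
  }
  weights <- list(
    enc = enc,
    w_mu = init_dense(flat_dim, config$latent_dim, gain = 1),
    w_lv = init_dense(flat_dim, config$latent_dim, gain = 1),
    dec_fc = init_dense(config$latent_dim, s_dec^2 * c0),
    dec = dec,
    dec_out = init_conv(k, config$decoder_filters[ld], config$in_channels, gain = 1),
    cls = init_dense(config$latent_dim, config$n_classes, gain = 1)
  )
  structure(
    list(config = config, weights = weights, trained = FALSE, history = NULL),
    class = "morphovae_model"
  )
}

#' @export
print.morphovae_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<morphovae_model> %dpx x %dch -> latent %d -> %d classes; enc [%s], dec [%s]; alpha=%g%s\n",
    cfg$img_size, cfg$in_channels, cfg$latent_dim, cfg$n_classes,
    paste(cfg$encoder_filters, collapse = ","),
    paste(cfg$decoder_filters, collapse = ","),
    cfg$alpha, if (x$trained) "; trained" else ""
  ))
  invisible(x)
}

upsample2 <- function(h) cpp_upsample2(h)

downsample2_sum <- function(d4) cpp_downsample2_sum(d4)

as_batch_array <- function(x, cfg) {
  if (inherits(x, "projection_triplet")) x <- as_input_array(x)
  d <- dim(x)
  if (length(d) == 3) dim(x) <- c(d, 1)
  d <- dim(x)
  if (d[1] != cfg$img_size || d[2] != cfg$img_size || d[3] != cfg$in_channels) {
    stop(sprintf(
      "input geometry %s does not match model (%d, %d, %d)",
      paste(d[1:3], collapse = "x"), cfg$img_size, cfg$img_size, cfg$in_channels
    ))
  }
  x
}

# Full forward pass with cached intermediates for backprop.
model_forward <- function(model, x, eps = NULL) {
  cfg <- model$config
  w <- model$weights
  act <- activation_fun(cfg$activation)
  dact_name <- cfg$decoder_activation
  dec_act <- activation_fun(dact_name)
  N <- dim(x)[4]

  acts <- vector("list", length(w$enc) + 1)
  acts[[1]] <- x
  h <- x
  for (l in seq_along(w$enc)) {
    h <- cpp_conv2d_fwd(h, w$enc[[l]]$W, w$enc[[l]]$b, 2L, 1L)
    h <- act(h)
    acts[[l + 1]] <- h
  }
  flat <- matrix(h, prod(dim(h)[1:3]), N)
  mu <- w$w_mu$W %*% flat + w$w_mu$b
  lv <- w$w_lv$W %*% flat + w$w_lv$b
  lv <- pmin(pmax(lv, -15), 15) # numerical guard on log-variance
  if (is.null(eps)) eps <- matrix(0, cfg$latent_dim, N)
  z <- mu + exp(0.5 * lv) * eps

  s_dec <- cfg$img_size / 2^length(w$dec)
  fc_a <- dec_act(w$dec_fc$W %*% z + w$dec_fc$b)
  h <- array(fc_a, c(s_dec, s_dec, cfg$decoder_filters[1], N))
  dec_up <- vector("list", length(w$dec))
  dec_acts <- vector("list", length(w$dec))
  for (l in seq_along(w$dec)) {
    up <- upsample2(h)
    dec_up[[l]] <- up
    h <- dec_act(cpp_conv2d_fwd(up, w$dec[[l]]$W, w$dec[[l]]$b, 1L, 1L))
    dec_acts[[l]] <- h
  }
  logits_img <- cpp_conv2d_fwd(h, w$dec_out$W, w$dec_out$b, 1L, 1L)
  q <- sigmoid(logits_img)

  cls_logits <- w$cls$W %*% z + w$cls$b
  probs <- softmax_cols(cls_logits)

  list(
    acts = acts, flat = flat, mu = mu, lv = lv, eps = eps, z = z,
    fc_a = fc_a, dec_up = dec_up, dec_acts = dec_acts,
    logits_img = logits_img, q = q, cls_logits = cls_logits, probs = probs
  )
}

# Gradient of E_total w.r.t. all weights for one batch.
model_backward <- function(model, fw, y_onehot) {
  cfg <- model$config
  w <- model$weights
  alpha <- cfg$alpha
  N <- ncol(fw$mu)
  dimp <- cfg$img_size^2 * cfg$in_channels
  dact <- activation_deriv(cfg$activation)
  ddec <- activation_deriv(cfg$decoder_activation)

  g <- list(
    enc = vector("list", length(w$enc)),
    dec = vector("list", length(w$dec))
  )

  # reconstruction head: sigmoid + BCE collapse to (q - p); the training
  # objective scales the reconstruction term by recon_loss_scale
  dlog <- (1 - alpha) * cfg$recon_loss_scale * (fw$q - fw$acts[[1]]) / (dimp * N)
  bw <- cpp_conv2d_bwd(fw$dec_acts[[length(w$dec)]], w$dec_out$W, dlog, 1L, 1L)
  g$dec_out <- list(W = bw$dw, b = bw$db)
  dh <- bw$dx
  for (l in rev(seq_along(w$dec))) {
    dpre <- dh * ddec(fw$dec_acts[[l]])
    bw <- cpp_conv2d_bwd(fw$dec_up[[l]], w$dec[[l]]$W, dpre, 1L, 1L)
    g$dec[[l]] <- list(W = bw$dw, b = bw$db)
    dh <- downsample2_sum(bw$dx)
  }
  dfc_a <- matrix(dh, nrow(w$dec_fc$W), N)
  dfc_pre <- dfc_a * ddec(matrix(fw$fc_a, nrow(w$dec_fc$W), N))
  g$dec_fc <- list(
    W = dfc_pre %*% t(fw$z),
    b = rowSums(dfc_pre)
  )
  dz <- t(w$dec_fc$W) %*% dfc_pre

  # classifier head (class_loss_scale mirrors the reconstruction scale)
  dcls_logits <- alpha * cfg$class_loss_scale * (fw$probs - y_onehot) /
    (cfg$n_classes * N)
  g$cls <- list(W = dcls_logits %*% t(fw$z), b = rowSums(dcls_logits))
  dz <- dz + t(w$cls$W) %*% dcls_logits

  # KL term (mean over batch of per-sample sums), plus reparameterization
  dmu <- (1 - alpha) * fw$mu / N + dz
  dlv <- (1 - alpha) * 0.5 * (exp(fw$lv) - 1) / N +
    dz * fw$eps * 0.5 * exp(0.5 * fw$lv)

  g$w_mu <- list(W = dmu %*% t(fw$flat), b = rowSums(dmu))
  g$w_lv <- list(W = dlv %*% t(fw$flat), b = rowSums(dlv))
  dflat <- t(w$w_mu$W) %*% dmu + t(w$w_lv$W) %*% dlv

  le <- length(w$enc)
  dh <- array(dflat, dim(fw$acts[[le + 1]]))
  for (l in rev(seq_len(le))) {
    dpre <- dh * dact(fw$acts[[l + 1]])
    bw <- cpp_conv2d_bwd(fw$acts[[l]], w$enc[[l]]$W, dpre, 2L, 1L,
      need_dx = l > 1
    )
    g$enc[[l]] <- list(W = bw$dw, b = bw$db)
    dh <- bw$dx
  }
  g[names(w)] # same element order as the weight tree (optimizer recurses positionally)
}

#' Loss components for one batch
#'
#' Computes the reconstruction loss (binary cross-entropy per pixel,
#' averaged over all pixels and samples), the regularization loss (the
#' closed-form KL divergence of the diagonal Gaussian `N(mu, sigma)` from
#' the standard-normal prior, summed over latent dimensions and averaged
#' over samples), the classification loss (cross-entropy scaled by
#' `1/n_classes`), and their combinations
#' `E_VAE = E_Rec + E_Reg`, `E_total = (1 - alpha) E_VAE + alpha E_C`.
#'
#' @param p input images (any numeric array/vector in `[0, 1]`).
#' @param q reconstructed images, same shape as `p`; clipped to
#'   `[clip_eps, 1 - clip_eps]` before the logarithms.
#' @param code list with `mu` and `log_var` (vectors or `d x N` matrices).
#' @param labels list with one-hot `y` and predicted `y_prime`
#'   (`n_classes x N`); may be `NULL` when only the VAE terms are wanted.
#' @param alpha loss weight.
#' @param clip_eps clipping bound (default 1e-7).
#' @return object of class `loss_breakdown` with fields `e_rec`, `e_reg`,
#'   `e_c`, `e_vae`, `e_total`.
#' @export
compute_losses <- function(p, q, code = NULL, labels = NULL, alpha = 0.1,
                           clip_eps = 1e-7) {
  if (length(p) != length(q)) stop("p and q have mismatched shapes")
  qc <- clip01(as.numeric(q), clip_eps)
  pv <- as.numeric(p)
  e_rec <- -mean(pv * log(qc) + (1 - pv) * log(1 - qc))

  e_reg <- 0
  if (!is.null(code)) {
    mu <- as.matrix(code$mu)
    lv <- as.matrix(code$log_var)
    e_reg <- mean(colSums(0.5 * (mu^2 + exp(lv) - lv - 1)))
  }
  e_c <- 0
  if (!is.null(labels)) {
    y <- as.matrix(labels$y)
    yp <- clip01(as.matrix(labels$y_prime), clip_eps)
    e_c <- mean(colSums(-y * log(yp)) / nrow(y))
  }
  e_vae <- e_rec + e_reg
  structure(
    list(
      e_rec = e_rec, e_reg = e_reg, e_c = e_c, e_vae = e_vae,
      e_total = (1 - alpha) * e_vae + alpha * e_c, alpha = alpha
    ),
    class = "loss_breakdown"
  )
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "E_Rec=%.5g E_Reg=%.5g E_C=%.5g E_VAE=%.5g E_total=%.5g (alpha=%g)\n",
    x$e_rec, x$e_reg, x$e_c, x$e_vae, x$e_total, x$alpha
  ))
  invisible(x)
}

#' Draw a latent sample by reparameterization
#'
#' `zeta = mu + exp(log_var / 2) * eps`, `eps ~ N(0, I)`; the mechanism
#' used by stochastic encoding.
#'
#' @param mu,log_var numeric vectors (or `d x N` matrices).
#' @param seed optional integer seed for the draw.
#' @return sample(s) with the shape of `mu`.
#' @export
reparameterize <- function(mu, log_var, seed = NULL) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  eps <- array(rnorm(length(mu)), dim = dim(mu) %||% length(mu))
  mu + exp(0.5 * log_var) * eps
}

#' Encode projection triplets into the latent space
#'
#' @param model a [morphovae_model()].
#' @param triplet a [projection_triplet()], an `(H, W, 3)` array, or an
#'   `(H, W, 3, N)` batch.
#' @param mode `"deterministic"` sets `zeta = mu`; `"stochastic"` samples
#'   `zeta ~ N(mu, sigma)`.
#' @param seed seed for the stochastic draw.
#' @return for a single input, a `latent_code` (fields `mu`, `log_var`,
#'   `zeta`); for a batch, a list of `d x N` matrices with the same names.
#' @export
encode <- function(model, triplet, mode = c("deterministic", "stochastic"),
                   seed = NULL) {
  mode <- match.arg(mode)
  x <- as_batch_array(triplet, model$config)
  fw <- encoder_only_forward(model, x)
  zeta <- if (mode == "deterministic") {
    fw$mu
  } else {
    reparameterize(fw$mu, fw$lv, seed = seed)
  }
  if (dim(x)[4] == 1) {
    structure(
      list(
        mu = drop(fw$mu), log_var = drop(fw$lv),
        zeta = drop(zeta)
      ),
      class = "latent_code"
    )
  } else {
    list(mu = fw$mu, log_var = fw$lv, zeta = zeta)
  }
}

# Encoder pass without the decoder (used by encode/saliency/metrics).
encoder_only_forward <- function(model, x, keep_acts = FALSE) {
  cfg <- model$config
  w <- model$weights
  act <- activation_fun(cfg$activation)
  N <- dim(x)[4]
  acts <- if (keep_acts) vector("list", length(w$enc)) else NULL
  h <- x
  for (l in seq_along(w$enc)) {
    h <- act(cpp_conv2d_fwd(h, w$enc[[l]]$W, w$enc[[l]]$b, 2L, 1L))
    if (keep_acts) acts[[l]] <- h
  }
  flat <- matrix(h, prod(dim(h)[1:3]), N)
  mu <- w$w_mu$W %*% flat + w$w_mu$b
  lv <- pmin(pmax(w$w_lv$W %*% flat + w$w_lv$b, -15), 15)
  list(mu = mu, lv = lv, acts = acts)
}

#' Decode latent points into images
#'
#' @param model a [morphovae_model()].
#' @param zeta a latent vector, a `d x N` matrix of latent columns, or a
#'   `latent_code` (its `zeta` is used).
#' @return an `(H, W, 3)` array in (0, 1) for a single point, else
#'   `(H, W, 3, N)`.
#' @export
decode <- function(model, zeta) {
  cfg <- model$config
  w <- model$weights
  if (inherits(zeta, "latent_code")) zeta <- zeta$zeta
  z <- if (is.matrix(zeta)) zeta else matrix(zeta, cfg$latent_dim, 1)
  if (!all(is.finite(z))) stop("non-finite latent value")
  N <- ncol(z)
  dec_act <- activation_fun(cfg$decoder_activation)
  s_dec <- cfg$img_size / 2^length(w$dec)
  h <- array(
    dec_act(w$dec_fc$W %*% z + w$dec_fc$b),
    c(s_dec, s_dec, cfg$decoder_filters[1], N)
  )
  for (l in seq_along(w$dec)) {
    h <- dec_act(cpp_conv2d_fwd(upsample2(h), w$dec[[l]]$W, w$dec[[l]]$b, 1L, 1L))
  }
  q <- sigmoid(cpp_conv2d_fwd(h, w$dec_out$W, w$dec_out$b, 1L, 1L))
  if (N == 1) array(q, dim(q)[1:3]) else q
}

#' Classify latent points
#'
#' The single-layer softmax head: logits are an affine function of `zeta`.
#'
#' @param model a [morphovae_model()].
#' @param zeta latent vector, `d x N` matrix, or `latent_code`.
#' @return probability vector (or `n_classes x N` matrix) with the logits
#'   attached as attribute `"logits"`.
#' @export
classify <- function(model, zeta) {
  cfg <- model$config
  if (inherits(zeta, "latent_code")) zeta <- zeta$zeta
  z <- if (is.matrix(zeta)) zeta else matrix(zeta, cfg$latent_dim, 1)
  if (!all(is.finite(z))) stop("non-finite latent value")
  logits <- model$weights$cls$W %*% z + model$weights$cls$b
  probs <- softmax_cols(logits)
  if (ncol(z) == 1) {
    structure(drop(probs), logits = drop(logits))
  } else {
    structure(probs, logits = logits)
  }
}

# chunked deterministic encoding of a big batch; returns d x N matrices
encode_batch <- function(model, x4, chunk = 64) {
  N <- dim(x4)[4]
  d <- model$config$latent_dim
  mu <- matrix(0, d, N)
  lv <- matrix(0, d, N)
  for (s in seq(1, N, chunk)) {
    e <- min(s + chunk - 1, N)
    fw <- encoder_only_forward(model, x4[, , , s:e, drop = FALSE])
    mu[, s:e] <- fw$mu
    lv[, s:e] <- fw$lv
  }
  list(mu = mu, log_var = lv, zeta = mu)
}

# chunked decode
decode_batch <- function(model, z, chunk = 64) {
  N <- ncol(z)
  cfg <- model$config
  out <- array(0, c(cfg$img_size, cfg$img_size, cfg$in_channels, N))
  for (s in seq(1, N, chunk)) {
    e <- min(s + chunk - 1, N)
    q <- decode(model, z[, s:e, drop = FALSE])
    if (length(dim(q)) == 3) dim(q) <- c(dim(q), 1)
    out[, , , s:e] <- q
  }
  out
}

#' Save / load a model as JSON
#'
#' Plain-text checkpoint: configuration plus all weight arrays.
#'
#' @param model a [morphovae_model()].
#' @param path file path.
#' @export
save_model <- function(model, path) {
  ser <- list(
    config = unclass(model$config),
    weights = rapply(model$weights, function(a) {
      list(dim = dim(a) %||% length(a), data = as.numeric(a))
    }, how = "list"),
    trained = model$trained
  )
  writeLines(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::fromJSON(readLines(path),
    simplifyVector = TRUE,
    simplifyDataFrame = FALSE, simplifyMatrix = FALSE
  )
  cfg <- do.call(morphovae_config, ser$config[setdiff(
    names(ser$config),
    character()
  )])
  restore <- function(node) {
    if (is.list(node) && !is.null(node$dim) && !is.null(node$data)) {
      a <- node$data
      if (length(node$dim) > 1) dim(a) <- node$dim
      if (length(node$dim) == 2) a <- matrix(node$data, node$dim[1], node$dim[2])
      return(a)
    }
    lapply(node, restore)
  }
  m <- morphovae_model(cfg)
  m$weights <- restore(ser$weights)
  m$trained <- isTRUE(ser$trained)
  m
}
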