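test_that("configuration validation rejects broken candidates", {
  expect_error(morphovae_config(n_classes = 3, encoder_filters = c(0, 8)))
  expect_error(morphovae_config(n_classes = 3, alpha = 1.5))
  expect_error(morphovae_config(n_classes = 3, latent_dim = 1))
  expect_error(morphovae_config(
    n_classes = 3, img_size = 100,
    encoder_filters = c(8, 8, 8)
  ), "divisible")
  cfg <- morphovae_config(n_classes = 7)
  expect_equal(cfg$encoder_filters, c(128L, 128L, 32L, 32L, 64L))
  expect_equal(cfg$decoder_filters, c(64L, 32L, 32L, 128L, 128L))
  expect_equal(cfg$alpha, 0.1)
  expect_equal(cfg$latent_dim, 3L)
  expect_equal(cfg$scorecam_layer, 4L) # the 8x8 activation layer
})

make_toy <- function(seed = 4, n_classes = 3, ...) {
  morphovae_model(morphovae_config(
    n_classes = n_classes,
    encoder_filters = c(4, 6), decoder_filters = c(6, 4),
    img_size = 32, seed = seed, ...
  ))
}

toy_input <- function(n = 1, seed = 2, size = 32) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  array((runif(size * size * 3 * n) > 0.7) * 1, c(size, size, 3, n))
}

test_that("encode modes: deterministic zeta = mu, seeded draws reproduce", {
  m <- make_toy()
  x <- toy_input()
  cd <- encode(m, x, mode = "deterministic")
  expect_identical(cd$zeta, cd$mu)
  cs1 <- encode(m, x, mode = "stochastic", seed = 99)
  cs2 <- encode(m, x, mode = "stochastic", seed = 99)
  expect_identical(cs1$zeta, cs2$zeta)
  expect_false(identical(cs1$zeta, cd$mu))
  expect_error(encode(m, array(0, c(16, 16, 3, 1))), "geometry")
})

test_that("reparameterized draws have the encoded mean and spread", {
  m <- make_toy()
  code <- encode(m, toy_input(), mode = "deterministic")
  n <- 4000
  mu <- matrix(code$mu, 3, n)
  lv <- matrix(code$log_var, 3, n)
  z <- reparameterize(mu, lv, seed = 123)
  se <- exp(0.5 * code$log_var) / sqrt(n)
  expect_true(all(abs(rowMeans(z) - code$mu) < 3 * se))
})

test_that("decode output is strictly inside (0,1), smooth, and guarded", {
  m <- make_toy()
  q <- decode(m, c(0, 0, 0))
  expect_equal(dim(q), c(32, 32, 3))
  expect_true(all(q > 0 & q < 1))
  q2 <- decode(m, c(0, 0, 0) + 1e-6 / sqrt(3))
  expect_lt(max(abs(q2 - q)), 1e-3)
  expect_error(decode(m, c(NA, 0, 0)), "finite")
  expect_error(decode(m, c(Inf, 0, 0)), "finite")
})

test_that("classifier is a normalized softmax over an affine map", {
  m <- make_toy()
  set.seed(10)
  for (i in 1:5) {
    z <- rnorm(3) * 2
    p <- classify(m, z)
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
  # single-layer contract: logits additive up to the bias
  z1 <- rnorm(3)
  z2 <- rnorm(3)
  l <- function(z) attr(classify(m, z), "logits")
  expect_equal(l(z1 + z2), l(z1) + l(z2) - l(c(0, 0, 0)), tolerance = 1e-8)
})

test_that("loss components match their closed forms and identities", {
  # perfect reconstruction: clipped BCE below 1e-6
  p <- c(0, 1, 1, 0, 1)
  expect_lte(compute_losses(p, p, alpha = 0)$e_rec, 1e-6)

  # prior match: KL exactly 0
  lb <- compute_losses(p, p,
    code = list(mu = rep(0, 3), log_var = rep(0, 3)),
    alpha = 0
  )
  expect_identical(lb$e_reg, 0)

  # brute-force elementwise oracle on random batches
  set.seed(42)
  for (r in 1:5) {
    n <- 4
    d <- 3
    npix <- 30
    pm <- matrix(runif(npix * n) > 0.5, npix, n) * 1
    qm <- matrix(runif(npix * n), npix, n)
    mu <- matrix(rnorm(d * n), d, n)
    lv <- matrix(rnorm(d * n, sd = 0.5), d, n)
    y <- morphovae:::onehot(sample(letters[1:d], n, TRUE), letters[1:d])
    yp <- apply(matrix(runif(d * n), d, n), 2, function(v) v / sum(v))
    a <- runif(1)
    lb <- compute_losses(pm, qm,
      code = list(mu = mu, log_var = lv),
      labels = list(y = y, y_prime = yp), alpha = a
    )
    # independent elementwise sums
    e_rec <- 0
    for (i in seq_len(npix)) {
      for (j in seq_len(n)) {
        q <- min(max(qm[i, j], 1e-7), 1 - 1e-7)
        e_rec <- e_rec - (pm[i, j] * log(q) + (1 - pm[i, j]) * log(1 - q))
      }
    }
    e_rec <- e_rec / (npix * n)
    e_reg <- 0
    for (j in seq_len(n)) {
      for (k in seq_len(d)) {
        e_reg <- e_reg + 0.5 * (mu[k, j]^2 + exp(lv[k, j]) - lv[k, j] - 1)
      }
    }
    e_reg <- e_reg / n
    e_c <- 0
    for (j in seq_len(n)) {
      for (k in seq_len(d)) e_c <- e_c - y[k, j] * log(yp[k, j])
    }
    e_c <- e_c / (d * n)
    expect_equal(lb$e_rec, e_rec, tolerance = 1e-10)
    expect_equal(lb$e_reg, e_reg, tolerance = 1e-10)
    expect_equal(lb$e_c, e_c, tolerance = 1e-10)
    expect_equal(lb$e_vae, lb$e_rec + lb$e_reg, tolerance = 1e-12)
    expect_equal(lb$e_total, (1 - a) * lb$e_vae + a * lb$e_c, tolerance = 1e-12)
    # endpoint identities
    lb0 <- compute_losses(pm, qm,
      code = list(mu = mu, log_var = lv),
      labels = list(y = y, y_prime = yp), alpha = 0
    )
    lb1 <- compute_losses(pm, qm,
      code = list(mu = mu, log_var = lv),
      labels = list(y = y, y_prime = yp), alpha = 1
    )
    expect_equal(lb0$e_total, lb0$e_vae, tolerance = 1e-12)
    expect_equal(lb1$e_total, lb1$e_c, tolerance = 1e-12)
    expect_error(compute_losses(pm, qm[1:10, ]), "mismatch")
  }
})

test_that("closed-form KL agrees with numerical integration", {
  for (ms in list(c(0, 0), c(1, 0), c(-0.5, 0.7), c(2, -1))) {
    mu <- ms[1]
    lv <- ms[2]
    s <- exp(0.5 * lv)
    closed <- compute_losses(0.5, 0.5,
      code = list(mu = mu, log_var = lv),
      alpha = 0
    )$e_reg
    num <- stats::integrate(function(x) {
      q <- stats::dnorm(x, mu, s)
      ifelse(q > 0, q * (stats::dnorm(x, mu, s, log = TRUE) -
        stats::dnorm(x, log = TRUE)), 0)
    }, mu - 12 * s, mu + 12 * s, rel.tol = 1e-9)$value
    expect_equal(closed, num, tolerance = 1e-3)
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- morphovae_config(
    n_classes = 3, alpha = 0.3, latent_dim = 3,
    encoder_filters = c(4, 5), decoder_filters = c(5, 4),
    activation = "tanh", img_size = 16, seed = 9
  )
  m <- morphovae_model(cfg)
  x <- toy_input(n = 3, seed = 2, size = 16)
  set.seed(5)
  y <- morphovae:::onehot(sample(c("a", "b", "c"), 3, TRUE), c("a", "b", "c"))
  eps <- matrix(rnorm(9), 3)

  loss_of <- function(w) {
    # the optimized objective (reconstruction at recon_loss_scale)
    mm <- m
    mm$weights <- w
    fw <- morphovae:::model_forward(mm, x, eps = eps)
    lb <- morphovae:::batch_losses(mm, fw, y)
    morphovae:::train_objective(cfg, lb$e_rec, lb$e_reg, lb$e_c)
  }
  fw <- morphovae:::model_forward(m, x, eps = eps)
  g <- morphovae:::model_backward(m, fw, y)
  expect_identical(names(g), names(m$weights))

  relist_like <- function(v, skel) {
    pos <- 0
    walk <- function(node) {
      if (is.list(node)) {
        return(lapply(node, walk))
      }
      n <- length(node)
      out <- v[(pos + 1):(pos + n)]
      pos <<- pos + n
      if (!is.null(dim(node))) dim(out) <- dim(node)
      out
    }
    walk(skel)
  }
  wv <- unlist(m$weights, use.names = FALSE)
  gv <- unlist(g, use.names = FALSE)
  set.seed(3)
  idx <- sample(length(wv), 40)
  h <- 1e-5
  for (k in idx) {
    wp <- wv
    wp[k] <- wp[k] + h
    wm <- wv
    wm[k] <- wm[k] - h
    num <- (loss_of(relist_like(wp, m$weights)) -
      loss_of(relist_like(wm, m$weights))) / (2 * h)
    expect_equal(gv[k], num, tolerance = 1e-4)
  }
})

test_that("a model overfit to one specimen reconstructs it", {
  gen <- generate_dataset(shape_presets("separable", 2), c(1, 1),
    seed = 31, check_connectivity = "none"
  )
  man <- gen$manifest[1, , drop = FALSE]
  man$label <- "only"
  ds <- preprocess_dataset(gen$volumes[man$specimen_id], man,
    target_length_px = 52
  )
  ds$labels <- factor(c("a", "b")) # one label per half keeps n_classes = 2
  split <- structure(
    list(
      train_ids = man$specimen_id, val_ids = character(0),
      test_ids = character(0), seed = 1
    ),
    class = "split_plan"
  )
  cfg <- morphovae_config(
    n_classes = 2, alpha = 0,
    encoder_filters = c(8, 8, 16, 16, 16), decoder_filters = c(16, 16, 8, 8, 8),
    batch_size = 2, learning_rate = 2e-3, epochs = 150, seed = 3
  )
  m <- suppressWarnings(train_model(ds, cfg, split))
  x <- ds$triplets[, , , 1]
  q <- decode(m, encode(m, x, mode = "deterministic")$zeta)
  expect_gte(mean(abs(q - x) < 0.1), 0.95)
})

test_that("models round-trip through the JSON checkpoint", {
  m <- make_toy(seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$weights, m$weights)
  x <- toy_input(seed = 8)
  expect_equal(encode(m2, x)$mu, encode(m, x)$mu)
  expect_equal(m2$config$encoder_filters, m$config$encoder_filters)
})
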