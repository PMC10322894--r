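# Shared fixtures, cached across test files (test_dir runs one process).
# The two trained fixtures are expensive (minutes); every file that needs a
# trained model reuses them through these getters.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, force(expr), envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

small_net_config <- function(n_classes = 3, ...) {
  # fixture-scale optimization: small filters for the CI budget, smaller
  # batches / slightly larger steps because the fixture runs see only
  # ~1e3 optimizer steps (the published batch size and learning rate are
  # not stated and are exposed as configuration)
  morphovae_config(
    n_classes = n_classes,
    encoder_filters = c(8, 8, 16, 16, 32),
    decoder_filters = c(32, 16, 16, 8, 8),
    batch_size = 16,
    learning_rate = 2e-3,
    ...
  )
}

# tiny separable dataset for fast unit tests (no training quality claims)
fx_tiny_dataset <- function() {
  cached("tiny_dataset", synthetic_morphovae_dataset(
    "separable", 3,
    n_per_class = 6, seed = 11
  ))
}

# the main evaluation fixture: separable preset, 3 classes x 60 specimens,
# 100 epochs — the scaled-down structural replication of the published
# evaluation (small filter counts keep the run inside the CI budget)
fx_main <- function() {
  cached("main", {
    ds <- synthetic_morphovae_dataset("separable", 3, n_per_class = 60, seed = 42)
    split <- make_splits(ds, seed = 42)
    cfg <- small_net_config(3, alpha = 0.1, epochs = 100, seed = 42)
    model <- train_model(ds, cfg, split)
    list(ds = ds, split = split, model = model)
  })
}

# quadrant-informative fixture for saliency / direction ablation
fx_quadrant <- function() {
  cached("quadrant", {
    ds <- synthetic_morphovae_dataset("quadrant", 3, n_per_class = 18, seed = 77)
    split <- make_splits(ds, seed = 77)
    cfg <- small_net_config(3, alpha = 0.1, epochs = 50, seed = 77)
    model <- train_model(ds, cfg, split)
    list(ds = ds, split = split, model = model)
  })
}

# deterministic pseudo-random binary volume for projection oracles
random_volume <- function(dims, p = 0.1, seed = 1) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  array(runif(prod(dims)) < p, dim = dims)
}

# test-side ellipsoid volume with canonical-pose landmarks
ellipsoid_volume <- function(dims = c(64, 80, 64), center = c(32, 40, 32),
                             semi = c(18, 24, 14), id = "ell") {
  # center/semi given as physical (x, y, z)
  X <- array(rep(0:(dims[3] - 1), each = dims[1] * dims[2]), dims)
  Y <- array(rep(rep(0:(dims[2] - 1), each = dims[1]), dims[3]), dims)
  Z <- array(rep(0:(dims[1] - 1), dims[2] * dims[3]), dims)
  occ <- ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
  voxel_volume(occ,
    specimen_id = id,
    landmarks = list(
      condyle_left = center + c(-semi[1] / 2, -semi[2] / 4, 0),
      condyle_right = center + c(semi[1] / 2, -semi[2] / 4, 0),
      tip = center + c(0, semi[2] * 0.9, 0),
      angular = center + c(0, -semi[2] * 0.9, 0)
    )
  )
}

halves_idx <- function(ds, ids) which(ds$parent_id %in% ids)

encode_points <- function(model, ds, ids) {
  idx <- halves_idx(ds, ids)
  list(
    z = t(morphovae:::encode_batch(model, ds$triplets[, , , idx, drop = FALSE])$mu),
    labels = ds$labels[idx],
    idx = idx
  )
}
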