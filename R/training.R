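# Data partitioning with leakage control, the E_total training loop,
# alpha selection by cross-validation, and a budgeted random
# hyperparameter search.

#' Stratified specimen-level train/validation/test split
#'
#' One third of the specimens form the test set; of the remainder, 75%
#' train and 25% validate. Partition sizes per label follow proportional
#' extraction (largest-remainder rounding, so per-label proportions match
#' the full dataset within one specimen). Splitting happens at the
#' *specimen* level: both mirrored halves of a specimen always land in the
#' same partition, so no specimen leaks between train and test.
#'
#' @param manifest data frame with `specimen_id` and `label` columns (one
#'   row per specimen), or a `morphovae_dataset`.
#' @param seed integer seed; identical seeds give identical plans.
#' @param test_frac,train_frac partition fractions (defaults 1/3 and 0.75).
#' @return object of class `split_plan` with `train_ids`, `val_ids`,
#'   `test_ids` and per-label counts.
#' @export
make_splits <- function(manifest, seed, test_frac = 1 / 3, train_frac = 0.75) {
  if (inherits(manifest, "morphovae_dataset")) {
    manifest <- dataset_manifest(manifest)
  }
  stopifnot(all(c("specimen_id", "label") %in% names(manifest)))
  if (anyNA(manifest$label)) stop("every specimen needs a label")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  ids <- as.character(manifest$specimen_id)
  labels <- as.character(manifest$label)
  tab <- table(labels)
  if (any(tab < 3)) {
    warning("some labels have fewer than 3 specimens")
  }
  singles <- names(tab)[tab == 1]
  forced_train <- ids[labels %in% singles]
  keep <- !(labels %in% singles)
  ids_k <- ids[keep]
  labels_k <- labels[keep]

  # largest-remainder allocation of `target` slots across labels
  allocate <- function(counts, frac) {
    target <- round(sum(counts) * frac)
    quota <- counts * frac
    base <- floor(quota)
    rem <- target - sum(base)
    if (rem > 0) {
      ord <- order(quota - base, runif(length(quota)), decreasing = TRUE)
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    } else if (rem < 0) {
      ord <- order(quota - base, runif(length(quota)))
      take <- ord[base[ord] > 0][seq_len(-rem)]
      base[take] <- base[take] - 1
    }
    base
  }

  labs <- names(table(labels_k))
  counts <- as.numeric(table(labels_k)[labs])
  n_test <- allocate(counts, test_frac)
  test_ids <- character(0)
  rest_ids <- character(0)
  rest_labels <- character(0)
  for (i in seq_along(labs)) {
    pool <- sample(ids_k[labels_k == labs[i]])
    test_ids <- c(test_ids, pool[seq_len(n_test[i])])
    rest <- pool[setdiff(seq_along(pool), seq_len(n_test[i]))]
    rest_ids <- c(rest_ids, rest)
    rest_labels <- c(rest_labels, rep(labs[i], length(rest)))
  }
  counts2 <- as.numeric(table(rest_labels)[labs])
  counts2[is.na(counts2)] <- 0
  n_train <- allocate(counts2, train_frac)
  train_ids <- forced_train
  val_ids <- character(0)
  for (i in seq_along(labs)) {
    pool <- sample(rest_ids[rest_labels == labs[i]])
    train_ids <- c(train_ids, pool[seq_len(n_train[i])])
    val_ids <- c(val_ids, pool[setdiff(seq_along(pool), seq_len(n_train[i]))])
  }
  if (length(forced_train)) {
    warning(
      "labels with a single specimen assigned to train: ",
      paste(singles, collapse = ", ")
    )
  }
  part <- factor(
    ifelse(ids %in% train_ids, "train",
      ifelse(ids %in% val_ids, "val", "test")
    ),
    levels = c("train", "val", "test")
  )
  structure(
    list(
      train_ids = sort(train_ids), val_ids = sort(val_ids),
      test_ids = sort(test_ids),
      counts = table(labels, part), seed = seed
    ),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "<split_plan> %d train / %d val / %d test specimens (seed %d)\n",
    length(x$train_ids), length(x$val_ids), length(x$test_ids), x$seed
  ))
  print(x$counts)
  invisible(x)
}

#' Specimen-level manifest of a dataset
#'
#' @param dataset a `morphovae_dataset`.
#' @return data frame with one row per specimen (`specimen_id`, `label`).
#' @export
dataset_manifest <- function(dataset) {
  u <- !duplicated(dataset$parent_id)
  data.frame(
    specimen_id = dataset$parent_id[u],
    label = as.character(dataset$labels)[u],
    stringsAsFactors = FALSE
  )
}

# indices of dataset halves belonging to a set of specimen ids
halves_of <- function(dataset, ids) which(dataset$parent_id %in% ids)

onehot <- function(labels, levels) {
  y <- matrix(0, length(levels), length(labels))
  y[cbind(match(as.character(labels), levels), seq_along(labels))] <- 1
  y
}

init_opt_state <- function(weights) {
  rapply(weights, function(a) {
    z <- a * 0
    list(v = z, m = z)
  }, how = "list")
}

# one optimizer step over the nested weight list, in place semantics
opt_step <- function(weights, grads, state, cfg, t) {
  lr <- cfg$learning_rate
  upd <- function(w, g, s) {
    if (is.list(w) && !is.list(g)) stop("gradient tree mismatch")
    if (is.list(w) && is.null(s$v)) {
      nm <- names(w) %||% seq_along(w)
      out_w <- w
      out_s <- s
      for (i in seq_along(w)) {
        r <- upd(w[[i]], g[[i]], s[[i]])
        out_w[[i]] <- r$w
        out_s[[i]] <- r$s
      }
      return(list(w = out_w, s = out_s))
    }
    if (cfg$optimizer == "sgd") {
      w <- w - lr * g
    } else if (cfg$optimizer == "rmsprop") {
      s$v <- 0.9 * s$v + 0.1 * g^2
      w <- w - lr * g / (sqrt(s$v) + 1e-8)
    } else { # adam
      s$m <- 0.9 * s$m + 0.1 * g
      s$v <- 0.999 * s$v + 0.001 * g^2
      mh <- s$m / (1 - 0.9^t)
      vh <- s$v / (1 - 0.999^t)
      w <- w - lr * mh / (sqrt(vh) + 1e-8)
    }
    list(w = w, s = s)
  }
  upd(weights, grads, state)
}

batch_losses <- function(model, fw, y_onehot) {
  compute_losses(
    p = fw$acts[[1]], q = fw$q,
    code = list(mu = fw$mu, log_var = fw$lv),
    labels = list(y = y_onehot, y_prime = fw$probs),
    alpha = model$config$alpha, clip_eps = model$config$clip_eps
  )
}

eval_losses <- function(model, x4, y_onehot, chunk = 64) {
  # deterministic evaluation (zeta = mu)
  N <- dim(x4)[4]
  acc <- c(e_rec = 0, e_reg = 0, e_c = 0)
  correct <- 0
  for (s in seq(1, N, chunk)) {
    e <- min(s + chunk - 1, N)
    xb <- x4[, , , s:e, drop = FALSE]
    fw <- model_forward(model, xb, eps = matrix(0, model$config$latent_dim, e - s + 1))
    lb <- batch_losses(model, fw, y_onehot[, s:e, drop = FALSE])
    wgt <- (e - s + 1) / N
    acc <- acc + wgt * c(lb$e_rec, lb$e_reg, lb$e_c)
    correct <- correct + sum(max.col(t(fw$probs)) == max.col(t(y_onehot[, s:e, drop = FALSE])))
  }
  a <- model$config$alpha
  list(
    e_rec = acc[["e_rec"]], e_reg = acc[["e_reg"]], e_c = acc[["e_c"]],
    e_vae = acc[["e_rec"]] + acc[["e_reg"]],
    e_total = (1 - a) * (acc[["e_rec"]] + acc[["e_reg"]]) + a * acc[["e_c"]],
    objective = train_objective(model$config, acc[["e_rec"]], acc[["e_reg"]], acc[["e_c"]]),
    accuracy = correct / N
  )
}

# the optimized total: both cross-entropies at their sum scales (see
# morphovae_config), regularization as reported
train_objective <- function(cfg, e_rec, e_reg, e_c) {
  (1 - cfg$alpha) * (cfg$recon_loss_scale * e_rec + e_reg) +
    cfg$alpha * cfg$class_loss_scale * e_c
}

#' Train a Morpho-VAE by minimizing E_total
#'
#' Minibatch backpropagation with the configured optimizer for a fixed
#' number of epochs (no early stopping). The returned model carries the
#' weights of the epoch with the lowest validation value of the optimized
#' objective (history column `val_objective`; the reconstruction term is
#' scaled by `config$recon_loss_scale`) alongside the full per-epoch
#' history of the reported loss components. The identities
#' `E_VAE = E_Rec + E_Reg` and `E_total = (1-alpha) E_VAE + alpha E_C`
#' are asserted on every batch.
#'
#' @param dataset a `morphovae_dataset` (see [preprocess_dataset()]).
#' @param config a [morphovae_config()]; `n_classes` must equal
#'   `nlevels(dataset$labels)`.
#' @param split a [make_splits()] plan over the dataset's specimens.
#' @param verbose print a line per epoch.
#' @return trained `morphovae_model` with a `history` data frame
#'   (per-epoch train/val loss components; attribute `best_epoch`).
#' @export
train_model <- function(dataset, config, split, verbose = FALSE) {
  stopifnot(inherits(config, "morphovae_config"))
  levels_ <- levels(dataset$labels)
  if (config$n_classes != length(levels_)) {
    stop("config$n_classes must match the number of label levels")
  }
  it <- halves_of(dataset, split$train_ids)
  iv <- halves_of(dataset, split$val_ids)
  if (!length(it)) stop("empty training partition")
  x_tr <- dataset$triplets[, , , it, drop = FALSE]
  y_tr <- onehot(dataset$labels[it], levels_)
  has_val <- length(iv) > 0
  if (has_val) {
    x_va <- dataset$triplets[, , , iv, drop = FALSE]
    y_va <- onehot(dataset$labels[iv], levels_)
  } else {
    warning("no validation specimens; using training loss for model selection")
  }

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(config$seed, 2))

  model <- morphovae_model(config)
  state <- init_opt_state(model$weights)
  n <- dim(x_tr)[4]
  bs <- min(config$batch_size, n)
  hist_rows <- vector("list", config$epochs)
  best <- list(objective = Inf, epoch = NA, weights = NULL)
  t_step <- 0

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    tr_acc <- c(e_rec = 0, e_reg = 0, e_c = 0)
    for (s in seq(1, n, bs)) {
      idx <- ord[s:min(s + bs - 1, n)]
      xb <- x_tr[, , , idx, drop = FALSE]
      yb <- y_tr[, idx, drop = FALSE]
      eps <- matrix(rnorm(config$latent_dim * length(idx)), config$latent_dim)
      fw <- model_forward(model, xb, eps = eps)
      lb <- batch_losses(model, fw, yb)
      if (!is.finite(lb$e_total) ||
        !is.finite(train_objective(config, lb$e_rec, lb$e_reg, lb$e_c))) {
        stop(sprintf(
          "training diverged at epoch %d (E_total not finite); lower the learning rate",
          epoch
        ))
      }
      stopifnot(
        isTRUE(all.equal(lb$e_vae, lb$e_rec + lb$e_reg, tolerance = 1e-8)),
        isTRUE(all.equal(lb$e_total,
          (1 - config$alpha) * lb$e_vae + config$alpha * lb$e_c,
          tolerance = 1e-8
        ))
      )
      g <- model_backward(model, fw, yb)
      t_step <- t_step + 1
      r <- opt_step(model$weights, g, state, config, t_step)
      model$weights <- r$w
      state <- r$s
      wgt <- length(idx) / n
      tr_acc <- tr_acc + wgt * c(lb$e_rec, lb$e_reg, lb$e_c)
    }
    a <- config$alpha
    tr <- list(
      e_rec = tr_acc[["e_rec"]], e_reg = tr_acc[["e_reg"]],
      e_c = tr_acc[["e_c"]],
      e_vae = tr_acc[["e_rec"]] + tr_acc[["e_reg"]],
      e_total = (1 - a) * (tr_acc[["e_rec"]] + tr_acc[["e_reg"]]) + a * tr_acc[["e_c"]],
      objective = train_objective(config, tr_acc[["e_rec"]], tr_acc[["e_reg"]], tr_acc[["e_c"]])
    )
    va <- if (has_val) eval_losses(model, x_va, y_va) else tr
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch,
      train_e_rec = tr$e_rec, train_e_reg = tr$e_reg, train_e_c = tr$e_c,
      train_e_vae = tr$e_vae, train_e_total = tr$e_total,
      train_objective = tr$objective,
      val_e_rec = va$e_rec, val_e_reg = va$e_reg, val_e_c = va$e_c,
      val_e_vae = va$e_vae, val_e_total = va$e_total,
      val_objective = va$objective,
      val_accuracy = va$accuracy %||% NA_real_
    )
    if (va$objective < best$objective) {
      best <- list(objective = va$objective, epoch = epoch, weights = model$weights)
    }
    if (verbose) {
      cat(sprintf(
        "epoch %3d  train obj %.4f  val obj %.4f  val E_C %.4f\n",
        epoch, tr$objective, va$objective, va$e_c
      ))
    }
  }
  history <- do.call(rbind, hist_rows)
  attr(history, "best_epoch") <- best$epoch
  model$weights <- best$weights
  model$trained <- TRUE
  model$history <- history
  model$split <- split
  model$label_levels <- levels_
  model
}

#' Cross-validated selection of the loss weight alpha
#'
#' Trains the model at each `alpha` for `n_repeats` different
#' train/validation reshuffles, records the best-epoch validation `E_C`
#' and `E_VAE`, and normalizes each by its maximum over the grid (so the
#' maximum is 1). `E_VAE` is taken at the scale the model optimizes
#' (`recon_loss_scale * E_Rec + E_Reg`) — the quantity a training loop
#' actually monitors; the per-pixel `e_rec` and raw `e_reg` components
#' are returned alongside. The recommended alpha is the smallest grid
#' value whose `E_C` is within `ec_tol` of the grid minimum while its
#' `E_VAE` exceeds the `alpha = 0` value by less than `evae_tol`.
#'
#' @param dataset a `morphovae_dataset`.
#' @param alpha_grid numeric grid in `[0, 1]` (should contain 0, the
#'   normalization baseline).
#' @param n_repeats train/validation reshuffles per grid point.
#' @param config base [morphovae_config()]; its `alpha` is overridden.
#' @param epochs epochs per run (defaults to `config$epochs`).
#' @param ec_tol,evae_tol tolerances of the recommendation rule.
#' @return data frame (`alpha`, `e_c`, `e_vae`, `e_c_norm`, `e_vae_norm`)
#'   with attributes `recommended_alpha` and `runs`.
#' @export
select_alpha <- function(dataset, alpha_grid, n_repeats, config,
                         epochs = NULL, ec_tol = 0.1, evae_tol = 0.05) {
  stopifnot(all(alpha_grid >= 0), all(alpha_grid <= 1), n_repeats >= 1)
  if (!0 %in% alpha_grid) {
    warning("alpha grid does not contain 0; normalization baseline missing")
  }
  manifest <- dataset_manifest(dataset)
  runs <- list()
  for (r in seq_len(n_repeats)) {
    split <- make_splits(manifest, seed = derive_seed(config$seed, 50 + r))
    for (k in seq_along(alpha_grid)) {
      cfg <- config
      cfg$alpha <- alpha_grid[k]
      cfg$seed <- derive_seed(config$seed, 1000 + 37 * r + k)
      if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
      m <- train_model(dataset, cfg, split)
      h <- m$history
      b <- attr(h, "best_epoch")
      runs[[length(runs) + 1]] <- data.frame(
        repeat_ = r, alpha = alpha_grid[k],
        e_c = h$val_e_c[b], e_rec = h$val_e_rec[b], e_reg = h$val_e_reg[b],
        e_vae = cfg$recon_loss_scale * h$val_e_rec[b] + h$val_e_reg[b]
      )
    }
  }
  runs <- do.call(rbind, runs)
  agg <- aggregate(cbind(e_c, e_rec, e_reg, e_vae) ~ alpha, data = runs, FUN = mean)
  agg <- agg[order(agg$alpha), ]
  agg$e_c_norm <- agg$e_c / max(agg$e_c)
  agg$e_vae_norm <- agg$e_vae / max(agg$e_vae)
  base_vae <- if (0 %in% agg$alpha) agg$e_vae[agg$alpha == 0] else min(agg$e_vae)
  ok <- agg$e_c <= min(agg$e_c) * (1 + ec_tol) &
    agg$e_vae <= base_vae * (1 + evae_tol)
  rec <- if (any(ok)) min(agg$alpha[ok]) else agg$alpha[which.min(agg$e_c)]
  attr(agg, "recommended_alpha") <- rec
  attr(agg, "runs") <- runs
  agg
}

#' Budgeted random hyperparameter search
#'
#' Samples `budget_trials` configurations from the structural search space
#' (1-5 layers, 16-128 filters per layer, ReLU/sigmoid/tanh activations,
#' SGD/Adam/RMSprop optimizers), trains each, and returns the configuration
#' with the lowest best-epoch validation `E_total`. Invalid candidates are
#' rejected by configuration validation before any training.
#'
#' @param dataset a `morphovae_dataset`.
#' @param config base [morphovae_config()] providing fixed fields
#'   (latent_dim, alpha, seed, ...).
#' @param split a [make_splits()] plan reused across trials.
#' @param budget_trials number of sampled configurations; 0 returns the
#'   base config with a warning.
#' @param search_space optional list overriding any of `n_layers`,
#'   `filters`, `activation`, `optimizer`, `learning_rate` (each a vector
#'   of candidate values).
#' @param epochs epochs per trial (defaults to `config$epochs`).
#' @return the winning `morphovae_config` with attribute `trial_log`
#'   (a data frame over all trials).
#' @export
tune_hyperparameters <- function(dataset, config, split, budget_trials,
                                 search_space = NULL, epochs = NULL) {
  if (budget_trials < 1) {
    warning("budget_trials = 0; returning the base configuration")
    return(config)
  }
  sp <- list(
    n_layers = 1:5, filters = 16:128,
    activation = c("relu", "sigmoid", "tanh"),
    optimizer = c("sgd", "adam", "rmsprop"),
    learning_rate = NULL
  )
  sp[names(search_space)] <- search_space

  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(derive_seed(config$seed, 7))

  log_rows <- vector("list", budget_trials)
  best <- list(score = Inf, config = config)
  pick <- function(x, n = 1) x[sample.int(length(x), n, replace = TRUE)]
  for (t in seq_len(budget_trials)) {
    nl <- pick(sp$n_layers)
    ef <- pick(sp$filters, nl)
    df <- pick(sp$filters, nl)
    act <- pick(sp$activation)
    opt <- pick(sp$optimizer)
    lr <- if (is.null(sp$learning_rate)) {
      10^runif(1, -4, -2)
    } else {
      pick(sp$learning_rate)
    }
    cand <- try(
      morphovae_config(
        n_classes = config$n_classes, alpha = config$alpha,
        latent_dim = config$latent_dim, encoder_filters = ef,
        decoder_filters = df, activation = act, optimizer = opt,
        learning_rate = lr, batch_size = config$batch_size,
        epochs = as.integer(epochs %||% config$epochs),
        seed = derive_seed(config$seed, 200 + t),
        img_size = config$img_size, in_channels = config$in_channels
      ),
      silent = TRUE
    )
    if (inherits(cand, "try-error")) {
      log_rows[[t]] <- data.frame(
        trial = t, n_layers = nl, activation = act, optimizer = opt,
        learning_rate = lr, val_objective = NA_real_, status = "rejected"
      )
      next
    }
    m <- try(train_model(dataset, cand, split), silent = TRUE)
    if (inherits(m, "try-error")) {
      log_rows[[t]] <- data.frame(
        trial = t, n_layers = nl, activation = act, optimizer = opt,
        learning_rate = lr, val_objective = NA_real_, status = "diverged"
      )
      next
    }
    score <- min(m$history$val_objective)
    log_rows[[t]] <- data.frame(
      trial = t, n_layers = nl, activation = act, optimizer = opt,
      learning_rate = lr, val_objective = score, status = "ok"
    )
    if (score < best$score) best <- list(score = score, config = cand)
  }
  out <- best$config
  attr(out, "trial_log") <- do.call(rbind, log_rows)
  out
}

#' Sweep the latent dimensionality
#'
#' Repeats training at each candidate latent dimension and reports the
#' minimum validation `E_total` per run; used to justify the default of 3.
#'
#' @param dataset a `morphovae_dataset`.
#' @param dims integer vector of candidate dimensions (>= 2).
#' @param config base config.
#' @param n_repeats reshuffles per dimension.
#' @param epochs epochs per run.
#' @return data frame `dim`, `repeat_`, `min_val_objective`.
#' @export
sweep_latent_dim <- function(dataset, dims = 2:10, config, n_repeats = 3,
                             epochs = NULL) {
  manifest <- dataset_manifest(dataset)
  rows <- list()
  for (d in dims) {
    for (r in seq_len(n_repeats)) {
      cfg <- config
      cfg$latent_dim <- as.integer(d)
      cfg$seed <- derive_seed(config$seed, 5000 + 17 * d + r)
      if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
      split <- make_splits(manifest, seed = derive_seed(config$seed, 70 + r))
      m <- train_model(dataset, cfg, split)
      rows[[length(rows) + 1]] <- data.frame(
        dim = d, repeat_ = r, min_val_objective = min(m$history$val_objective)
      )
    }
  }
  do.call(rbind, rows)
}
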