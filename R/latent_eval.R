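# Latent-space evaluation: pairwise cluster separation index (CSI), the
# Davies-Bouldin aggregation, an RBF-SVM readout, reconstruction
# re-classification, the generative latent grid, and the PCA baseline.

#' Cluster separation statistics
#'
#' For labelled points, computes per-cluster centroids `x_G^i`, RMS
#' dispersions `delta_i = sqrt(mean ||x_k - x_G^i||^2)`, pairwise centroid
#' distances `Delta_ij`, and the separation index
#' `CSI_ij = (delta_i + delta_j) / Delta_ij`. `CSI_ij < 1` indicates that
#' clusters i and j are separated. With `dispersion = "mean"` the
#' dispersion is the mean (rather than RMS) distance, which matches the
#' convention of common reference implementations of the Davies-Bouldin
#' score.
#'
#' @param points numeric matrix, one row per point.
#' @param labels vector of cluster labels (>= 2 clusters, each >= 1 point).
#' @param dispersion `"rms"` (default) or `"mean"`.
#' @return object of class `cluster_stats`: `centroids`, `dispersions`,
#'   `centroid_dist`, and the symmetric `csi` matrix (diagonal `NaN`).
#'   Coincident centroids yield `Inf` entries with a warning.
#' @export
compute_csi <- function(points, labels, dispersion = c("rms", "mean")) {
  dispersion <- match.arg(dispersion)
  points <- as.matrix(points)
  labels <- factor(labels)
  k <- nlevels(labels)
  if (k < 2) stop("need at least 2 clusters")
  cents <- matrix(0, k, ncol(points), dimnames = list(levels(labels), NULL))
  delta <- numeric(k)
  for (i in seq_len(k)) {
    pi_ <- points[labels == levels(labels)[i], , drop = FALSE]
    cents[i, ] <- colMeans(pi_)
    d2 <- rowSums((pi_ - matrix(cents[i, ], nrow(pi_), ncol(points), byrow = TRUE))^2)
    delta[i] <- if (dispersion == "rms") sqrt(mean(d2)) else mean(sqrt(d2))
  }
  Delta <- as.matrix(stats::dist(cents))
  csi <- outer(delta, delta, "+") / Delta
  diag(csi) <- NaN
  if (any(is.infinite(csi))) {
    warning("coincident cluster centroids: infinite CSI reported")
  }
  dimnames(csi) <- list(levels(labels), levels(labels))
  structure(
    list(
      points = points, labels = labels, centroids = cents,
      dispersions = delta, centroid_dist = Delta, csi = csi,
      dispersion = dispersion
    ),
    class = "cluster_stats"
  )
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(
    "<cluster_stats> %d clusters, %d points (%s dispersion)\n",
    nrow(x$centroids), nrow(x$points), x$dispersion
  ))
  print(round(x$csi, 3))
  invisible(x)
}

#' Davies-Bouldin index
#'
#' `(1/k) * sum_i max_{j != i} CSI_ij`; with RMS dispersions this is the
#' Davies-Bouldin index with p = q = 2. A score below 1 indicates
#' well-separated clusters.
#'
#' @param stats a [compute_csi()] result.
#' @return scalar index.
#' @export
davies_bouldin <- function(stats) {
  stopifnot(inherits(stats, "cluster_stats"))
  k <- nrow(stats$centroids)
  stopifnot(k >= 2)
  r <- vapply(seq_len(k), function(i) max(stats$csi[i, -i]), 0)
  if (any(is.infinite(r))) warning("infinite CSI propagated into the index")
  mean(r)
}

# ---------------------------------------------------------------- SVM ---

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  exp(-gamma * (outer(an, bn, "+") - 2 * tcrossprod(a, b)))
}

# simplified SMO for a binary soft-margin SVM on a precomputed kernel
smo_binary <- function(K, y, C, tol, max_passes = 5, max_iter = 2000) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  fx <- function() as.numeric(K %*% (alpha * y)) + b
  passes <- 0
  iter <- 0
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1
    changed <- 0
    f <- fx()
    for (i in seq_len(n)) {
      Ei <- f[i] - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1, 1)
        if (j >= i) j <- j + 1
        Ej <- f[j] - y[j]
        ai <- alpha[i]
        aj <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj - ai)
          H <- min(C, C + aj - ai)
        } else {
          L <- max(0, ai + aj - C)
          H <- min(C, ai + aj)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        ajn <- min(max(aj - y[j] * (Ei - Ej) / eta, L), H)
        if (abs(ajn - aj) < 1e-6) next
        ain <- ai + y[i] * y[j] * (aj - ajn)
        b1 <- b - Ei - y[i] * (ain - ai) * K[i, i] - y[j] * (ajn - aj) * K[i, j]
        b2 <- b - Ej - y[i] * (ain - ai) * K[i, j] - y[j] * (ajn - aj) * K[j, j]
        b <- if (ain > 0 && ain < C) {
          b1
        } else if (ajn > 0 && ajn < C) {
          b2
        } else {
          (b1 + b2) / 2
        }
        alpha[i] <- ain
        alpha[j] <- ajn
        f <- fx()
        changed <- changed + 1
      }
    }
    passes <- if (changed == 0) passes + 1 else 0
  }
  list(alpha = alpha, b = b)
}

#' Fit a multi-class RBF-kernel SVM
#'
#' One-vs-one soft-margin SVMs trained by a simplified SMO solver; votes
#' decide the predicted class. Defaults follow the latent-space evaluation
#' protocol: regularization `C = 1`, stopping tolerance `1e-3`, kernel
#' coefficient `gamma = 1 / ncol(x)`.
#'
#' @param x numeric matrix of training points (rows).
#' @param y training labels.
#' @param C,tol,gamma SVM hyperparameters.
#' @param seed seed for the SMO working-pair choice.
#' @return object of class `svm_rbf`.
#' @export
svm_rbf_fit <- function(x, y, C = 1, tol = 1e-3, gamma = 1 / ncol(x), seed = 1) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("training set contains a single class")
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lv <- levels(y)
  pairs <- utils::combn(seq_along(lv), 2)
  models <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]
    bcl <- pairs[2, p]
    idx <- which(y %in% lv[c(a, bcl)])
    yy <- ifelse(y[idx] == lv[a], 1, -1)
    K <- rbf_kernel(x[idx, , drop = FALSE], x[idx, , drop = FALSE], gamma)
    fit <- smo_binary(K, yy, C, tol)
    models[[p]] <- list(idx = idx, y = yy, fit = fit, classes = c(a, bcl))
  }
  structure(
    list(x = x, levels = lv, gamma = gamma, models = models),
    class = "svm_rbf"
  )
}

#' @param object a fitted `svm_rbf`.
#' @param newdata matrix of points to classify.
#' @param ... unused.
#' @rdname svm_rbf_fit
#' @export
predict.svm_rbf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  votes <- matrix(0, nrow(newdata), length(object$levels))
  for (m in object$models) {
    Kt <- rbf_kernel(newdata, object$x[m$idx, , drop = FALSE], object$gamma)
    f <- as.numeric(Kt %*% (m$fit$alpha * m$y)) + m$fit$b
    win <- ifelse(f >= 0, m$classes[1], m$classes[2])
    votes[cbind(seq_len(nrow(newdata)), win)] <-
      votes[cbind(seq_len(nrow(newdata)), win)] + 1
  }
  factor(object$levels[max.col(votes, ties.method = "first")],
    levels = object$levels
  )
}

#' SVM classification accuracy in the latent space
#'
#' Fits the RBF-kernel SVM (radial basis function kernel, regularization
#' 1.0, stopping tolerance 0.001, kernel coefficient `1/latent_dim`) on
#' the training points only and reports the fraction of correctly
#' classified test points — a measure of cluster separation.
#'
#' @param train_points,test_points latent point matrices (rows).
#' @param train_labels,test_labels labels.
#' @param latent_dim latent dimensionality (sets the kernel coefficient).
#' @return accuracy in `[0, 1]`.
#' @export
svm_latent_accuracy <- function(train_points, train_labels, test_points,
                                test_labels, latent_dim = ncol(as.matrix(train_points))) {
  fit <- svm_rbf_fit(train_points, train_labels,
    C = 1, tol = 1e-3,
    gamma = 1 / latent_dim
  )
  pred <- predict(fit, test_points)
  mean(as.character(pred) == as.character(test_labels))
}

# -------------------------------------------------- reconstruction QC ---

model_accuracy <- function(model, x4, labels) {
  z <- encode_batch(model, x4)$mu
  pred <- model$label_levels[max.col(t(classify(model, z)))]
  mean(pred == as.character(labels))
}

#' Classifier accuracy on originals vs. their reconstructions
#'
#' Each input is deterministically encoded and classified; then the
#' reconstruction `decode(encode(x))` is re-input and classified again. A
#' small gap indicates that reconstruction preserves the class-relevant
#' morphology.
#'
#' @param model trained [morphovae_model()].
#' @param triplets `(H, W, 3, N)` array (or a `morphovae_dataset`).
#' @param labels true labels (taken from the dataset if omitted).
#' @return named vector `c(original_acc, reconstructed_acc)`.
#' @export
reclassification_accuracy <- function(model, triplets, labels = NULL) {
  if (inherits(triplets, "morphovae_dataset")) {
    labels <- labels %||% triplets$labels
    triplets <- triplets$triplets
  }
  stopifnot(!is.null(labels))
  orig <- model_accuracy(model, triplets, labels)
  z <- encode_batch(model, triplets)$mu
  recon <- decode_batch(model, z)
  rec <- model_accuracy(model, recon, labels)
  c(original_acc = orig, reconstructed_acc = rec)
}

# ------------------------------------------------------- latent grid ----

#' Generative latent grid on the principal plane
#'
#' Computes the principal axes of the latent points, lays a grid over the
#' data's bounding box in the PC1-PC2 plane (expanded 10%) at PC3 = 0,
#' decodes every grid node and classifies it; data points are projected
#' onto the plane with their |PC3| distances recorded (for size-coded
#' plotting).
#'
#' @param model trained model.
#' @param latent_points `N x d` matrix of latent points (>= 3).
#' @param grid_size nodes per side.
#' @param expand bounding-box expansion fraction.
#' @return object of class `grid_panel`.
#' @export
latent_pca_grid <- function(model, latent_points, grid_size = 7, expand = 0.1) {
  latent_points <- as.matrix(latent_points)
  if (nrow(latent_points) < 3) stop("need at least 3 latent points")
  if (all(apply(latent_points, 2, sd) < 1e-12)) {
    stop("degenerate latent covariance: all points coincide")
  }
  pc <- prcomp(latent_points, center = TRUE, scale. = FALSE)
  scores <- pc$x
  r1 <- range(scores[, 1])
  r2 <- range(scores[, 2])
  pad1 <- diff(r1) * expand
  pad2 <- diff(r2) * expand
  g1 <- seq(r1[1] - pad1, r1[2] + pad1, length.out = grid_size)
  g2 <- seq(r2[1] - pad2, r2[2] + pad2, length.out = grid_size)
  nodes2 <- cbind(rep(g1, each = grid_size), rep(g2, times = grid_size))
  zeta <- t(nodes2 %*% t(pc$rotation[, 1:2])) + pc$center # d x G, PC3 = 0
  imgs <- decode_batch(model, zeta)
  node_probs <- classify(model, zeta)
  node_labels <- max.col(t(node_probs))
  dist3 <- if (ncol(scores) >= 3) abs(scores[, 3]) else rep(0, nrow(scores))
  structure(
    list(
      basis = pc$rotation[, 1:2], center = pc$center,
      sdev = pc$sdev, grid1 = g1, grid2 = g2, images = imgs,
      node_labels = node_labels, scores = scores[, 1:2, drop = FALSE],
      point_dist = dist3
    ),
    class = "grid_panel"
  )
}

#' @export
print.grid_panel <- function(x, ...) {
  cat(sprintf(
    "<grid_panel> %dx%d nodes; PC1/PC2 contribution %.1f%% / %.1f%%\n",
    length(x$grid1), length(x$grid2),
    100 * x$sdev[1]^2 / sum(x$sdev^2), 100 * x$sdev[2]^2 / sum(x$sdev^2)
  ))
  invisible(x)
}

#' Plot a latent grid panel
#'
#' Base-graphics montage of the decoded x-projection channel at every grid
#' node, with projected data points overlaid.
#'
#' @param x a `grid_panel`.
#' @param channel image channel to show (1 = x projection).
#' @param ... unused.
#' @export
plot.grid_panel <- function(x, channel = 1, ...) {
  n1 <- length(x$grid1)
  n2 <- length(x$grid2)
  d1 <- diff(x$grid1[1:2])
  d2 <- diff(x$grid2[1:2])
  plot(NA,
    xlim = range(x$grid1) + c(-d1, d1) / 2, ylim = range(x$grid2) + c(-d2, d2) / 2,
    xlab = "PC1", ylab = "PC2", asp = NA
  )
  g <- 0
  for (j in seq_len(n2)) {
    for (i in seq_len(n1)) {
      g <- g + 1
      img <- x$images[, , channel, g]
      graphics::rasterImage(
        as.raster(1 - t(img)[, rev(seq_len(nrow(img)))]),
        x$grid1[i] - d1 / 2, x$grid2[j] - d2 / 2,
        x$grid1[i] + d1 / 2, x$grid2[j] + d2 / 2
      )
    }
  }
  graphics::points(x$scores[, 1], x$scores[, 2],
    pch = 21, bg = "tomato",
    cex = 0.5 + x$point_dist / max(c(x$point_dist, 1e-9))
  )
  invisible(x)
}

# ---------------------------------------------------------- baselines ---

#' Pixel-PCA baseline embedding
#'
#' Flattens each projection triplet to a pixel vector, fits PCA (mean
#' centering, no scaling) on the training images and projects train and
#' test images onto the top `k` components — the linear baseline the
#' supervised latent space is compared against.
#'
#' @param train_x4 training images `(H, W, C, N)`.
#' @param test_x4 optional test images.
#' @param k number of components (default 3).
#' @return list with `train_scores`, `test_scores`, `rotation`, `center`,
#'   `sdev`.
#' @export
pca_baseline <- function(train_x4, test_x4 = NULL, k = 3) {
  flat <- function(x4) {
    d <- dim(x4)
    t(matrix(x4, prod(d[1:3]), d[4]))
  }
  xtr <- flat(train_x4)
  pc <- prcomp(xtr, center = TRUE, scale. = FALSE, rank. = k)
  out <- list(
    train_scores = pc$x[, 1:k, drop = FALSE],
    rotation = pc$rotation, center = pc$center, sdev = pc$sdev
  )
  if (!is.null(test_x4)) {
    xte <- flat(test_x4)
    out$test_scores <- sweep(xte, 2, pc$center) %*% pc$rotation
  }
  out
}
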