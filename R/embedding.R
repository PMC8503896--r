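# Patch embedding: deep features, 2-D layout, diverse selection.
#
# The 2-D layout exists so an annotator (simulated here) can pick patches
# spread across the model's feature space instead of annotating near
# duplicates. The projector is a compact seeded neighbor embedding in the
# spirit of UMAP/LargeVis: a fuzzy k-nearest-neighbor graph in feature
# space, PCA initialization, then attraction along graph edges and
# repulsion against sampled non-neighbors.

#' Deep feature vectors for patches
#'
#' One fixed-length vector per patch: the channel-wise global average of the
#' deepest encoder (bottleneck) activations, i.e. the most compressed
#' representation the network has learned. Requires a model that has at
#' least been pretrained, since untrained features carry no structure.
#'
#' @param model a `seg_model`, stage `"pretrained"` or `"finetuned"`.
#' @param patches list of patches or pixel arrays.
#' @return numeric matrix (patches x channels); row names are patch ids
#'   when available.
#' @export
extract_features <- function(model, patches) {
  stopifnot(inherits(model, "seg_model"))
  if (model$stage == "untrained")
    stop_value("features require a pretrained or finetuned model, got stage 'untrained'")
  px <- as_pixel_list(patches)
  feats <- t(vapply(px, function(x) {
    b <- unet_capture(model, x, "bottleneck")$bottleneck
    apply(b, 4L, mean)
  }, numeric(model$config$base_width * 2^(model$config$depth - 1L))))
  ids <- vapply(seq_along(patches), function(i) {
    p <- patches[[i]]
    if (is.list(p) && !is.null(p$patch_id)) p$patch_id else sprintf("patch_%04d", i)
  }, character(1))
  rownames(feats) <- ids
  feats
}

# Fit the low-dimensional similarity curve 1 / (1 + a d^(2b)) so that it is
# ~1 below min_dist and decays like exp(-(d - min_dist)) beyond it.
fit_ab <- function(min_dist) {
  d <- seq(0.05, 3, by = 0.05)
  target <- ifelse(d <= min_dist, 1, exp(-(d - min_dist)))
  obj <- function(p) sum((1 / (1 + p[1] * d^(2 * p[2])) - target)^2)
  optim(c(1.6, 0.9), obj, method = "L-BFGS-B", lower = c(1e-3, 1e-3))$par
}

#' Project patch features to a 2-D layout
#'
#' Lays the patches out in two dimensions so that patches the model
#' considers similar land near each other. Deterministic for a fixed seed.
#'
#' @param features numeric matrix (patches x dims), e.g. from
#'   [extract_features()].
#' @param seed integer RNG seed (mandatory for reproducible layouts).
#' @param n_neighbors neighborhood size of the kNN graph.
#' @param min_dist distance below which embedded neighbors are considered
#'   "as close as needed"; smaller values give tighter clumps.
#' @param n_epochs optimization epochs.
#' @return data frame with columns `patch_id`, `x`, `y`.
#' @export
project_2d <- function(features, seed, n_neighbors = 10L, min_dist = 0.1,
                       n_epochs = 200L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2L) stop_value("projection requires at least 2 feature vectors, got %d", n)
  if (!all(is.finite(features))) stop_value("features must be finite")
  k <- max(1L, min(n_neighbors, n - 1L))
  D <- as.matrix(dist(features))
  # fuzzy kNN weights: local scale from the kth neighbor, offset by the
  # nearest neighbor so every point keeps at least one strong edge
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ds <- sort(D[i, -i])
    rho <- ds[1L]; sig <- max(ds[k] - rho, 1e-8)
    nb <- order(D[i, ])[2:(k + 1L)]
    W[i, nb] <- exp(-pmax(0, D[i, nb] - rho) / sig)
  }
  W <- W + t(W) - W * t(W)
  ab <- fit_ab(min_dist)
  a <- ab[1L]; b <- ab[2L]
  with_seed(seed, {
    # PCA init, sign-fixed so the layout does not depend on LAPACK sign choices
    pc <- prcomp(features, rank. = 2L, center = TRUE, scale. = FALSE)
    Y <- pc$x
    if (ncol(Y) < 2L) Y <- cbind(Y, 0)
    for (j in 1:2) {
      v <- pc$rotation[, min(j, ncol(pc$rotation))]
      if (v[which.max(abs(v))] < 0) Y[, j] <- -Y[, j]
    }
    Y <- Y / max(sd(Y[, 1L]), 1e-8)
    edges <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
    ew <- W[edges]
    n_neg <- 5L
    for (ep in seq_len(n_epochs)) {
      alpha <- 0.05 * (1 - (ep - 1) / n_epochs)
      ord <- sample.int(nrow(edges))
      for (e in ord) {
        i <- edges[e, 1L]; j <- edges[e, 2L]
        dy <- Y[i, ] - Y[j, ]
        d2 <- sum(dy^2)
        # attraction along the edge
        gr <- (-2 * a * b * d2^(b - 1) / (1 + a * d2^b)) * dy * ew[e]
        gr <- pmin(4, pmax(-4, gr))
        Y[i, ] <- Y[i, ] + alpha * gr
        Y[j, ] <- Y[j, ] - alpha * gr
        # repulsion from sampled non-neighbors
        for (s in sample.int(n, n_neg, replace = TRUE)) {
          if (s == i) next
          dy <- Y[i, ] - Y[s, ]
          d2 <- sum(dy^2)
          gr <- (2 * b / ((0.001 + d2) * (1 + a * d2^b))) * dy
          gr <- pmin(4, pmax(-4, gr))
          Y[i, ] <- Y[i, ] + alpha * gr
        }
      }
    }
    data.frame(patch_id = rownames(features) %||% sprintf("patch_%04d", seq_len(n)),
               x = Y[, 1L], y = Y[, 2L])
  })
}

#' Select dispersed patches by farthest-point sampling
#'
#' Greedy max-min selection in the 2-D layout: the first pick is seeded
#' uniformly at random, every further pick maximizes the minimum distance
#' to the picks so far (ties broken by lowest index). This automates the
#' "annotate dispersed patches" policy and carries the classical factor-2
#' guarantee on the minimum pairwise distance of the selected set.
#'
#' @param points data frame from [project_2d()] (columns `patch_id`, `x`,
#'   `y`) or a numeric matrix with row names.
#' @param k number of patches to select, `1 <= k <= n`.
#' @param seed RNG seed for the first pick.
#' @return character vector of `k` unique patch ids.
#' @export
select_diverse <- function(points, k, seed = 1L) {
  if (is.data.frame(points)) {
    ids <- points$patch_id
    xy <- as.matrix(points[, c("x", "y")])
  } else {
    xy <- as.matrix(points)
    ids <- rownames(xy) %||% sprintf("patch_%04d", seq_len(nrow(xy)))
  }
  n <- nrow(xy)
  if (k < 1L || k > n) stop_value("k must be in 1..%d, got %s", n, k)
  with_seed(seed, {
    sel <- integer(k)
    sel[1L] <- sample.int(n, 1L)
    if (k > 1L) {
      mind <- sqrt(colSums((t(xy) - xy[sel[1L], ])^2))
      for (j in 2:k) {
        mind[sel[seq_len(j - 1L)]] <- -Inf
        sel[j] <- which.max(mind)
        mind <- pmin(mind, sqrt(colSums((t(xy) - xy[sel[j], ])^2)))
      }
    }
    ids[sel]
  })
}
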