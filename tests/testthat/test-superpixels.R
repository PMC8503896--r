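# SLIC-style superpixels: partition/connectivity invariants, boundary
# recall, annotation snapping, DL-feature mode.

sp_partition_ok <- function(sp) {
  lab <- sp$labels
  L <- max(lab) + 1L
  # consecutive 0..L-1, every pixel labeled
  all(sort(unique(as.vector(lab))) == 0:(L - 1L)) &&
    # every label connected (4-connectivity)
    max(histannot:::label_components_int(lab + 1L, 4L)) == L
}

test_that("superpixel maps are connected partitions near the requested count", {
  sc <- small_scene()
  sp <- compute_superpixels(sc$image, n_segments = 64, seed = 1)
  expect_s3_class(sp, "superpixel_map")
  expect_identical(sp$source, "intensity")
  expect_true(sp_partition_ok(sp))
  L <- max(sp$labels) + 1L
  expect_gte(L, 64 / 2); expect_lte(L, 64 * 2)
  # constant image: clustering degenerates to a near-regular grid partition
  flat <- array(0.5, c(64, 64, 3))
  spf <- compute_superpixels(flat, n_segments = 16, seed = 1)
  expect_true(sp_partition_ok(spf))
  # single segment covers the image
  sp1 <- compute_superpixels(flat, n_segments = 1, seed = 1)
  expect_identical(unique(as.vector(sp1$labels)), 0L)
  expect_error(compute_superpixels(flat, n_segments = 1e6), "exceeds pixel count")
})

test_that("superpixel computation is deterministic for a fixed seed", {
  sc <- small_scene()
  a <- compute_superpixels(sc$image, n_segments = 32, seed = 4)
  b <- compute_superpixels(sc$image, n_segments = 32, seed = 4)
  expect_identical(a$labels, b$labels)
})

test_that("boundary recall matches the exhaustive oracle on toy rasters", {
  # hand-built 8x8: superpixels split at column 4, gt blob in the corner
  lab <- matrix(0L, 8, 8); lab[, 5:8] <- 1L
  sp <- structure(list(labels = lab, source = "intensity",
                       n_segments_requested = 2L, compactness = 1),
                  class = "superpixel_map")
  set.seed(12)
  for (trial in 1:8) {
    gt <- matrix(0L, 8, 8)
    gt[sample(3:6, 1):sample(7:8, 1), sample(1:3, 1):sample(4:8, 1)] <- 1L
    for (tol in 0:3) {
      expect_equal(boundary_recall(sp, gt, tol),
                   oracle_boundary_recall(lab, gt, tol),
                   info = sprintf("trial %d tol %d", trial, tol))
    }
  }
  # superpixel boundaries covering every gt boundary: recall 1
  gt2 <- matrix(0L, 8, 8); gt2[, 5:8] <- 1L
  expect_equal(boundary_recall(sp, gt2, 0), 1)
  # gt boundary far beyond tolerance: recall 0
  lab_far <- matrix(0L, 16, 16); lab_far[, 9:16] <- 1L
  sp_far <- structure(list(labels = lab_far, source = "intensity",
                           n_segments_requested = 2L, compactness = 1),
                      class = "superpixel_map")
  gt3 <- matrix(0L, 16, 16); gt3[1:3, 1:3] <- 1L
  expect_equal(boundary_recall(sp_far, gt3, 1), 0)
  # empty reference boundary: undefined, not zero
  expect_warning(r <- boundary_recall(sp, matrix(0L, 8, 8), 2), "undefined")
  expect_true(is.na(r))
})

test_that("annotation snapping selects whole superpixels idempotently", {
  sc <- small_scene()
  sp <- compute_superpixels(sc$image, n_segments = 25, seed = 2)
  lab <- sp$labels
  one <- snap_annotation(cbind(10, 10), sp)
  expect_identical(one, lab == lab[10, 10])
  # duplicate seeds change nothing
  expect_identical(snap_annotation(rbind(c(10, 10), c(10, 10)), sp), one)
  # seeds touching every label select the full image
  pick <- do.call(rbind, lapply(0:max(lab), function(l) {
    i <- which(lab == l)[1]
    c((i - 1) %% nrow(lab) + 1, (i - 1) %/% nrow(lab) + 1)
  }))
  expect_true(all(snap_annotation(pick, sp)))
  expect_error(snap_annotation(matrix(numeric(0), 0, 2), sp), "at least one")
  expect_error(snap_annotation(cbind(0, 5), sp), "out of bounds")
})

test_that("DL-feature superpixels adhere to structure boundaries at least as well as intensity", {
  # train one compact model per seed on a small scene, then compare
  # boundary recall of feature-space vs color-space superpixels (sign test)
  wins <- 0; losses <- 0; diffs <- numeric(0)
  for (s in 1:5) {
    sc <- generate_scene("nuclei", 256, 256, density = 250, seed = 200 + s)
    tile <- structure(list(pixels = sc$image, tile_id = "t", origin = c(0L, 0L),
                           valid = matrix(TRUE, 256, 256), mask = NULL,
                           gt_instances = sc$gt_instances), class = "tile")
    ps <- extract_patches(tile, 128L)
    for (i in seq_along(ps))
      ps[[i]]$mask <- ifelse(ps[[i]]$gt_instances > 0L, MASK_POSITIVE, MASK_NEGATIVE)
    m <- build_model(model_config(depth = 4, base_width = 4, patch_size = 128,
                                  init_seed = s))
    m <- pretrain_autoencoder(m, ps, epochs = 3, seed = s)
    m <- finetune(m, ps, epochs = 20, seed = s, batch_size = 2)
    gt <- sc$gt_instances > 0L
    fmap <- dl_feature_map(m, sc$image, patch_size = 128)
    sp_int <- compute_superpixels(sc$image, n_segments = 150, seed = s)
    sp_dl <- compute_superpixels(sc$image, feature_map = fmap,
                                 n_segments = 150, seed = s)
    expect_identical(sp_dl$source, "dl_features")
    expect_true(sp_partition_ok(sp_dl))
    br_i <- boundary_recall(sp_int, gt, 2)
    br_d <- boundary_recall(sp_dl, gt, 2)
    diffs <- c(diffs, br_d - br_i)
    if (br_d > br_i) wins <- wins + 1 else if (br_d < br_i) losses <- losses + 1
  }
  # one-sided sign test at alpha 0.05 over the informative seeds
  if (wins + losses > 0) {
    p <- binom.test(wins, wins + losses, alternative = "greater")$p.value
    expect_lt(p, 0.05)
  }
  expect_gte(median(diffs), 0)
})
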