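# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; fixtures are cached per session so expensive objects
# (scenes, trained models) are built once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small nuclei scene used across modules
small_scene <- function(seed = 42) {
  fixture(paste0("scene", seed), function()
    generate_scene("nuclei", 256, 256, density = 250, seed = seed))
}

# a tiny but real model configuration that trains in seconds
tiny_cfg <- function(...) model_config(depth = 3L, base_width = 2L,
                                       patch_size = 64L, init_seed = 7L, ...)

# fully annotated 64 px patches from a small scene
tiny_patches <- function(n = 8L, seed = 42) {
  fixture(paste0("tinypatches", n, "_", seed), function() {
    sc <- small_scene(seed)
    tile <- structure(list(pixels = sc$image, tile_id = "fx", origin = c(0L, 0L),
                           valid = matrix(TRUE, 256, 256), mask = NULL,
                           gt_instances = sc$gt_instances), class = "tile")
    ps <- extract_patches(tile, 64L)
    for (i in seq_along(ps)) {
      gt <- ps[[i]]$gt_instances > 0L
      ps[[i]]$gt_bin <- gt
      ps[[i]]$mask_full <- ifelse(gt, MASK_POSITIVE, MASK_NEGATIVE)
    }
    ps[seq_len(min(n, length(ps)))]
  })
}

# pretrained tiny model shared by feature/superpixel tests
tiny_pretrained <- function() {
  fixture("tiny_pretrained", function() {
    ps <- tiny_patches(8L)
    m <- build_model(tiny_cfg())
    pretrain_autoencoder(m, ps, epochs = 2L, seed = 1L)
  })
}

# ---- independent oracles ----------------------------------------------------

# f-score by direct confusion-table counting
oracle_f_score <- function(mask, ref) {
  m <- as.logical(mask); r <- as.logical(ref)
  tp <- sum(m & r); fp <- sum(m & !r); fn <- sum(!m & r)
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# brute-force farthest-point: greedy max-min with seeded first pick,
# implemented independently with explicit distance recomputation
oracle_maxmin_select <- function(xy, k, first) {
  n <- nrow(xy)
  sel <- first
  while (length(sel) < k) {
    best <- -1; bi <- NA
    for (i in setdiff(seq_len(n), sel)) {
      di <- min(sapply(sel, function(s) sqrt(sum((xy[i, ] - xy[s, ])^2))))
      if (di > best + 1e-12) { best <- di; bi <- i }
    }
    sel <- c(sel, bi)
  }
  sel
}

# exhaustive boundary recall on toy rasters: pixel-by-pixel distance check
oracle_boundary_recall <- function(sp_labels_0based, gt, tol) {
  lab <- sp_labels_0based + 1L
  H <- nrow(lab); W <- ncol(lab)
  is_b <- function(M, i, j) {
    v <- M[i, j]
    (i > 1 && M[i - 1, j] != v) || (i < H && M[i + 1, j] != v) ||
      (j > 1 && M[i, j - 1] != v) || (j < W && M[i, j + 1] != v)
  }
  gtm <- matrix(as.integer(as.logical(gt)), H, W)
  gtb <- spb <- matrix(FALSE, H, W)
  for (i in 1:H) for (j in 1:W) {
    gtb[i, j] <- gtm[i, j] == 1L && is_b(gtm, i, j)
    spb[i, j] <- is_b(lab, i, j)
  }
  if (!any(gtb)) return(NA_real_)
  if (!any(spb)) return(0)
  spc <- which(spb, arr.ind = TRUE)
  hits <- 0
  for (p in which(gtb)) {
    i <- (p - 1) %% H + 1; j <- (p - 1) %/% H + 1
    d <- min(sqrt((spc[, 1] - i)^2 + (spc[, 2] - j)^2))
    if (d <= tol) hits <- hits + 1
  }
  hits / sum(gtb)
}

# closed-form parameter count of the configured network, summed layer by
# layer (independent of the builder)
oracle_param_count <- function(depth, base_width, in_ch = 3L, out_ch = 2L,
                               upsample = "nearest") {
  ch <- base_width * 2^(0:(depth - 1))
  conv3 <- function(i, o) 9 * i * o + o
  total <- 0
  cin <- in_ch
  for (l in seq_len(depth)) {
    total <- total + conv3(cin, ch[l]) + conv3(ch[l], ch[l])
    cin <- ch[l]
  }
  for (l in rev(seq_len(depth - 1))) {
    total <- total + if (upsample == "nearest") cin * ch[l] + ch[l]
                     else 4 * cin * ch[l] + ch[l]
    total <- total + conv3(2 * ch[l], ch[l]) + conv3(ch[l], ch[l])
    cin <- ch[l]
  }
  total + cin * out_ch + out_ch
}

# expand an H x W logical mask across the 3 channels of an H x W x 3 array
abind_mask <- function(m) {
  array(rep(m, 3L), dim = c(dim(m), 3L))
}
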