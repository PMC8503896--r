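# Synthetic histology-like scenes with ground-truth instance masks.
#
# Three structure scales are emulated so that every downstream stage (patch
# extraction, training, review simulation, metrics) can run without external
# slides: many small elliptical blobs (nuclei scale), mid-size annular
# structures with lumens (tubule scale), and large irregular regions from a
# thresholded smooth noise field (epithelium scale). The scenes make no
# attempt at photorealism; they provide color-separable foreground structure
# at controlled density, size, and noise.

#' Default stain palette for synthetic scenes
#'
#' A two-color scheme loosely following hematoxylin/eosin: purple foreground
#' structures on a pink background. The generator is agnostic to the palette;
#' any pair whose mean channel intensities differ by at least the configured
#' margin is accepted.
#'
#' @param background,foreground RGB triples in \[0, 1\].
#' @param jitter half-width of the uniform per-instance color perturbation.
#' @return a list with elements `background`, `foreground`, `jitter`.
#' @export
scene_palette <- function(background = c(0.93, 0.80, 0.86),
                          foreground = c(0.48, 0.33, 0.60),
                          jitter = 0.05) {
  stopifnot(length(background) == 3L, length(foreground) == 3L)
  list(background = clamp01(background), foreground = clamp01(foreground),
       jitter = jitter)
}

scene_kinds <- c("nuclei", "tubules", "epithelium")

default_density <- function(kind) {
  switch(kind, nuclei = 300, tubules = 12, epithelium = 8)
}

#' Generate a synthetic histology scene
#'
#' Draws structures of the requested scale into an RGB raster and returns the
#' image together with a ground-truth instance raster. Instances are drawn in
#' order and later instances overwrite earlier ones, so the ground truth is a
#' partition; after drawing, each instance is reduced to its largest
#' 4-connected part and instances below `min_size` pixels are removed, then
#' ids are renumbered consecutively 1..K.
#'
#' @param structure_kind one of `"nuclei"` (ellipses, semi-axes 4-12 px),
#'   `"tubules"` (annuli with lumens, outer semi-axes 20-60 px), or
#'   `"epithelium"` (thresholded smoothed noise field yielding large
#'   irregular regions).
#' @param height,width scene size in pixels (>= 256).
#' @param density expected structures per megapixel; defaults per kind
#'   (300 nuclei, 12 tubules, 8 epithelium regions). For nuclei and tubules
#'   the instance count is Poisson with this intensity; for epithelium the
#'   density sets the correlation length of the noise field, so the realized
#'   count is only approximately proportional.
#' @param seed integer RNG seed; identical arguments give bit-identical
#'   scenes.
#' @param noise noise amplitude in \[0, 1\]; additive Gaussian pixel noise
#'   with standard deviation `0.25 * noise`.
#' @param palette see [scene_palette()].
#' @param margin required minimum difference in mean channel intensity
#'   between foreground and background colors.
#' @param min_size minimum instance area in pixels.
#' @return an object of class `synthetic_scene`: a list with `image`
#'   (H x W x 3 array in \[0, 1\]), `gt_instances` (integer H x W matrix,
#'   0 = background), `structure_kind`, `seed`, and `params`.
#' @export
#' @examples
#' sc <- generate_scene("nuclei", 256, 256, density = 100, seed = 1)
#' max(sc$gt_instances) # number of instances
generate_scene <- function(structure_kind, height = 1024L, width = 1024L,
                           density = NULL, seed = 1L, noise = 0.3,
                           palette = scene_palette(), margin = 0.15,
                           min_size = 10L) {
  structure_kind <- match.arg(structure_kind, scene_kinds)
  if (!is.numeric(height) || !is.numeric(width) || height <= 0 || width <= 0)
    stop_value("height and width must be positive")
  if (height < 256 || width < 256)
    stop_value("scene dimensions must be >= 256 px, got %dx%d", height, width)
  density <- density %||% default_density(structure_kind)
  check_scalar_number(density, "density", lower = 0)
  check_scalar_number(noise, "noise", lower = 0, upper = 1)
  height <- as.integer(height); width <- as.integer(width)
  sep <- abs(mean(palette$background) - mean(palette$foreground))
  if (sep < margin)
    stop_value("palette separation %.3f is below the required margin %.3f", sep, margin)

  with_seed(seed, {
    ids <- switch(structure_kind,
      nuclei = draw_ellipses(height, width, density, r_range = c(4, 12)),
      tubules = draw_annuli(height, width, density, r_outer = c(20, 60),
                            lumen_frac = c(0.4, 0.6)),
      epithelium = draw_noise_regions(height, width, density, min_size))
    ids <- enforce_instance_invariants(ids, min_size)
    K <- max(ids)
    img <- paint_scene(ids, K, palette, noise)
    structure(list(
      image = img,
      gt_instances = ids,
      structure_kind = structure_kind,
      seed = as.integer(seed),
      params = list(density = density, noise = noise, palette = palette,
                    margin = margin, min_size = as.integer(min_size),
                    expected_count = density * height * width / 1e6,
                    n_instances = K)
    ), class = "synthetic_scene")
  })
}

# Rasterize one filled ellipse into `ids` (later draws win).
stamp_ellipse <- function(ids, id, cy, cx, a, b, theta,
                          hole_frac = NA_real_) {
  H <- nrow(ids); W <- ncol(ids)
  r <- ceiling(max(a, b))
  ylo <- max(1L, floor(cy - r)); yhi <- min(H, ceiling(cy + r))
  xlo <- max(1L, floor(cx - r)); xhi <- min(W, ceiling(cx + r))
  if (ylo > yhi || xlo > xhi) return(ids)
  dy <- (ylo:yhi) - cy
  dx <- (xlo:xhi) - cx
  u <- outer(dy, dx, function(y, x) (x * cos(theta) + y * sin(theta)))
  v <- outer(dy, dx, function(y, x) (-x * sin(theta) + y * cos(theta)))
  e <- (u / a)^2 + (v / b)^2
  inside <- e <= 1
  if (!is.na(hole_frac)) inside <- inside & (e > hole_frac^2)
  sub <- ids[ylo:yhi, xlo:xhi, drop = FALSE]
  sub[inside] <- id
  ids[ylo:yhi, xlo:xhi] <- sub
  ids
}

draw_ellipses <- function(H, W, density, r_range) {
  n <- rpois(1L, density * H * W / 1e6)
  ids <- matrix(0L, H, W)
  if (n == 0L) return(ids)
  cy <- runif(n, 1, H); cx <- runif(n, 1, W)
  a <- runif(n, r_range[1], r_range[2])
  b <- runif(n, r_range[1], r_range[2])
  th <- runif(n, 0, pi)
  for (i in seq_len(n)) ids <- stamp_ellipse(ids, i, cy[i], cx[i], a[i], b[i], th[i])
  ids
}

draw_annuli <- function(H, W, density, r_outer, lumen_frac) {
  n <- rpois(1L, density * H * W / 1e6)
  ids <- matrix(0L, H, W)
  if (n == 0L) return(ids)
  cy <- runif(n, 1, H); cx <- runif(n, 1, W)
  a <- runif(n, r_outer[1], r_outer[2])
  b <- a * runif(n, 0.8, 1)
  th <- runif(n, 0, pi)
  hole <- runif(n, lumen_frac[1], lumen_frac[2])
  for (i in seq_len(n))
    ids <- stamp_ellipse(ids, i, cy[i], cx[i], a[i], b[i], th[i], hole_frac = hole[i])
  ids
}

# Bilinearly upsample a coarse Gaussian grid and threshold it. The grid
# spacing scales with 1/sqrt(density) so that higher densities give more,
# smaller regions; roughly a third of the area is foreground.
draw_noise_regions <- function(H, W, density, min_size, coverage = 0.35) {
  if (density == 0) return(matrix(0L, H, W))
  len <- max(16, sqrt(1e6 / density) / 3.2)
  gh <- ceiling(H / len) + 2L
  gw <- ceiling(W / len) + 2L
  g <- matrix(rnorm(gh * gw), gh, gw)
  field <- bilinear_upsample_grid(g, H, W, len)
  thr <- quantile(field, 1 - coverage)
  lab <- label_components(field >= thr, connectivity = 4L)
  lab
}

# Interpolation from grid nodes (spacing `len`, node 1 at pixel 1) to pixels.
bilinear_upsample_grid <- function(g, H, W, len) {
  interp_mat <- function(n, gn) {
    pos <- (seq_len(n) - 1) / len + 1
    i0 <- pmin(floor(pos), gn - 1)
    w1 <- pos - i0
    M <- matrix(0, n, gn)
    M[cbind(seq_len(n), i0)] <- 1 - w1
    M[cbind(seq_len(n), i0 + 1)] <- w1
    M
  }
  interp_mat(H, nrow(g)) %*% g %*% t(interp_mat(W, ncol(g)))
}

# Keep each instance's largest 4-connected part, drop small instances,
# renumber consecutively by first occurrence.
enforce_instance_invariants <- function(ids, min_size) {
  if (max(ids) == 0L) return(ids)
  parts <- label_components_int(ids, connectivity = 4L)
  np <- max(parts)
  if (np == 0L) return(matrix(0L, nrow(ids), ncol(ids)))
  sizes <- tabulate(parts, nbins = np)
  sel <- parts > 0L
  # parent instance id of each part
  first_px <- match(seq_len(np), parts)
  parent <- ids[first_px]
  keep <- logical(np)
  for (p in split(seq_len(np), parent)) keep[p[which.max(sizes[p])]] <- TRUE
  keep <- keep & sizes >= max(min_size, 1L)
  relab <- integer(np)
  relab[keep] <- seq_len(sum(keep))
  out <- matrix(0L, nrow(ids), ncol(ids))
  out[sel] <- relab[parts[sel]]
  out
}

paint_scene <- function(ids, K, palette, noise) {
  H <- nrow(ids); W <- ncol(ids)
  fg <- ids > 0L
  img <- array(0, dim = c(H, W, 3L))
  if (K > 0L) {
    jit <- matrix(runif(3L * K, -palette$jitter, palette$jitter), K, 3L)
    cols <- sweep(jit, 2L, palette$foreground, `+`)
    cols <- clamp01(cols)
  }
  for (ch in 1:3) {
    v <- matrix(palette$background[ch], H, W)
    if (K > 0L) v[fg] <- cols[ids[fg], ch]
    img[, , ch] <- v
  }
  if (noise > 0)
    img <- clamp01(img + array(rnorm(length(img), 0, 0.25 * noise), dim = dim(img)))
  img
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %s, %dx%d px, %d instances (seed %d)\n",
              x$structure_kind, nrow(x$gt_instances), ncol(x$gt_instances),
              x$params$n_instances, x$seed))
  invisible(x)
}

#' Cut a scene into tiles with ground-truth masks
#'
#' Tiles cover the scene exactly once. When the scene dimensions are not a
#' multiple of `tile_size` the canvas is reflect-padded (mirrored without
#' edge duplication, avoiding boundary artifacts in training) and padded
#' pixels are flagged in each tile's `valid` raster. Each tile carries the
#' binarized ground truth as a fully annotated mask: instance pixels are
#' positive, the rest negative, with no unknown pixels.
#'
#' @param scene a `synthetic_scene`.
#' @param tile_size tile side in pixels (> 0).
#' @return list of tiles; each tile is a list with `pixels`
#'   (tile_size x tile_size x 3), `tile_id`, `origin` (0-based (row, col) in
#'   the padded canvas), `valid` (logical matrix, FALSE on padded pixels),
#'   and `mask` (integer annotation mask, see [mask_codes()]).
#' @export
scene_to_tiles <- function(scene, tile_size = 512L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!is.numeric(tile_size) || tile_size <= 0)
    stop_value("tile_size must be > 0")
  tile_size <- as.integer(tile_size)
  H <- nrow(scene$gt_instances); W <- ncol(scene$gt_instances)
  Hp <- tile_size * ceiling(H / tile_size)
  Wp <- tile_size * ceiling(W / tile_size)
  img <- reflect_pad(scene$image, Hp, Wp)
  gt <- reflect_pad(scene$gt_instances, Hp, Wp)
  valid <- matrix(FALSE, Hp, Wp); valid[seq_len(H), seq_len(W)] <- TRUE
  tiles <- list()
  for (r0 in seq(0L, Hp - tile_size, by = tile_size)) {
    for (c0 in seq(0L, Wp - tile_size, by = tile_size)) {
      rows <- (r0 + 1L):(r0 + tile_size)
      cols <- (c0 + 1L):(c0 + tile_size)
      mask <- matrix(MASK_NEGATIVE, tile_size, tile_size)
      mask[gt[rows, cols] > 0L] <- MASK_POSITIVE
      tiles[[length(tiles) + 1L]] <- structure(list(
        pixels = img[rows, cols, , drop = FALSE],
        tile_id = sprintf("tile_r%03d_c%03d", r0 %/% tile_size, c0 %/% tile_size),
        origin = c(r0, c0),
        valid = valid[rows, cols, drop = FALSE],
        mask = mask,
        gt_instances = gt[rows, cols, drop = FALSE]
      ), class = "tile")
    }
  }
  tiles
}

#' Reassemble tiles into a raster
#'
#' Inverse of [scene_to_tiles()]: places each tile at its origin and crops
#' to the requested size, reproducing the source raster bit-exactly.
#'
#' @param tiles list of tiles from [scene_to_tiles()].
#' @param height,width size of the original raster.
#' @param what tile field to assemble (`"pixels"` or `"gt_instances"`).
#' @return array or matrix of the requested size.
#' @export
reassemble_tiles <- function(tiles, height, width, what = "pixels") {
  ts <- nrow(tiles[[1L]][[if (what == "pixels") "pixels" else what]])
  Hp <- max(vapply(tiles, function(t) t$origin[1L], numeric(1))) + ts
  Wp <- max(vapply(tiles, function(t) t$origin[2L], numeric(1))) + ts
  out <- if (what == "pixels") array(0, dim = c(Hp, Wp, 3L)) else matrix(0L, Hp, Wp)
  for (t in tiles) {
    rows <- (t$origin[1L] + 1L):(t$origin[1L] + ts)
    cols <- (t$origin[2L] + 1L):(t$origin[2L] + ts)
    if (what == "pixels") out[rows, cols, ] <- t$pixels
    else out[rows, cols] <- t[[what]]
  }
  if (what == "pixels") out[seq_len(height), seq_len(width), , drop = FALSE]
  else out[seq_len(height), seq_len(width), drop = FALSE]
}

#' Write / read a scene as paired PNGs plus a JSON sidecar
#'
#' The image is an 8-bit RGB PNG. Instance labels are stored losslessly in a
#' second 8-bit RGB PNG with the id split across the red and green channels
#' (`id = 256 * R + G`), supporting up to 65,535 instances. Generator
#' parameters and the seed go into `scene.json`.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @return `write_scene` returns `dir` invisibly; `read_scene` returns the
#'   scene (palette-dependent `params` are restored from the sidecar).
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(scene$image, file.path(dir, "image.png"))
  ids <- scene$gt_instances
  lab <- array(0, dim = c(nrow(ids), ncol(ids), 3L))
  lab[, , 1L] <- (ids %/% 256L) / 255
  lab[, , 2L] <- (ids %% 256L) / 255
  png::writePNG(lab, file.path(dir, "labels.png"))
  side <- list(structure_kind = scene$structure_kind, seed = scene$seed,
               params = scene$params[c("density", "noise", "margin",
                                       "min_size", "expected_count",
                                       "n_instances")])
  jsonlite::write_json(side, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  img <- png::readPNG(file.path(dir, "image.png"))
  lab <- png::readPNG(file.path(dir, "labels.png"))
  ids <- matrix(as.integer(round(lab[, , 1L] * 255)) * 256L +
                  as.integer(round(lab[, , 2L] * 255)),
                nrow(lab), ncol(lab))
  side <- jsonlite::read_json(file.path(dir, "scene.json"), simplifyVector = TRUE)
  structure(list(image = img, gt_instances = ids,
                 structure_kind = side$structure_kind,
                 seed = side$seed, params = side$params),
            class = "synthetic_scene")
}
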