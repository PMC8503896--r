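# Patch extraction, three-class annotation masks, overlays, and tile-level
# reassembly of patch predictions.
#
# An annotation mask assigns every pixel one of three labels: positive
# (structure of interest), negative (annotated non-target), or unknown
# (unannotated). Unknown is the default state and carries no supervision, so
# sparse partial annotations train cleanly.

#' @rdname mask_codes
#' @export
MASK_UNKNOWN <- 0L
#' @rdname mask_codes
#' @export
MASK_POSITIVE <- 1L
#' @rdname mask_codes
#' @export
MASK_NEGATIVE <- 2L

#' Annotation mask label codes and display palette
#'
#' Masks are integer matrices with codes 0 = unknown, 1 = positive,
#' 2 = negative. On screen and in encoded PNGs, positive regions are
#' turquoise and negative (non-target) regions fuchsia; unknown pixels are
#' black in encoded masks. Model suggestions are rendered as a white overlay.
#'
#' @return named list with `codes` and the RGB `palette` rows
#'   (`unknown`, `positive`, `negative`, `suggestion`).
#' @export
mask_codes <- function() {
  list(
    codes = c(unknown = MASK_UNKNOWN, positive = MASK_POSITIVE,
              negative = MASK_NEGATIVE),
    palette = rbind(unknown = c(0, 0, 0),
                    positive = c(64, 224, 208) / 255,   # turquoise
                    negative = c(255, 0, 255) / 255,    # fuchsia
                    suggestion = c(1, 1, 1))
  )
}

#' Create an all-unknown annotation mask
#'
#' @param nrow,ncol mask size in pixels.
#' @return integer matrix of `MASK_UNKNOWN`.
#' @export
new_annotation_mask <- function(nrow, ncol = nrow) {
  matrix(MASK_UNKNOWN, nrow, ncol)
}

is_annotation_mask <- function(m) {
  is.matrix(m) && all(m %in% c(MASK_UNKNOWN, MASK_POSITIVE, MASK_NEGATIVE))
}

#' Extract fixed-size patches from a tile
#'
#' Cuts a tile (or plain RGB array) into `patch_size` x `patch_size` patches
#' on a stride grid. Coordinates are 0-based, row-major, half-open: a patch
#' at `(row, col)` covers pixel rows `row .. row+patch_size-1`. When the tile
#' is not covered exactly, the canvas is reflect-padded to the next stride
#' multiple. With `stride = patch_size` (the default) the patches partition
#' the padded tile. Fresh patches carry an all-unknown mask.
#'
#' @param tile a tile from [scene_to_tiles()] or an H x W x 3 array.
#' @param patch_size patch side in pixels (>= 32).
#' @param stride step between patch origins, `1 <= stride <= patch_size`.
#' @return list of patches; each is a list with `pixels`, `coords`
#'   (`tile_id`, `row`, `col`), `mask`, `annotated` flag, `valid` raster and,
#'   when the tile has ground truth, `gt_instances`.
#' @export
extract_patches <- function(tile, patch_size = 256L, stride = patch_size) {
  if (is.array(tile) && !inherits(tile, "tile"))
    tile <- structure(list(pixels = tile, tile_id = "tile",
                           origin = c(0L, 0L),
                           valid = matrix(TRUE, dim(tile)[1L], dim(tile)[2L]),
                           mask = NULL, gt_instances = NULL), class = "tile")
  if (!is.numeric(patch_size) || patch_size < 32)
    stop_value("patch_size must be >= 32")
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (stride < 1L || stride > patch_size)
    stop_value("stride must satisfy 1 <= stride <= patch_size")
  H <- dim(tile$pixels)[1L]; W <- dim(tile$pixels)[2L]
  pad_to <- function(n) patch_size + stride * ceiling(max(0L, n - patch_size) / stride)
  Hp <- pad_to(H); Wp <- pad_to(W)
  if (patch_size > Hp || patch_size > Wp)
    stop_value("patch_size %d exceeds padded tile side %dx%d", patch_size, Hp, Wp)
  px <- reflect_pad(tile$pixels, Hp, Wp)
  valid <- matrix(FALSE, Hp, Wp)
  valid[seq_len(H), seq_len(W)] <- tile$valid
  gt <- if (!is.null(tile$gt_instances)) reflect_pad(tile$gt_instances, Hp, Wp)
  gtm <- if (!is.null(tile$mask)) reflect_pad(tile$mask, Hp, Wp)
  patches <- list()
  for (r0 in seq(0L, Hp - patch_size, by = stride)) {
    for (c0 in seq(0L, Wp - patch_size, by = stride)) {
      rows <- (r0 + 1L):(r0 + patch_size)
      cols <- (c0 + 1L):(c0 + patch_size)
      patches[[length(patches) + 1L]] <- structure(list(
        pixels = px[rows, cols, , drop = FALSE],
        coords = list(tile_id = tile$tile_id, row = r0, col = c0),
        patch_id = sprintf("%s_p%04d_%04d", tile$tile_id, r0, c0),
        mask = new_annotation_mask(patch_size),
        annotated = FALSE,
        valid = valid[rows, cols, drop = FALSE],
        gt_instances = if (!is.null(gt)) gt[rows, cols, drop = FALSE],
        gt_mask = if (!is.null(gtm)) gtm[rows, cols, drop = FALSE]
      ), class = "patch")
    }
  }
  patches
}

#' Encode / decode an annotation mask as an RGB image
#'
#' `encode_mask` maps the three labels to the display palette (positive
#' turquoise, negative fuchsia, unknown black); `decode_mask` inverts it.
#' The round trip is bit-exact for every valid mask. Use with
#' [png::writePNG()] / [png::readPNG()] to persist masks.
#'
#' @param mask integer annotation mask.
#' @param img H x W x 3 array using the declared palette.
#' @return `encode_mask`: H x W x 3 array; `decode_mask`: integer mask.
#' @export
encode_mask <- function(mask) {
  if (!is_annotation_mask(mask)) stop_value("not a valid 3-class annotation mask")
  pal <- mask_codes()$palette
  out <- array(0, dim = c(nrow(mask), ncol(mask), 3L))
  for (ch in 1:3) {
    v <- matrix(pal["unknown", ch], nrow(mask), ncol(mask))
    v[mask == MASK_POSITIVE] <- pal["positive", ch]
    v[mask == MASK_NEGATIVE] <- pal["negative", ch]
    out[, , ch] <- v
  }
  out
}

#' @rdname encode_mask
#' @export
decode_mask <- function(img) {
  if (!is_rgb_array(img)) stop_value("expected an H x W x 3 array")
  pal <- round(mask_codes()$palette * 255)
  key <- round(img * 255)
  code <- key[, , 1L] * 65536 + key[, , 2L] * 256 + key[, , 3L]
  pkey <- pal[, 1L] * 65536 + pal[, 2L] * 256 + pal[, 3L]
  out <- matrix(NA_integer_, nrow(code), ncol(code))
  out[code == pkey[["unknown"]]] <- MASK_UNKNOWN
  out[code == pkey[["positive"]]] <- MASK_POSITIVE
  out[code == pkey[["negative"]]] <- MASK_NEGATIVE
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop_value("unknown palette value at pixel %d: RGB(%d, %d, %d)",
               bad, key[, , 1L][bad], key[, , 2L][bad], key[, , 3L][bad])
  }
  out
}

#' Render annotations and suggestions over an image
#'
#' Alpha-blends the annotation palette over the image: positive turquoise,
#' negative fuchsia, and an optional binary suggestion mask in white.
#'
#' @param image H x W x 3 array.
#' @param mask optional annotation mask.
#' @param suggestion optional logical matrix of model suggestions.
#' @param alpha overlay opacity in \[0, 1\].
#' @return H x W x 3 array.
#' @export
render_overlay <- function(image, mask = NULL, suggestion = NULL, alpha = 0.5) {
  stopifnot(is_rgb_array(image))
  pal <- mask_codes()$palette
  out <- image
  blend <- function(out, where, col) {
    for (ch in 1:3) {
      v <- out[, , ch]
      v[where] <- (1 - alpha) * v[where] + alpha * col[ch]
      out[, , ch] <- v
    }
    out
  }
  if (!is.null(suggestion)) out <- blend(out, as.logical(suggestion), pal["suggestion", ])
  if (!is.null(mask)) {
    out <- blend(out, mask == MASK_POSITIVE, pal["positive", ])
    out <- blend(out, mask == MASK_NEGATIVE, pal["negative", ])
  }
  out
}

#' Assemble patch predictions into a tile-level map
#'
#' Places per-patch probability maps back onto the tile canvas. Pixels
#' covered by a single patch copy their source; pixels covered by several
#' (overlapping stride) take the arithmetic mean of all contributors.
#' Padded canvas beyond `tile_shape` is dropped. Every tile pixel must be
#' covered by at least one patch.
#'
#' @param patches list of `list(coords = c(row, col), map = matrix)` with
#'   0-based patch origins, or a list of patches paired with `maps`.
#' @param tile_shape integer vector `c(height, width)` of the target tile.
#' @return matrix `tile_shape` of probabilities in \[0, 1\].
#' @export
assemble_predictions <- function(patches, tile_shape) {
  stopifnot(length(tile_shape) == 2L)
  H <- tile_shape[1L]; W <- tile_shape[2L]
  origin_of <- function(p) {
    if (is.list(p$coords)) c(p$coords$row, p$coords$col) else p$coords[1:2]
  }
  canvas_h <- H; canvas_w <- W
  for (p in patches) {
    o <- origin_of(p)
    if (any(o < 0)) stop_value("negative patch origin")
    canvas_h <- max(canvas_h, o[1L] + nrow(p$map))
    canvas_w <- max(canvas_w, o[2L] + ncol(p$map))
  }
  acc <- matrix(0, canvas_h, canvas_w)
  cnt <- matrix(0L, canvas_h, canvas_w)
  for (p in patches) {
    o <- origin_of(p)
    m <- p$map
    rows <- (o[1L] + 1L):(o[1L] + nrow(m)); cols <- (o[2L] + 1L):(o[2L] + ncol(m))
    acc[rows, cols] <- acc[rows, cols] + m
    cnt[rows, cols] <- cnt[rows, cols] + 1L
  }
  cnt_t <- cnt[seq_len(H), seq_len(W), drop = FALSE]
  if (any(cnt_t == 0L)) {
    bad <- which(cnt_t == 0L)[1L]
    stop_value("tile pixel %d is not covered by any patch", bad)
  }
  acc[seq_len(H), seq_len(W), drop = FALSE] / cnt_t
}

#' Write a patch manifest
#'
#' One row per patch: patch id, tile id, 0-based origin, and whether the
#' patch carries any annotation.
#'
#' @param patches list of patches.
#' @param path optional CSV path; when `NULL` the data frame is returned
#'   without writing.
#' @return data frame (invisibly when written).
#' @export
patch_manifest <- function(patches, path = NULL) {
  df <- do.call(rbind, lapply(patches, function(p) data.frame(
    patch_id = p$patch_id,
    tile_id = p$coords$tile_id,
    row = p$coords$row,
    col = p$coords$col,
    annotated = isTRUE(p$annotated) || any(p$mask != MASK_UNKNOWN)
  )))
  if (!is.null(path)) {
    write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
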