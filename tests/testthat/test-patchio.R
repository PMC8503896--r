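# Patch extraction, mask encode/decode, overlays, prediction assembly.

test_that("stride = patch_size partitions the tile with half-open 0-based coords", {
  img <- array(runif(512 * 512 * 3), c(512, 512, 3))
  ps <- extract_patches(img, 256)
  expect_length(ps, 4L)
  origins <- t(vapply(ps, function(p) c(p$coords$row, p$coords$col), numeric(2)))
  expect_setequal(unname(split(origins, row(origins))),
                  unname(split(rbind(c(0, 0), c(0, 256), c(256, 0), c(256, 256)), 1:4)))
  cover <- matrix(0L, 512, 512)
  for (p in ps)
    cover[p$coords$row + 1:256, p$coords$col + 1:256] <-
      cover[p$coords$row + 1:256, p$coords$col + 1:256] + 1L
  expect_true(all(cover == 1L))
  # fresh masks are all-unknown
  expect_true(all(vapply(ps, function(p) all(p$mask == MASK_UNKNOWN), logical(1))))
  # a patch-sized tile is a single identity patch
  one <- extract_patches(img[1:256, 1:256, , drop = FALSE], 256)
  expect_length(one, 1L)
  expect_identical(one[[1]]$pixels, img[1:256, 1:256, , drop = FALSE])
})

test_that("non-multiple tiles are reflect-padded to the patch grid", {
  img <- array(runif(300 * 300 * 3), c(300, 300, 3))
  ps <- extract_patches(img, 256)
  expect_length(ps, 4L)  # ceiling(300/256) = 2 per axis on a 512x512 canvas
  expect_true(any(vapply(ps, function(p) any(!p$valid), logical(1))))
  # source region is untouched
  expect_identical(ps[[1]]$pixels[1:256, 1:256, ], img[1:256, 1:256, ])
  # padded rows mirror the source: padded row 300 + k equals row 300 - k
  full <- histannot:::reflect_pad(img, 512, 512)
  for (k in c(1, 50, 150))
    expect_identical(full[300 + k, 1:300, ], img[300 - k, 1:300, ])
})

test_that("reflect padding mirrors the source without edge duplication", {
  x <- matrix(1:5, 5, 1)
  padded <- histannot:::reflect_pad(x, 9, 1)
  expect_equal(as.vector(padded), c(1, 2, 3, 4, 5, 4, 3, 2, 1))
})

test_that("invalid patch grids error", {
  img <- array(0, c(64, 64, 3))
  expect_error(extract_patches(img, 16), ">= 32")
  expect_error(extract_patches(img, 64, stride = 0), "stride")
  expect_error(extract_patches(img, 64, stride = 100), "stride")
})

test_that("mask encode/decode round-trips exhaustively on 2x2 masks", {
  codes <- c(MASK_UNKNOWN, MASK_POSITIVE, MASK_NEGATIVE)
  grid <- expand.grid(codes, codes, codes, codes)
  for (r in seq_len(nrow(grid))) {
    m <- matrix(as.integer(unlist(grid[r, ])), 2, 2)
    expect_identical(decode_mask(encode_mask(m)), m)
  }
  # through PNG bytes as well
  m <- matrix(c(MASK_POSITIVE, MASK_NEGATIVE, MASK_UNKNOWN, MASK_POSITIVE), 2, 2)
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(encode_mask(m), f)
  expect_identical(decode_mask(png::readPNG(f)), m)
})

test_that("encoded masks use the turquoise/fuchsia display palette", {
  m <- matrix(c(MASK_POSITIVE, MASK_NEGATIVE), 1, 2)
  img <- encode_mask(m)
  expect_equal(round(img[1, 1, ] * 255), c(64, 224, 208))   # positive: turquoise
  expect_equal(round(img[1, 2, ] * 255), c(255, 0, 255))    # negative: fuchsia
  # suggestions render as white overlay at full opacity
  base <- array(0.2, c(1, 2, 3))
  ov <- render_overlay(base, suggestion = matrix(c(TRUE, FALSE), 1, 2), alpha = 1)
  expect_equal(ov[1, 1, ], c(1, 1, 1))
  expect_equal(ov[1, 2, ], c(0.2, 0.2, 0.2))
})

test_that("decoding a foreign palette names the offending value", {
  img <- array(0, c(2, 2, 3)); img[1, 1, ] <- c(0.5, 0.5, 0.5)
  expect_error(decode_mask(img), "RGB\\(128, 128, 128\\)")
})

test_that("prediction assembly copies, averages overlaps, drops padding and flags gaps", {
  # single full-tile patch: identity
  m <- matrix(runif(64), 8, 8)
  out <- assemble_predictions(list(list(coords = c(0, 0), map = m)), c(8, 8))
  expect_equal(out, m)
  # two overlapping constant maps of 0.8: overlap stays 0.8
  a <- list(coords = c(0, 0), map = matrix(0.8, 8, 8))
  b <- list(coords = c(0, 4), map = matrix(0.8, 8, 8))
  out <- assemble_predictions(list(a, b), c(8, 12))
  expect_true(all(out == 0.8))
  # overlap of constant 0 and constant 1: mean 0.5
  z <- list(coords = c(0, 0), map = matrix(0, 8, 8))
  o <- list(coords = c(0, 4), map = matrix(1, 8, 8))
  out <- assemble_predictions(list(z, o), c(8, 12))
  expect_equal(unique(as.vector(out[, 5:8])), 0.5)
  expect_true(all(out[, 1:4] == 0) && all(out[, 9:12] == 1))
  # padded area beyond the tile is dropped
  big <- list(coords = c(0, 0), map = matrix(0.3, 16, 16))
  expect_equal(dim(assemble_predictions(list(big), c(10, 10))), c(10, 10))
  # an uncovered pixel is an error
  expect_error(assemble_predictions(list(list(coords = c(0, 0), map = matrix(1, 4, 4))),
                                    c(8, 8)), "not covered")
})

test_that("assemble after extract is the identity on a prediction map", {
  map <- matrix(runif(128 * 128), 128, 128)
  fake <- array(0.5, c(128, 128, 3))
  ps <- extract_patches(fake, 64)
  pieces <- lapply(ps, function(p) list(
    coords = p$coords,
    map = map[p$coords$row + 1:64, p$coords$col + 1:64]))
  expect_equal(assemble_predictions(pieces, c(128, 128)), map)
})

test_that("patch manifest lists ids, origins and annotation state", {
  ps <- tiny_patches(4)
  ps[[2]]$mask <- ps[[2]]$mask_full
  df <- patch_manifest(ps)
  expect_equal(nrow(df), 4L)
  expect_true(df$annotated[2] && !df$annotated[1])
  f <- withr::local_tempfile(fileext = ".csv")
  patch_manifest(ps, f)
  expect_equal(nrow(read.csv(f)), 4L)
})
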