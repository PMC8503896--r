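# Run-length connected-component labeling.
#
# Works on an integer id raster: two pixels are connected when they are
# neighbors under the chosen connectivity AND carry the same positive id.
# This generalization is needed in two places: plain binary masks (all
# foreground shares one id) and instance rasters, where touching instances
# with different ids must stay separate.

label_runs <- function(ids) {
  H <- nrow(ids); W <- ncol(ids)
  v <- ids > 0L
  up_v <- rbind(FALSE, v[-H, , drop = FALSE])
  up_id <- rbind(0L, ids[-H, , drop = FALSE])
  starts <- v & (!up_v | ids != up_id)
  down_v <- rbind(v[-1L, , drop = FALSE], FALSE)
  down_id <- rbind(ids[-1L, , drop = FALSE], 0L)
  ends <- v & (!down_v | ids != down_id)
  start_pos <- which(starts)
  end_pos <- which(ends)
  run_of_px <- cumsum(as.vector(starts))
  run_of_px[!v] <- 0L
  list(
    n = length(start_pos),
    col = ((start_pos - 1L) %/% H) + 1L,
    row_start = ((start_pos - 1L) %% H) + 1L,
    row_end = ((end_pos - 1L) %% H) + 1L,
    id = ids[start_pos],
    start_pos = start_pos,
    run_of_px = matrix(run_of_px, H, W)
  )
}

# Label connected components of an integer id raster.
# Returns an integer matrix with labels 1..K (0 = background), numbered by
# first occurrence in column-major order.
label_components_int <- function(ids, connectivity = 8L) {
  stopifnot(is.matrix(ids))
  if (!connectivity %in% c(4L, 8L)) stop_value("connectivity must be 4 or 8")
  storage.mode(ids) <- "integer"
  r <- label_runs(ids)
  if (r$n == 0L) return(matrix(0L, nrow(ids), ncol(ids)))
  parent <- seq_len(r$n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8L) 1L else 0L
  # match runs of adjacent columns; runs are sorted by (col, row) and runs of
  # one column are disjoint, so candidates form a contiguous index range
  col_idx <- split(seq_len(r$n), r$col)
  cols <- as.integer(names(col_idx))
  for (ci in seq_along(cols)[-1L]) {
    if (cols[ci] - cols[ci - 1L] != 1L) next
    a <- col_idx[[ci - 1L]]; b <- col_idx[[ci]]
    re_a <- r$row_end[a]; rs_a <- r$row_start[a]
    lo <- findInterval(r$row_start[b] - slack - 0.5, re_a) + 1L
    hi <- findInterval(r$row_end[b] + slack + 0.5, rs_a)
    for (ib in seq_along(b)) {
      if (lo[ib] > hi[ib]) next
      rb <- b[ib]
      for (ra in a[lo[ib]:hi[ib]]) {
        if (r$id[ra] == r$id[rb]) {
          fa <- find(ra); fb <- find(rb)
          if (fa != fb) parent[max(fa, fb)] <- min(fa, fb)
        }
      }
    }
  }
  root <- vapply(seq_len(r$n), find, integer(1))
  # consecutive labels ordered by first pixel occurrence
  first_pos <- tapply(r$start_pos, root, min)
  ord <- order(first_pos)
  relab <- integer(max(root))
  relab[as.integer(names(first_pos))[ord]] <- seq_along(ord)
  run_label <- relab[root]
  out <- r$run_of_px
  out[out > 0L] <- run_label[out[out > 0L]]
  out
}

label_components <- function(mask, connectivity = 8L) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  label_components_int(m, connectivity)
}
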