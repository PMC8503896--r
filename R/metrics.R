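#' Pixel-level f-score between two binary masks
#'
#' Computes F1 = 2TP / (2TP + FP + FN) over pixels, the standard concordance
#' measure between a produced segmentation mask and a reference mask. When
#' both masks are empty the score is defined as 1.0: perfect agreement on
#' the absence of the structure (and it avoids the 0/0 indeterminacy).
#'
#' @param mask logical or 0/1 matrix, the produced mask.
#' @param reference logical or 0/1 matrix of the same shape, the reference
#'   (ground-truth or manual) mask.
#' @return a single number in \[0, 1\].
#' @export
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2, 2)
#' pixel_f_score(a, a) # 1
pixel_f_score <- function(mask, reference) {
  m <- as.logical(mask); r <- as.logical(reference)
  if (!identical(dim(mask), dim(reference)))
    stop_value("mask and reference shapes differ: %s vs %s",
               paste(dim(mask), collapse = "x"), paste(dim(reference), collapse = "x"))
  tp <- sum(m & r)
  fp <- sum(m & !r)
  fn <- sum(!m & r)
  if (tp + fp + fn == 0L) return(1.0)
  2 * tp / (2 * tp + fp + fn)
}

#' Count structures in a binary mask
#'
#' Number of connected foreground components with at least `min_size` pixels.
#' Defaults (8-connectivity, 10 px minimum) reflect common practice for
#' histologic structure counting; the conventions are configurable because
#' published counts rarely state them.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (neighbors sharing an edge, or an edge/corner).
#' @param min_size minimum component area in pixels; smaller components are
#'   ignored.
#' @return integer count.
#' @export
count_structures <- function(mask, connectivity = 8L, min_size = 10L) {
  if (min_size < 0) stop_value("min_size must be >= 0")
  lab <- label_components(mask, as.integer(connectivity))
  if (max(lab) == 0L) return(0L)
  sizes <- tabulate(lab, nbins = max(lab))
  sum(sizes >= max(min_size, 1L))
}

#' Extrapolate fully-manual annotation time
#'
#' Scales the measured manual annotation rate on a subset linearly to the
#' full set of structures: `M_t = total * (minutes / structures)` of the
#' subset. This mirrors the standard practice of timing a manageable subset
#' and extrapolating, since manually annotating full cohorts is intractable.
#'
#' @param subset_minutes minutes spent manually annotating the subset (> 0).
#' @param subset_structures structures annotated in the subset (>= 1).
#' @param total_structures structures in the full task.
#' @return extrapolated manual minutes `M_t`.
#' @export
#' @examples
#' extrapolate_manual_time(2, 10, 100) # 20
extrapolate_manual_time <- function(subset_minutes, subset_structures, total_structures) {
  check_scalar_number(subset_minutes, "subset_minutes")
  check_scalar_number(subset_structures, "subset_structures")
  check_scalar_number(total_structures, "total_structures", lower = 0)
  if (subset_structures < 1) stop_value("subset_structures must be >= 1")
  if (subset_minutes <= 0) stop_value("subset_minutes must be > 0")
  total_structures * (subset_minutes / subset_structures)
}

#' Integer annotation speed-up multiplier
#'
#' The efficiency improvement of assisted annotation is the ratio of the
#' extrapolated manual time `M_t` to the assisted human time `QA_t`,
#' reported as an integer multiplier: `floor(M_t / QA_t)`. The floor
#' convention is pinned for reproducibility; it is the simple rounding rule
#' consistent with reporting e.g. 102x for a raw ratio of 102.7.
#'
#' @param M_t extrapolated manual minutes.
#' @param QA_t assisted human minutes (> 0).
#' @return integer speed-up multiplier.
#' @export
#' @examples
#' speedup(40165, 391) # 102
speedup <- function(M_t, QA_t) {
  check_scalar_number(M_t, "M_t", lower = 0)
  check_scalar_number(QA_t, "QA_t")
  if (QA_t <= 0) stop_value("QA_t must be > 0")
  as.integer(floor(M_t / QA_t))
}

#' Annotation-efficiency curve from a session log
#'
#' Bins completed structures (manually annotated, accepted, or corrected)
#' by cumulative human time and reports structures per minute in each bin.
#' The curve is conservative: `sum(rate * bin_minutes)` equals the total
#' number of structures completed in the log.
#'
#' @param log a `session_log` (see [simulate_session()]) or its `events`
#'   data frame.
#' @param bin_minutes bin width on the human-time axis, in minutes.
#' @return data frame with columns `human_minute` (right edge of each bin)
#'   and `structures_per_minute`.
#' @export
efficiency_curve <- function(log, bin_minutes = 1) {
  check_scalar_number(bin_minutes, "bin_minutes")
  if (bin_minutes <= 0) stop_value("bin_minutes must be > 0")
  ev <- if (is.data.frame(log)) log else log$events
  ev <- ev[ev$kind %in% c("annotate", "accept", "correct"), , drop = FALSE]
  if (nrow(ev) == 0L)
    return(data.frame(human_minute = numeric(0), structures_per_minute = numeric(0)))
  hmin <- ev$human_s / 60
  nb <- max(1L, ceiling(max(hmin) / bin_minutes - 1e-9))
  bin <- pmin(nb, pmax(1L, ceiling(hmin / bin_minutes - 1e-9)))
  counts <- vapply(seq_len(nb), function(b) sum(ev$structures_touched[bin == b]), numeric(1))
  data.frame(human_minute = seq_len(nb) * bin_minutes,
             structures_per_minute = counts / bin_minutes)
}

#' Per-image and project-level annotation statistics
#'
#' Summarizes structure counts and positive areas per image, with pixel
#' f-scores when reference masks are available, plus a project total row
#' whose counts and areas are the sums of the per-image values.
#'
#' @param masks named list of binary masks (one per image).
#' @param references optional named list of reference masks matched by name.
#' @param connectivity,min_size structure counting conventions, see
#'   [count_structures()].
#' @return data frame with one row per image and a final `TOTAL` row.
#' @export
project_stats <- function(masks, references = NULL, connectivity = 8L, min_size = 10L) {
  if (length(masks) == 0L) stop_value("at least one mask is required")
  nm <- names(masks) %||% paste0("image_", seq_along(masks))
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    f <- NA_real_
    if (!is.null(references) && !is.null(references[[nm[i]]]))
      f <- pixel_f_score(m, references[[nm[i]]])
    data.frame(image = nm[i],
               n_structures = count_structures(m, connectivity, min_size),
               positive_pixels = sum(as.logical(m)),
               f_score = f)
  })
  out <- do.call(rbind, rows)
  total <- data.frame(image = "TOTAL",
                      n_structures = sum(out$n_structures),
                      positive_pixels = sum(out$positive_pixels),
                      f_score = if (all(is.na(out$f_score))) NA_real_ else
                        mean(out$f_score, na.rm = TRUE))
  rbind(out, total)
}
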