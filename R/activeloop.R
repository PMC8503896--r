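# The annotate -> train -> suggest -> accept/correct cycle, driven by a
# simulated annotator (an oracle with access to the ground truth) under an
# explicit per-action cost model.
#
# Times are kept on a virtual clock: human actions cost what the oracle
# cost model says, and training costs a deterministic per-patch-epoch
# amount, so a fixed seed reproduces the session log bit for bit. Measured
# training wall time is additionally accumulated on the model object.
# Human time excludes training time (the annotator is "dismissed" while
# the model trains); total time includes it.

#' Configuration of the simulated annotator
#'
#' The oracle reviews each model suggestion against the ground truth: when
#' the patch-level pixel f-score reaches `accept_threshold` it accepts the
#' suggestion unchanged (one click); otherwise it corrects, flipping each
#' erroneous pixel to the truth independently with probability
#' `correction_fidelity`. Costs are explicit configuration because real
#' per-action timings are study-specific; vary them in sensitivity analyses
#' rather than treating the defaults as ground truth.
#'
#' @param accept_threshold patch f-score at or above which a suggestion is
#'   accepted unchanged. Values above 1 mean "never accept".
#' @param correction_fidelity fraction of erroneous pixels fixed when
#'   correcting, in \[0, 1\].
#' @param seconds_per_structure manual annotation cost per structure.
#' @param accept_seconds cost of accepting a reviewed patch (one click).
#' @param correct_seconds_per_structure cost per ground-truth structure
#'   intersecting the error set when correcting.
#' @param train_seconds_per_patch_epoch deterministic virtual cost of one
#'   training epoch over one patch (counts toward total, not human, time).
#' @param seed RNG seed for correction sampling in standalone
#'   [oracle_review()] calls.
#' @return object of class `oracle_config`.
#' @export
oracle_config <- function(accept_threshold = 0.9, correction_fidelity = 1,
                          seconds_per_structure = 2, accept_seconds = 1.5,
                          correct_seconds_per_structure = 1,
                          train_seconds_per_patch_epoch = 0.5, seed = 1L) {
  check_scalar_number(correction_fidelity, "correction_fidelity", 0, 1)
  if (accept_threshold < 0) stop_value("accept_threshold must be >= 0")
  for (v in c(seconds_per_structure, accept_seconds,
              correct_seconds_per_structure, train_seconds_per_patch_epoch))
    if (v < 0) stop_value("costs must be >= 0")
  structure(list(accept_threshold = accept_threshold,
                 correction_fidelity = correction_fidelity,
                 seconds_per_structure = seconds_per_structure,
                 accept_seconds = accept_seconds,
                 correct_seconds_per_structure = correct_seconds_per_structure,
                 train_seconds_per_patch_epoch = train_seconds_per_patch_epoch,
                 seed = as.integer(seed)),
            class = "oracle_config")
}

#' Oracle review of one suggested mask
#'
#' @param suggestion logical/0-1 suggested mask.
#' @param gt logical/0-1 ground-truth mask of the same shape.
#' @param cfg an [oracle_config()].
#' @param gt_instances optional instance raster used to count the
#'   structures touched by a correction; component labeling of `gt` is used
#'   when absent.
#' @param seed RNG seed for the correction sampling; `NULL` draws from the
#'   current RNG stream (used inside sessions).
#' @return list with `action` (`"accept"` or `"correct"`), `mask` (the
#'   resulting mask), `cost` (seconds), `structures` (ground-truth
#'   structures in the patch, all completed by the review), `n_touched`
#'   (structures intersecting the error set; drives the correction cost),
#'   and `f_score` of the suggestion.
#' @export
oracle_review <- function(suggestion, gt, cfg = oracle_config(),
                          gt_instances = NULL, seed = cfg$seed) {
  sugg <- matrix(as.logical(suggestion), nrow(suggestion), ncol(suggestion))
  gtl <- matrix(as.logical(gt), nrow(gt), ncol(gt))
  f <- pixel_f_score(sugg, gtl)  # errors on shape mismatch
  inst <- gt_instances %||% label_components(gtl, 8L)
  n_structures <- max(inst)
  if (f >= cfg$accept_threshold) {
    return(list(action = "accept", mask = sugg, cost = cfg$accept_seconds,
                structures = n_structures, n_touched = 0L, f_score = f))
  }
  err <- sugg != gtl
  flip <- with_seed(seed, runif(sum(err)) < cfg$correction_fidelity)
  corrected <- sugg
  fixed <- which(err)[flip]
  corrected[fixed] <- gtl[fixed]
  touched <- unique(inst[err])
  touched <- touched[touched > 0L]
  list(action = "correct", mask = corrected,
       cost = cfg$correct_seconds_per_structure * length(touched),
       structures = n_structures, n_touched = length(touched), f_score = f)
}

#' Simulate a full annotation session on a synthetic scene
#'
#' Runs the complete cycle against a generated scene: the network is
#' pretrained as an autoencoder on all patches, then per round the oracle
#' (1) annotates a diverse set of unannotated patches selected by
#' farthest-point sampling in the current 2-D patch embedding, (2) the
#' model is fine-tuned on everything annotated so far, and (3) the oracle
#' reviews the model's suggestions on all remaining patches, accepting or
#' correcting each. Final masks cover every patch: manually annotated
#' patches keep their annotation, the rest keep their last review outcome.
#'
#' @param scene a [generate_scene()] result.
#' @param model_cfg a [model_config()]; the patch size also sets the tiling.
#' @param oracle an [oracle_config()].
#' @param schedule list with `patches_per_round`, `rounds`,
#'   `epochs_per_round`; round 1 must annotate at least the training-gate
#'   minimum.
#' @param gate a [training_gate()].
#' @param pretrain_epochs autoencoder epochs before the first round.
#' @param threshold suggestion binarization threshold.
#' @param seed master RNG seed; every stochastic choice of the session
#'   derives from it.
#' @param lr,batch_size training hyperparameters passed through.
#' @return list with `final_mask` (scene-level logical mask), `patches`
#'   (with final per-patch masks), `log` (a `session_log`), `report` (an
#'   `efficiency_report`), and `model`.
#' @export
simulate_session <- function(scene, model_cfg = model_config(),
                             oracle = oracle_config(),
                             schedule = list(patches_per_round = 4L, rounds = 3L,
                                             epochs_per_round = 10L),
                             gate = training_gate(),
                             pretrain_epochs = 2L, threshold = 0.5, seed = 1L,
                             lr = 3e-3, batch_size = 2L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (schedule$rounds < 1L) stop_value("schedule must have at least 1 round")
  if (schedule$patches_per_round < gate$min_annotated_patches)
    stop_value("round 1 must annotate at least %d patches (training gate), schedule gives %d",
               gate$min_annotated_patches, schedule$patches_per_round)

  H <- nrow(scene$gt_instances); W <- ncol(scene$gt_instances)
  tile <- structure(list(pixels = scene$image, tile_id = "scene",
                         origin = c(0L, 0L), valid = matrix(TRUE, H, W),
                         mask = NULL, gt_instances = scene$gt_instances),
                    class = "tile")
  patches <- extract_patches(tile, patch_size = model_cfg$patch_size)
  np <- length(patches)
  gt_masks <- lapply(patches, function(p) p$gt_instances > 0L)

  # event log on the virtual clock
  events <- list()
  t_now <- 0; human_s <- 0
  log_event <- function(kind, patch_id, structures, dt, training = FALSE) {
    t_now <<- t_now + dt
    if (!training) human_s <<- human_s + dt
    events[[length(events) + 1L]] <<- data.frame(
      timestamp_s = t_now, kind = kind, patch_id = patch_id,
      structures_touched = structures, human_s = human_s)
  }
  patch_structures <- vapply(seq_len(np), function(i) {
    inst <- patches[[i]]$gt_instances
    length(unique(inst[inst > 0L & patches[[i]]$valid]))
  }, integer(1))

  warn_flag <- FALSE
  with_seed(seed, {
    model <- build_model(model_cfg)
    px_time <- oracle$train_seconds_per_patch_epoch
    if (pretrain_epochs > 0L) {
      log_event("train_start", NA_character_, 0L, 0)
      model <- pretrain_autoencoder(model, patches, epochs = pretrain_epochs,
                                    seed = sample.int(2^30, 1L), lr = 1e-3,
                                    batch_size = 4L)
      log_event("train_end", NA_character_, 0L, px_time * np * pretrain_epochs,
                training = TRUE)
    }
    annotated <- logical(np)
    final_masks <- vector("list", np)
    for (r in seq_len(schedule$rounds)) {
      todo <- which(!annotated)
      if (length(todo) == 0L) { warn_flag <- TRUE; break }
      n_pick <- min(schedule$patches_per_round, length(todo))
      picked <- if (model$stage == "untrained" || length(todo) <= n_pick) {
        todo[seq_len(n_pick)]
      } else {
        feats <- extract_features(model, patches[todo])
        rownames(feats) <- as.character(todo)
        emb <- project_2d(feats, seed = sample.int(2^30, 1L),
                          n_neighbors = min(10L, length(todo) - 1L),
                          n_epochs = 60L)
        as.integer(select_diverse(emb, n_pick, seed = sample.int(2^30, 1L)))
      }
      for (i in picked) {
        patches[[i]]$mask <- ifelse(gt_masks[[i]], MASK_POSITIVE, MASK_NEGATIVE)
        patches[[i]]$annotated <- TRUE
        annotated[i] <- TRUE
        final_masks[[i]] <- gt_masks[[i]]
        log_event("annotate", patches[[i]]$patch_id, patch_structures[i],
                  oracle$seconds_per_structure * patch_structures[i])
      }
      log_event("train_start", NA_character_, 0L, 0)
      model <- finetune(model, patches[annotated], gate = gate,
                        epochs = schedule$epochs_per_round,
                        seed = sample.int(2^30, 1L), lr = lr,
                        batch_size = batch_size)
      log_event("train_end", NA_character_, 0L,
                px_time * sum(annotated) * schedule$epochs_per_round,
                training = TRUE)
      review <- which(!annotated)
      for (i in review) {
        prob <- predict(model, patches[[i]])
        log_event("suggest", patches[[i]]$patch_id, 0L, 0)
        rev <- oracle_review(binarize(prob, threshold), gt_masks[[i]], oracle,
                             gt_instances = patches[[i]]$gt_instances, seed = NULL)
        final_masks[[i]] <- rev$mask
        log_event(rev$action, patches[[i]]$patch_id, rev$structures, rev$cost)
      }
    }
  })

  log <- session_log(do.call(rbind, events), warn_flag)
  # assemble the scene-level mask from per-patch final masks
  pm <- lapply(seq_len(np), function(i) list(coords = patches[[i]]$coords,
                                             map = final_masks[[i]] * 1))
  final_mask <- assemble_predictions(pm, c(H, W)) >= 0.5
  f <- pixel_f_score(final_mask, scene$gt_instances > 0L)
  for (i in seq_len(np)) patches[[i]]$final_mask <- final_masks[[i]]

  # manual-time extrapolation from the manually annotated subset
  ann <- log$events$kind == "annotate"
  subset_min <- sum(log$events$structures_touched[ann]) *
    oracle$seconds_per_structure / 60
  subset_n <- sum(log$events$structures_touched[ann])
  K <- scene$params$n_instances
  report <- efficiency_report(log,
    M_t = if (subset_n >= 1 && subset_min > 0)
      extrapolate_manual_time(subset_min, subset_n, K) else NA_real_,
    f_score = f, n_structures = K)

  list(final_mask = final_mask, patches = patches, log = log,
       report = report, model = model)
}

#' Session log constructor
#'
#' Ordered event record of a session on the virtual clock. The time
#' identity `human_seconds + training seconds = total_seconds` holds
#' exactly; every `train_start` has a matching `train_end`.
#'
#' @param events data frame with columns `timestamp_s`, `kind`,
#'   `patch_id`, `structures_touched`, `human_s`.
#' @param truncated whether the schedule exhausted the patches early.
#' @return object of class `session_log`.
#' @export
session_log <- function(events, truncated = FALSE) {
  stopifnot(is.data.frame(events))
  if (is.unsorted(events$timestamp_s)) stop_value("timestamps must be non-decreasing")
  if (sum(events$kind == "train_start") != sum(events$kind == "train_end"))
    stop_value("unmatched train_start/train_end events")
  total <- if (nrow(events)) max(events$timestamp_s) else 0
  human <- if (nrow(events)) events$human_s[nrow(events)] else 0
  structure(list(events = events, human_seconds = human,
                 total_seconds = total, truncated = truncated),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("session_log: %d events, %.1f human s, %.1f total s%s\n",
              nrow(x$events), x$human_seconds, x$total_seconds,
              if (x$truncated) " (schedule exhausted patches early)" else ""))
  invisible(x)
}

#' Efficiency report derived from a session log
#'
#' Collects the headline efficiency quantities: extrapolated manual time
#' `M_t`, assisted human and total times, the integer speed-up
#' `theta_t = floor(M_t / QA_t_human)`, the final pixel f-score, and the
#' structures-per-minute curve.
#'
#' @param log a `session_log`.
#' @param M_t extrapolated manual minutes (see [extrapolate_manual_time()]).
#' @param f_score final pixel f-score against ground truth.
#' @param n_structures total structures in the task.
#' @param bin_minutes bin width of the efficiency curve.
#' @return object of class `efficiency_report`.
#' @export
efficiency_report <- function(log, M_t, f_score, n_structures, bin_minutes = 1) {
  qa_h <- log$human_seconds / 60
  qa_t <- log$total_seconds / 60
  theta <- if (!is.na(M_t) && qa_h > 0) speedup(M_t, qa_h) else NA_integer_
  structure(list(M_t = M_t, QA_t_human = qa_h, QA_t_total = qa_t,
                 theta_t = theta, f_score = f_score,
                 n_structures = as.integer(n_structures),
                 curve = efficiency_curve(log, bin_minutes)),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf(paste0("efficiency_report: %d structures, f-score %.3f\n",
                     "  manual time M_t      %8.1f min\n",
                     "  assisted human time  %8.1f min (total %.1f min)\n",
                     "  speed-up theta_t     %8s x\n"),
              x$n_structures, x$f_score, x$M_t, x$QA_t_human, x$QA_t_total,
              ifelse(is.na(x$theta_t), "NA", x$theta_t)))
  invisible(x)
}

#' Write an efficiency report as JSON and CSV
#'
#' @param report an `efficiency_report`.
#' @param path_json,path_csv output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_report <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(list(
      M_t = report$M_t, QA_t_human = report$QA_t_human,
      QA_t_total = report$QA_t_total, theta_t = report$theta_t,
      f_score = report$f_score, n_structures = report$n_structures,
      curve = report$curve), path_json, auto_unbox = TRUE, digits = NA,
      na = "null")
  }
  if (!is.null(path_csv)) write.csv(report$curve, path_csv, row.names = FALSE)
  invisible(report)
}
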