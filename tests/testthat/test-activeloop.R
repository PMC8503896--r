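# Simulated annotator and full session loop.

test_that("oracle accepts perfect or above-threshold suggestions and corrects otherwise", {
  gt <- matrix(0L, 16, 16); gt[4:9, 4:9] <- 1L
  cfg <- oracle_config(accept_threshold = 0.9, correction_fidelity = 1)
  # suggestion identical to gt: accepted at any threshold <= 1
  r <- oracle_review(gt, gt, oracle_config(accept_threshold = 1))
  expect_identical(r$action, "accept")
  expect_identical(r$mask, gt > 0L)
  expect_equal(r$f_score, 1)
  # threshold 0 always accepts
  bad <- matrix(0L, 16, 16); bad[10:12, 10:12] <- 1L
  r0 <- oracle_review(bad, gt, oracle_config(accept_threshold = 0))
  expect_identical(r0$action, "accept")
  # full-fidelity correction reproduces gt exactly
  rc <- oracle_review(bad, gt, cfg)
  expect_identical(rc$action, "correct")
  expect_identical(rc$mask, gt > 0L)
  # zero-fidelity correction leaves the suggestion unchanged
  rz <- oracle_review(bad, gt, oracle_config(accept_threshold = 0.9,
                                             correction_fidelity = 0))
  expect_identical(rz$mask, bad > 0L)
  # partial fidelity is seeded and reproducible
  rp1 <- oracle_review(bad, gt, oracle_config(accept_threshold = 0.9,
                                              correction_fidelity = 0.5, seed = 3))
  rp2 <- oracle_review(bad, gt, oracle_config(accept_threshold = 0.9,
                                              correction_fidelity = 0.5, seed = 3))
  expect_identical(rp1$mask, rp2$mask)
  n_err_before <- sum(bad != gt)
  expect_lt(sum(rp1$mask != (gt > 0L)), n_err_before)
})

test_that("correction cost counts ground-truth structures touching the error set", {
  gt <- matrix(0L, 20, 20)
  gt[2:5, 2:5] <- 1L; gt[10:13, 10:13] <- 1L; gt[16:19, 16:19] <- 1L
  inst <- histannot:::label_components(gt, 8L)
  sugg <- gt
  sugg[2:5, 2:5] <- 0L              # miss structure 1 entirely
  sugg[10, 10] <- 0L                # clip one pixel of structure 2
  cfg <- oracle_config(accept_threshold = 1.1, correction_fidelity = 1,
                       correct_seconds_per_structure = 2)
  r <- oracle_review(sugg, gt, cfg, gt_instances = inst)
  expect_identical(r$action, "correct")
  expect_equal(r$n_touched, 2L)      # structures 1 and 2 intersect the errors
  expect_equal(r$cost, 2 * 2)
  expect_equal(r$structures, 3L)     # the whole patch is completed by the review
})

run_small_session <- function(seed = 21, oracle = oracle_config(),
                              rounds = 2L, epochs = 6L) {
  sc <- fixture(paste0("session_scene", 77), function()
    generate_scene("nuclei", 512, 512, density = 250, seed = 77))
  simulate_session(
    sc,
    model_cfg = model_config(patch_size = 128, init_seed = seed),
    oracle = oracle,
    schedule = list(patches_per_round = 4L, rounds = rounds,
                    epochs_per_round = epochs),
    pretrain_epochs = 1L, seed = seed)
}

test_that("session log keeps the exact human + training = total time identity", {
  res <- fixture("session_default", function() run_small_session())
  log <- res$log
  ev <- log$events
  # recompute training time by pairing train_start/train_end events
  starts <- ev$timestamp_s[ev$kind == "train_start"]
  ends <- ev$timestamp_s[ev$kind == "train_end"]
  expect_length(starts, length(ends))
  expect_equal(log$human_seconds + sum(ends - starts), log$total_seconds)
  expect_true(!is.unsorted(ev$timestamp_s))
  # final masks cover every patch
  expect_true(all(vapply(res$patches, function(p) !is.null(p$final_mask), logical(1))))
})

test_that("a fixed seed reproduces the session bit for bit", {
  a <- fixture("session_default", function() run_small_session())
  b <- run_small_session()
  expect_identical(a$final_mask, b$final_mask)
  expect_identical(a$log$events, b$log$events)
  expect_equal(a$report$f_score, b$report$f_score)
})

test_that("a perfect oracle yields ground truth regardless of model quality", {
  res <- run_small_session(seed = 5,
                           oracle = oracle_config(accept_threshold = 1.1,
                                                  correction_fidelity = 1),
                           rounds = 1L, epochs = 1L)
  expect_equal(res$report$f_score, 1)
  sc <- generate_scene("nuclei", 512, 512, density = 250, seed = 77)
  expect_identical(res$final_mask, sc$gt_instances > 0L)
})

test_that("with accept-everything review the final masks are the raw model suggestions", {
  res <- run_small_session(seed = 6,
                           oracle = oracle_config(accept_threshold = 0),
                           rounds = 1L, epochs = 1L)
  ev <- res$log$events
  expect_false(any(ev$kind == "correct"))
  reviewed <- which(!vapply(res$patches, function(p) isTRUE(p$annotated), logical(1)))
  m <- res$model
  for (i in reviewed[1:2]) {
    expect_identical(res$patches[[i]]$final_mask,
                     binarize(predict(m, res$patches[[i]]), 0.5))
  }
})

test_that("final f-score is non-decreasing in correction fidelity", {
  f_at <- function(fid) run_small_session(
    seed = 9, oracle = oracle_config(accept_threshold = 1.1,
                                     correction_fidelity = fid),
    rounds = 1L, epochs = 2L)$report$f_score
  fs <- c(f_at(0.2), f_at(0.6), f_at(1))
  expect_true(all(diff(fs) >= -1e-12))
  expect_equal(fs[3], 1)
})

test_that("annotation speed rises from the early to the late phase of a session", {
  rates <- vapply(1:3, function(s) {
    res <- run_small_session(seed = 30 + s, rounds = 3L, epochs = 6L)
    ev <- res$log$events
    done <- ev[ev$kind %in% c("annotate", "accept", "correct"), ]
    # structures per human second in the first vs last quartile of human time
    q <- quantile(done$human_s, c(0.25, 0.75))
    early <- done[done$human_s <= q[1], ]
    late <- done[done$human_s >= q[2], ]
    dt_e <- max(early$human_s)
    dt_l <- max(late$human_s) - min(late$human_s) + 1e-9
    c(sum(early$structures_touched) / dt_e,
      sum(late$structures_touched) / dt_l)
  }, numeric(2))
  # sign test across seeds: late-phase rate exceeds early-phase rate
  expect_true(all(rates[2, ] > rates[1, ]))
})

test_that("schedules that exhaust the patches terminate early with a flag", {
  res <- run_small_session(seed = 12,
                           oracle = oracle_config(accept_threshold = 0),
                           rounds = 6L, epochs = 1L)
  expect_true(res$log$truncated)
  # undersized first round violates the training gate up front
  sc <- generate_scene("nuclei", 512, 512, density = 250, seed = 77)
  expect_error(simulate_session(sc, model_cfg = model_config(patch_size = 128),
                                schedule = list(patches_per_round = 2L, rounds = 1L,
                                                epochs_per_round = 1L)),
               "training gate")
})
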