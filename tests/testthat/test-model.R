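# Network construction, parameter counting, pretraining, fine-tuning,
# prediction, binarization.

test_that("parameter count equals the closed-form per-layer sum on a config grid", {
  for (depth in 1:3) for (bw in c(2, 4, 8)) for (up in c("nearest", "transposed")) {
    cfg <- model_config(depth = depth, base_width = bw, patch_size = 32,
                        upsample = up)
    m <- build_model(cfg)
    expect_identical(count_parameters(m),
                     oracle_param_count(depth, bw, upsample = up),
                     info = sprintf("depth=%d width=%d up=%s", depth, bw, up))
  }
})

test_that("toy configuration matches a hand-summed parameter count", {
  # depth 1, width 2, in 3, out 2: two 3x3 convs (3->2, 2->2) plus 1x1 head
  # conv1: 9*3*2 + 2 = 56; conv2: 9*2*2 + 2 = 38; head: 2*2 + 2 = 6 -> 100
  m <- build_model(model_config(depth = 1, base_width = 2, patch_size = 32))
  expect_identical(count_parameters(m), 100)
})

test_that("building is deterministic and counting is invariant to reinitialization", {
  cfg <- tiny_cfg()
  m1 <- build_model(cfg); m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(count_parameters(m1), count_parameters(m2))
  m3 <- build_model(model_config(depth = 3, base_width = 2, patch_size = 64,
                                 init_seed = 99))
  expect_false(identical(m1$params, m3$params))
  expect_identical(count_parameters(m1), count_parameters(m3))
})

test_that("invalid configurations are rejected", {
  expect_error(model_config(depth = 0), ">= 1")
  expect_error(model_config(depth = 6, patch_size = 48), "incompatible")
})

test_that("autoencoder pretraining reduces held-out reconstruction error deterministically", {
  ps <- tiny_patches(8)
  train <- ps[1:6]; held <- ps[7:8]
  m0 <- build_model(tiny_cfg())
  loss_before <- ae_reconstruction_loss(m0, held)
  m1 <- pretrain_autoencoder(m0, train, epochs = 3, seed = 5)
  expect_identical(m1$stage, "pretrained")
  expect_lt(ae_reconstruction_loss(m1, held), loss_before)
  expect_gt(m1$train_wall_time, 0)
  # seeded determinism
  m2 <- pretrain_autoencoder(m0, train, epochs = 3, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_equal(ae_reconstruction_loss(m1, held), ae_reconstruction_loss(m2, held))
  # epochs = 0 is a no-op
  m3 <- pretrain_autoencoder(m0, train, epochs = 0, seed = 5)
  expect_identical(m3$params, m0$params)
  expect_identical(m3$stage, "untrained")
  expect_error(pretrain_autoencoder(m0, list()), "at least 1")
})

test_that("training gate refuses too few annotated patches and all-unknown masks", {
  ps <- tiny_patches(6)
  m <- build_model(tiny_cfg())
  ps[[1]]$mask <- ps[[1]]$mask_full
  ps[[2]]$mask <- ps[[2]]$mask_full
  expect_error(finetune(m, ps[1:2]), "3 annotated patches required, got 2")
  # all-unknown masks carry no supervision at all
  expect_error(finetune(m, ps[3:6]), "got 0")
  # a custom gate threshold is honored and named in the message
  expect_error(finetune(m, ps[1:2], gate = training_gate(5)), "5 annotated")
})

test_that("unknown pixels carry zero loss weight and zero gradient", {
  set.seed(31)
  logits <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  masks <- array(sample(c(MASK_UNKNOWN, MASK_POSITIVE, MASK_NEGATIVE),
                        6 * 6 * 2, replace = TRUE), c(6, 6, 2))
  lg <- histannot:::seg_loss_grad(logits, masks, class_balance = FALSE)
  unk <- masks == MASK_UNKNOWN
  expect_true(all(lg$dlogits[, , , 1][unk] == 0))
  expect_true(all(lg$dlogits[, , , 2][unk] == 0))
  # loss equals plain cross-entropy computed independently over labeled pixels
  p1 <- 1 / (1 + exp(logits[, , , 2] - logits[, , , 1]))
  ce <- ifelse(masks == MASK_POSITIVE, -log(p1), -log(1 - p1))
  expect_equal(lg$loss, mean(ce[!unk]))
  # consequently an all-unknown patch in the training set changes nothing
  ps <- tiny_patches(6)
  for (i in 1:3) ps[[i]]$mask <- ps[[i]]$mask_full
  m <- build_model(tiny_cfg())
  m_with <- finetune(m, ps[1:6], epochs = 1, seed = 3, batch_size = 6)
  m_without <- finetune(m, ps[1:3], epochs = 1, seed = 3, batch_size = 6)
  expect_equal(m_with$params, m_without$params, tolerance = 1e-10)
})

test_that("fine-tuning improves held-out f-score over the untrained model", {
  ps <- tiny_patches(16)
  for (i in 1:10) ps[[i]]$mask <- ps[[i]]$mask_full
  m0 <- build_model(tiny_cfg())
  f_of <- function(m) mean(vapply(11:16, function(i)
    pixel_f_score(binarize(predict(m, ps[[i]])), ps[[i]]$gt_bin), numeric(1)))
  f_before <- f_of(m0)
  m1 <- finetune(m0, ps[1:10], epochs = 40, seed = 2, batch_size = 2)
  expect_identical(m1$stage, "finetuned")
  expect_gt(f_of(m1), f_before)
  expect_gt(f_of(m1), 0.5)
})

test_that("prediction maps are shaped, bounded and deterministic", {
  ps <- tiny_patches(2)
  m <- tiny_pretrained()
  pr <- predict(m, ps[[1]])
  expect_identical(dim(pr), dim(ps[[1]]$pixels)[1:2])
  expect_true(all(pr >= 0 & pr <= 1))
  expect_identical(pr, predict(m, ps[[1]]))
  # incompatible input size errors
  expect_error(predict(m, array(0, c(30, 30, 3))), "not divisible")
  # list input gives a list of maps
  both <- predict(m, ps)
  expect_length(both, 2L)
})

test_that("binarization thresholds with ties mapping to positive", {
  m <- matrix(c(0.2, 0.5, 0.8), 1, 3)
  expect_identical(as.vector(binarize(m, 0.5)), c(FALSE, TRUE, TRUE))
  expect_true(all(binarize(m, 0)))
  expect_false(any(binarize(m, 0.81)))
  expect_true(all(binarize(matrix(0.5, 2, 2), 0.5)))
  expect_error(binarize(m, 1.5), "in \\[0, 1\\]")
})
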