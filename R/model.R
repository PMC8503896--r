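#' Configuration of the compact segmentation network
#'
#' Describes a symmetric encoder-decoder ("u-net" style) network with skip
#' connections: `depth` resolution levels, channel width doubling per level
#' starting at `base_width`, two 3x3 convolutions (ReLU) per block, 2x2 max
#' pooling between encoder levels, and per-level upsampling followed by skip
#' concatenation and two 3x3 convolutions in the decoder. A 1x1 convolution
#' maps the full-resolution decoder features to `out_channels` class logits.
#'
#' The pinned defaults (depth 5, base width 4, nearest-neighbor upsampling
#' with a 1x1 projection, no normalization) define a deliberately compact
#' network of 113,570 trainable parameters that trains on a CPU in minutes.
#' Normalization-free blocks were chosen because fine-tuning batches here
#' are small (a handful of sparsely annotated patches), where batch
#' statistics are unreliable; the compact widths train stably without it.
#'
#' @param depth number of encoder levels (>= 1).
#' @param base_width channels of the first level; width doubles per level.
#' @param in_channels,out_channels input image channels and output classes.
#' @param upsample `"nearest"` (nearest-neighbor x2 followed by a 1x1
#'   projection) or `"transposed"` (learned 2x2 stride-2 transposed
#'   convolution).
#' @param norm normalization mode; this implementation is
#'   normalization-free (`"none"`).
#' @param patch_size side of the training patches; must be divisible by
#'   `2^(depth-1)` so the bottleneck is at least 1 px.
#' @param init_seed seed for weight initialization, making
#'   [build_model()] deterministic.
#' @return an object of class `model_config`.
#' @export
model_config <- function(depth = 5L, base_width = 4L, in_channels = 3L,
                         out_channels = 2L, upsample = c("nearest", "transposed"),
                         norm = "none", patch_size = 256L, init_seed = 1L) {
  upsample <- match.arg(upsample)
  norm <- match.arg(norm, "none")
  depth <- as.integer(depth); base_width <- as.integer(base_width)
  if (depth < 1L) stop_value("depth must be >= 1")
  if (base_width < 1L) stop_value("base_width must be >= 1")
  if (patch_size %% 2^(depth - 1L) != 0L || patch_size < 2^(depth - 1L))
    stop_value(paste0("patch_size %d incompatible with depth %d: ",
                      "the bottleneck must be a whole number of pixels "),
               patch_size, depth)
  structure(list(depth = depth, base_width = base_width,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 upsample = upsample, norm = norm,
                 patch_size = as.integer(patch_size),
                 init_seed = as.integer(init_seed)),
            class = "model_config")
}

#' Minimum-annotation gate for supervised training
#'
#' Fine-tuning is refused until at least `min_annotated_patches` patches
#' carry at least one annotated (non-unknown) pixel; training a pixel
#' classifier on fewer exemplars is not meaningful. The default of 3 is the
#' smallest training set the annotation workflow accepts.
#'
#' @param min_annotated_patches integer >= 1.
#' @return an object of class `training_gate`.
#' @export
training_gate <- function(min_annotated_patches = 3L) {
  if (min_annotated_patches < 1L) stop_value("min_annotated_patches must be >= 1")
  structure(list(min_annotated_patches = as.integer(min_annotated_patches)),
            class = "training_gate")
}

#' Build the segmentation network
#'
#' Instantiates the configured network with seeded He-initialized weights
#' in stage `"untrained"`. An auxiliary 1x1 reconstruction head (used only
#' by [pretrain_autoencoder()], not part of the segmentation network) is
#' created alongside.
#'
#' @param config a [model_config()].
#' @return an object of class `seg_model`.
#' @export
#' @examples
#' m <- build_model(model_config(depth = 2, base_width = 2, patch_size = 32))
#' count_parameters(m)
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  with_seed(config$init_seed, {
    params <- unet_init_params(config)
    aux <- unet_init_ae_head(config)
  })
  structure(list(config = config, params = params, aux = aux,
                 stage = "untrained", train_wall_time = 0,
                 log = list()), class = "seg_model")
}

#' Count trainable parameters
#'
#' Exact number of trainable scalars of the segmentation network (weights
#' and biases of every convolution including the classification head). The
#' auxiliary autoencoder reconstruction head is excluded: it is scaffolding
#' for pretraining, not part of the deployed network.
#'
#' @param model a `seg_model`.
#' @return integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "seg_model"))
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

check_patch_dims <- function(model, H, W) {
  f <- 2^(model$config$depth - 1L)
  if (H %% f != 0L || W %% f != 0L)
    stop_value("input %dx%d is not divisible by %d (depth %d network)",
               H, W, f, model$config$depth)
}

as_pixel_list <- function(patches) {
  lapply(patches, function(p) {
    px <- if (is.list(p) && !is.null(p$pixels)) p$pixels else p
    if (!is_rgb_array(px)) stop_value("patches must carry H x W x 3 pixel arrays")
    px
  })
}

#' Unsupervised autoencoder pretraining
#'
#' Trains the network body (through the auxiliary reconstruction head) to
#' reproduce its input patches under mean squared error. This initializes
#' the features from unlabeled data before any annotation exists, so that
#' patch embeddings are informative and fine-tuning converges from few
#' labels. With `epochs = 0` the model is returned unchanged.
#'
#' @param model a `seg_model` in stage `"untrained"` or `"pretrained"`.
#' @param patches list of patches (or plain H x W x 3 arrays).
#' @param epochs passes over the patch set.
#' @param seed RNG seed controlling shuffling; fixed seed and data give an
#'   identical model.
#' @param lr,batch_size Adam learning rate and minibatch size.
#' @return the trained `seg_model`, stage `"pretrained"`, with measured
#'   training wall time accumulated on `train_wall_time`.
#' @export
pretrain_autoencoder <- function(model, patches, epochs = 3L, seed = 1L,
                                 lr = 1e-3, batch_size = 4L) {
  stopifnot(inherits(model, "seg_model"))
  if (length(patches) == 0L) stop_value("pretraining requires at least 1 patch")
  if (!model$stage %in% c("untrained", "pretrained"))
    stop_value("pretraining requires an untrained or pretrained model, got stage '%s'",
               model$stage)
  if (epochs == 0L) return(model)
  px <- as_pixel_list(patches)
  d <- dim(px[[1L]]); check_patch_dims(model, d[1L], d[2L])
  t0 <- proc.time()[["elapsed"]]
  with_seed(seed, {
    trainable <- c(model$params, list(aux = model$aux))
    state <- adam_init(trainable)
    t <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(px))
      for (bi in split(ord, ceiling(seq_along(ord) / batch_size))) {
        x <- stack_batch(px[bi])
        fw <- unet_forward(model$params, x, model$config, head = "ae",
                           aux = trainable$aux)
        lg <- ae_loss_grad(fw$out, x)
        g <- unet_backward(model$params, model$config, fw$cache, lg$dout,
                           head = "ae", aux = trainable$aux)
        t <- t + 1L
        upd <- adam_step(trainable, g, state, lr, t)
        trainable <- upd$params; state <- upd$state
        model$params[names(model$params)] <- trainable[names(model$params)]
      }
    }
    model$aux <- trainable$aux
  })
  model$train_wall_time <- model$train_wall_time + (proc.time()[["elapsed"]] - t0)
  model$stage <- "pretrained"
  model
}

#' Held-out autoencoder reconstruction loss
#'
#' Mean squared reconstruction error of the current model on a patch set;
#' used to verify that pretraining reduced the reconstruction error.
#'
#' @param model a `seg_model`.
#' @param patches list of patches or pixel arrays.
#' @return mean squared error.
#' @export
ae_reconstruction_loss <- function(model, patches) {
  px <- as_pixel_list(patches)
  x <- stack_batch(px)
  fw <- unet_forward(model$params, x, model$config, head = "ae", aux = model$aux)
  mean((fw$out - x)^2)
}

#' Supervised fine-tuning on sparse three-class masks
#'
#' Fine-tunes the network on annotated patches with per-pixel cross-entropy.
#' Unknown pixels carry zero loss weight and therefore contribute no
#' gradient: sparse partial annotation is the intended supervision. Patches
#' whose mask is entirely unknown count as unannotated; the training gate
#' refuses to run below its minimum.
#'
#' @param model a `seg_model` (fine-tuning from an untrained model is
#'   allowed but noted in the model log).
#' @param patches list of patches carrying `pixels` and `mask`.
#' @param gate a [training_gate()].
#' @param epochs,seed,lr,batch_size as in [pretrain_autoencoder()].
#' @return the trained `seg_model`, stage `"finetuned"`.
#' @export
finetune <- function(model, patches, gate = training_gate(), epochs = 10L,
                     seed = 1L, lr = 3e-3, batch_size = 2L) {
  stopifnot(inherits(model, "seg_model"), inherits(gate, "training_gate"))
  has_ann <- vapply(patches, function(p) any(p$mask != MASK_UNKNOWN), logical(1))
  if (sum(has_ann) < gate$min_annotated_patches)
    stop_value("training gate: %d annotated patches required, got %d (patches with all-unknown masks carry no supervision)",
               gate$min_annotated_patches, sum(has_ann))
  patches <- patches[has_ann]
  if (model$stage == "untrained")
    model$log <- c(model$log, "finetuned directly from untrained weights (no pretraining)")
  px <- as_pixel_list(patches)
  mk <- lapply(patches, `[[`, "mask")
  d <- dim(px[[1L]]); check_patch_dims(model, d[1L], d[2L])
  t0 <- proc.time()[["elapsed"]]
  with_seed(seed, {
    state <- adam_init(model$params)
    t <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(px))
      for (bi in split(ord, ceiling(seq_along(ord) / batch_size))) {
        x <- stack_batch(px[bi])
        m <- stack_masks(mk[bi])
        fw <- unet_forward(model$params, x, model$config, head = "seg")
        lg <- seg_loss_grad(fw$out, m)
        if (lg$n_labeled == 0L) next
        g <- unet_backward(model$params, model$config, fw$cache, lg$dlogits,
                           head = "seg")
        t <- t + 1L
        upd <- adam_step(model$params, g, state, lr, t)
        model$params <- upd$params; state <- upd$state
      }
    }
  })
  model$train_wall_time <- model$train_wall_time + (proc.time()[["elapsed"]] - t0)
  model$stage <- "finetuned"
  model
}

#' Per-pixel positive-class probability map
#'
#' Runs the segmentation head on a patch and returns the softmax probability
#' of the positive class per pixel. Deterministic given the weights.
#'
#' @param object a `seg_model`.
#' @param newdata a patch, an H x W x 3 array, or a list of either.
#' @param ... unused.
#' @return a probability matrix in \[0, 1\] of the input shape, or a list of
#'   such matrices.
#' @export
predict.seg_model <- function(object, newdata, ...) {
  single <- is_rgb_array(newdata) || (is.list(newdata) && !is.null(newdata$pixels))
  px <- as_pixel_list(if (single) list(newdata) else newdata)
  d <- dim(px[[1L]])
  check_patch_dims(object, d[1L], d[2L])
  out <- lapply(px, function(x) {
    xb <- stack_batch(list(x))
    fw <- unet_forward(object$params, xb, object$config, head = "seg")
    a1 <- fw$out[, , 1L, 1L]; a2 <- fw$out[, , 1L, 2L]
    mx <- pmax(a1, a2)
    e1 <- exp(a1 - mx)
    e1 / (e1 + exp(a2 - mx))
  })
  if (single) out[[1L]] else out
}

#' Threshold a probability map into a suggestion mask
#'
#' A pixel is suggested positive when its probability is greater than or
#' equal to the threshold (ties go to positive).
#'
#' @param map probability matrix in \[0, 1\].
#' @param threshold cut-off in \[0, 1\].
#' @return logical matrix.
#' @export
binarize <- function(map, threshold = 0.5) {
  check_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  map >= threshold
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("model_config: depth %d, widths %s, %d->%d channels, %s upsampling, patch %d px\n",
              x$depth, paste(unet_channels(x), collapse = "-"),
              x$in_channels, x$out_channels, x$upsample, x$patch_size))
  invisible(x)
}

#' @export
print.seg_model <- function(x, ...) {
  print(x$config)
  cat(sprintf("stage: %s; %s trainable parameters; %.1f s training wall time\n",
              x$stage, format(count_parameters(x), big.mark = ","),
              x$train_wall_time))
  invisible(x)
}

# Internal: deep activations for the embedding and superpixel modules.
unet_capture <- function(model, pixels, what) {
  xb <- stack_batch(list(pixels))
  fw <- unet_forward(model$params, xb, model$config, head = "none",
                     capture = what)
  fw$captured
}
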