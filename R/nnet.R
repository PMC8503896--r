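# Minimal dense convolutional network machinery.
#
# Feature tensors are numeric arrays with dim c(H, W, N, C): the batch axis
# sits before channels so a (H*W*N) x C matrix view is a plain `dim<-`
# without copying/permuting. Convolutions are im2col + BLAS GEMM; gradients
# are derived by hand. Everything is deterministic given the RNG state.

conv3_init <- function(cin, cout) {
  list(W = matrix(rnorm(9L * cin * cout, 0, sqrt(2 / (9 * cin))), 9L * cin, cout),
       b = numeric(cout))
}

conv1_init <- function(cin, cout) {
  list(W = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

tconv2_init <- function(cin, cout) {
  # 2x2 stride-2 transposed conv: one cin x cout matrix per output sub-position
  list(W = matrix(rnorm(cin * 4L * cout, 0, sqrt(2 / cin)), cin, 4L * cout),
       b = numeric(cout))
}

# Gather/scatter index vectors for the 3x3 im2col are cached per tensor
# shape: building them costs as much as using them once, and the same few
# shapes recur thousands of times during training.
.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(H, W, N, C) {
  key <- paste(H, W, N, C, sep = "x")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (length(ls(.im2col_cache)) > 48L)
    rm(list = ls(.im2col_cache), envir = .im2col_cache)
  Hp <- H + 2L; Wp <- W + 2L
  base_hw <- rep(1:H, times = W) + Hp * rep(0:(W - 1L), each = H)
  base <- rep(base_hw, times = N) + Hp * Wp * rep(0:(N - 1L), each = H * W)
  offs <- integer(9L); k <- 0L
  for (dj in 0:2) for (di in 0:2) { k <- k + 1L; offs[k] <- di + Hp * dj }
  ch <- Hp * Wp * N * (0:(C - 1L))
  colshift <- as.vector(outer(ch, offs, `+`))          # c fastest within k
  gather <- rep(base, times = 9L * C) + rep(colshift, each = length(base))
  scatter <- lapply(1:9, function(k)
    rep(base, times = C) + rep(ch + offs[k], each = length(base)))
  out <- list(gather = gather, scatter = scatter)
  assign(key, out, envir = .im2col_cache)
  out
}

im2col3 <- function(x) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; N <- d[3L]; C <- d[4L]
  P <- array(0, c(H + 2L, W + 2L, N, C))
  P[2:(H + 1L), 2:(W + 1L), , ] <- x
  out <- P[im2col_indices(H, W, N, C)$gather]
  dim(out) <- c(H * W * N, 9L * C)
  out
}

col2im3 <- function(dxcol, H, W, N, C) {
  idx <- im2col_indices(H, W, N, C)$scatter
  dP <- numeric((H + 2L) * (W + 2L) * N * C)
  for (k in 1:9) {
    chunk <- dxcol[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
    ik <- idx[[k]]
    dP[ik] <- dP[ik] + as.vector(chunk)
  }
  dim(dP) <- c(H + 2L, W + 2L, N, C)
  dP[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

conv3_fwd <- function(x, p, xcol = NULL) {
  d <- dim(x)
  if (is.null(xcol)) xcol <- im2col3(x)
  y <- xcol %*% p$W
  y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(d[1L], d[2L], d[3L], ncol(p$W))
  y
}

conv3_bwd <- function(x, p, dy, xcol = NULL) {
  d <- dim(x)
  dym <- dy; dim(dym) <- c(prod(d[1:3]), dim(dy)[4L])
  if (is.null(xcol)) xcol <- im2col3(x)
  dW <- crossprod(xcol, dym)
  db <- colSums(dym)
  dxcol <- tcrossprod(dym, p$W)
  list(dx = col2im3(dxcol, d[1L], d[2L], d[3L], d[4L]), dW = dW, db = db)
}

conv1_fwd <- function(x, p) {
  d <- dim(x)
  m <- x; dim(m) <- c(prod(d[1:3]), d[4L])
  y <- m %*% p$W
  y <- y + rep(p$b, each = nrow(y))
  dim(y) <- c(d[1L], d[2L], d[3L], ncol(p$W))
  y
}

conv1_bwd <- function(x, p, dy) {
  d <- dim(x)
  m <- x; dim(m) <- c(prod(d[1:3]), d[4L])
  dym <- dy; dim(dym) <- c(prod(d[1:3]), dim(dy)[4L])
  dx <- tcrossprod(dym, p$W)
  dim(dx) <- d
  list(dx = dx, dW = crossprod(m, dym), db = colSums(dym))
}

relu_fwd <- function(x) { x[x < 0] <- 0; x }
relu_bwd <- function(y, dy) dy * (y > 0)

pool_slices <- function(x) {
  d <- dim(x)
  oh <- seq(1L, d[1L], 2L); ow <- seq(1L, d[2L], 2L)
  list(s00 = x[oh, ow, , , drop = FALSE], s10 = x[oh + 1L, ow, , , drop = FALSE],
       s01 = x[oh, ow + 1L, , , drop = FALSE], s11 = x[oh + 1L, ow + 1L, , , drop = FALSE])
}

maxpool2_fwd <- function(x) {
  s <- pool_slices(x)
  pmax(s$s00, s$s10, s$s01, s$s11)
}

maxpool2_bwd <- function(x, y, dy) {
  d <- dim(x)
  s <- pool_slices(x)
  dx <- array(0, d)
  oh <- seq(1L, d[1L], 2L); ow <- seq(1L, d[2L], 2L)
  claimed <- array(FALSE, dim(y))
  put <- function(dx, rows, cols, slice) {
    m <- (slice == y) & !claimed
    claimed <<- claimed | m
    dx[rows, cols, , ] <- dy * m
    dx
  }
  dx <- put(dx, oh, ow, s$s00)
  dx <- put(dx, oh + 1L, ow, s$s10)
  dx <- put(dx, oh, ow + 1L, s$s01)
  dx <- put(dx, oh + 1L, ow + 1L, s$s11)
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  s <- pool_slices(dy)
  s$s00 + s$s10 + s$s01 + s$s11
}

tconv2_fwd <- function(x, p) {
  d <- dim(x); O <- length(p$b)
  m <- x; dim(m) <- c(prod(d[1:3]), d[4L])
  ym <- m %*% p$W           # (HWN) x 4O, sub-positions (0,0),(1,0),(0,1),(1,1)
  y <- array(0, c(2L * d[1L], 2L * d[2L], d[3L], O))
  oh <- seq(1L, 2L * d[1L], 2L); ow <- seq(1L, 2L * d[2L], 2L)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    chunk <- ym[, ((k - 1L) * O + 1L):(k * O), drop = FALSE]
    dim(chunk) <- c(d[1L], d[2L], d[3L], O)
    y[oh + offs[[k]][1L], ow + offs[[k]][2L], , ] <- chunk
  }
  y + rep(p$b, each = prod(dim(y)[1:3]))
}

tconv2_bwd <- function(x, p, dy) {
  d <- dim(x); O <- length(p$b)
  m <- x; dim(m) <- c(prod(d[1:3]), d[4L])
  oh <- seq(1L, 2L * d[1L], 2L); ow <- seq(1L, 2L * d[2L], 2L)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  dym <- matrix(0, prod(d[1:3]), 4L * O)
  for (k in 1:4) {
    chunk <- dy[oh + offs[[k]][1L], ow + offs[[k]][2L], , , drop = FALSE]
    dim(chunk) <- c(prod(d[1:3]), O)
    dym[, ((k - 1L) * O + 1L):(k * O)] <- chunk
  }
  dx <- tcrossprod(dym, p$W)
  dim(dx) <- d
  dbm <- dy; dim(dbm) <- c(prod(dim(dy)[1:3]), O)
  list(dx = dx, dW = crossprod(m, dym), db = colSums(dbm))
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  z <- array(0, c(da[1:3], da[4L] + db[4L]))
  z[, , , seq_len(da[4L])] <- a
  z[, , , da[4L] + seq_len(db[4L])] <- b
  z
}

# ---- u-net assembly ---------------------------------------------------------

unet_channels <- function(cfg) cfg$base_width * 2^(0:(cfg$depth - 1L))

# Initialize all trainable parameters for the configured network (plus the
# segmentation head). Relies on the current RNG state.
unet_init_params <- function(cfg) {
  ch <- unet_channels(cfg)
  p <- list()
  cin <- cfg$in_channels
  for (l in seq_len(cfg$depth)) {
    p[[sprintf("enc%d.conv1", l)]] <- conv3_init(cin, ch[l])
    p[[sprintf("enc%d.conv2", l)]] <- conv3_init(ch[l], ch[l])
    cin <- ch[l]
  }
  for (l in rev(seq_len(cfg$depth - 1L))) {
    if (cfg$upsample == "nearest")
      p[[sprintf("dec%d.proj", l)]] <- conv1_init(cin, ch[l])
    else
      p[[sprintf("dec%d.proj", l)]] <- tconv2_init(cin, ch[l])
    p[[sprintf("dec%d.conv1", l)]] <- conv3_init(2L * ch[l], ch[l])
    p[[sprintf("dec%d.conv2", l)]] <- conv3_init(ch[l], ch[l])
    cin <- ch[l]
  }
  p[["head.seg"]] <- conv1_init(ch[1L], cfg$out_channels)
  p
}

unet_init_ae_head <- function(cfg) conv1_init(cfg$base_width, cfg$in_channels)

# Forward pass. head: "seg" (class logits), "ae" (reconstruction; requires
# `aux`), or "none" (body only). Returns the output, the cache needed for
# the backward pass, and any captured intermediate activations
# ("bottleneck" = deepest encoder block output, "dec_full" = full-resolution
# decoder block output).
unet_forward <- function(params, x, cfg, head = "seg", aux = NULL,
                         capture = character()) {
  depth <- cfg$depth
  cache <- list(x0 = x)
  captured <- list()
  cur <- x
  for (l in seq_len(depth)) {
    a1 <- relu_fwd(conv3_fwd(cur, params[[sprintf("enc%d.conv1", l)]]))
    a2 <- relu_fwd(conv3_fwd(a1, params[[sprintf("enc%d.conv2", l)]]))
    cache[[sprintf("enc%d.in", l)]] <- cur
    cache[[sprintf("enc%d.a1", l)]] <- a1
    cache[[sprintf("enc%d.a2", l)]] <- a2
    if (l < depth) {
      cur <- maxpool2_fwd(a2)
      cache[[sprintf("pool%d.out", l)]] <- cur
    } else cur <- a2
  }
  if ("bottleneck" %in% capture) captured$bottleneck <- cur
  for (l in rev(seq_len(depth - 1L))) {
    pj <- params[[sprintf("dec%d.proj", l)]]
    if (cfg$upsample == "nearest") {
      u0 <- upsample2_fwd(cur)
      u <- conv1_fwd(u0, pj)
      cache[[sprintf("dec%d.u0", l)]] <- u0
    } else {
      u <- tconv2_fwd(cur, pj)
    }
    cache[[sprintf("dec%d.in", l)]] <- cur
    z <- concat_c(u, cache[[sprintf("enc%d.a2", l)]])
    cache[[sprintf("dec%d.z", l)]] <- z
    a1 <- relu_fwd(conv3_fwd(z, params[[sprintf("dec%d.conv1", l)]]))
    a2 <- relu_fwd(conv3_fwd(a1, params[[sprintf("dec%d.conv2", l)]]))
    cache[[sprintf("dec%d.a1", l)]] <- a1
    cache[[sprintf("dec%d.a2", l)]] <- a2
    cur <- a2
  }
  if ("dec_full" %in% capture) captured$dec_full <- cur
  cache$body_out <- cur
  out <- switch(head,
    seg = conv1_fwd(cur, params[["head.seg"]]),
    ae = conv1_fwd(cur, aux),
    none = cur)
  list(out = out, cache = cache, captured = captured)
}

# Backward pass; `dout` is the gradient at the head output. Returns gradients
# keyed like `params` (plus `aux` when head = "ae").
unet_backward <- function(params, cfg, cache, dout, head = "seg", aux = NULL) {
  depth <- cfg$depth
  g <- list()
  if (head == "seg") {
    bb <- conv1_bwd(cache$body_out, params[["head.seg"]], dout)
    g[["head.seg"]] <- list(W = bb$dW, b = bb$db)
    dcur <- bb$dx
  } else {
    bb <- conv1_bwd(cache$body_out, aux, dout)
    g[["aux"]] <- list(W = bb$dW, b = bb$db)
    dcur <- bb$dx
  }
  dskip <- vector("list", depth)  # gradient flowing into each enc block output
  for (l in seq_len(depth - 1L)) {
    a1 <- cache[[sprintf("dec%d.a1", l)]]
    a2 <- cache[[sprintf("dec%d.a2", l)]]
    z <- cache[[sprintf("dec%d.z", l)]]
    d2 <- relu_bwd(a2, dcur)
    b2 <- conv3_bwd(a1, params[[sprintf("dec%d.conv2", l)]], d2)
    g[[sprintf("dec%d.conv2", l)]] <- list(W = b2$dW, b = b2$db)
    d1 <- relu_bwd(a1, b2$dx)
    b1 <- conv3_bwd(z, params[[sprintf("dec%d.conv1", l)]], d1)
    g[[sprintf("dec%d.conv1", l)]] <- list(W = b1$dW, b = b1$db)
    cu <- dim(z)[4L] / 2L
    du <- b1$dx[, , , seq_len(cu), drop = FALSE]
    dskip[[l]] <- b1$dx[, , , cu + seq_len(cu), drop = FALSE]
    pj <- params[[sprintf("dec%d.proj", l)]]
    if (cfg$upsample == "nearest") {
      bp <- conv1_bwd(cache[[sprintf("dec%d.u0", l)]], pj, du)
      g[[sprintf("dec%d.proj", l)]] <- list(W = bp$dW, b = bp$db)
      dcur <- upsample2_bwd(bp$dx)
    } else {
      bp <- tconv2_bwd(cache[[sprintf("dec%d.in", l)]], pj, du)
      g[[sprintf("dec%d.proj", l)]] <- list(W = bp$dW, b = bp$db)
      dcur <- bp$dx
    }
  }
  # dcur now holds the gradient at the bottleneck block output
  for (l in rev(seq_len(depth))) {
    if (l < depth) {
      dpool <- maxpool2_bwd(cache[[sprintf("enc%d.a2", l)]], cache[[sprintf("pool%d.out", l)]], dcur)
      da2 <- dpool + dskip[[l]]
    } else da2 <- dcur
    a1 <- cache[[sprintf("enc%d.a1", l)]]
    a2 <- cache[[sprintf("enc%d.a2", l)]]
    d2 <- relu_bwd(a2, da2)
    b2 <- conv3_bwd(a1, params[[sprintf("enc%d.conv2", l)]], d2)
    g[[sprintf("enc%d.conv2", l)]] <- list(W = b2$dW, b = b2$db)
    d1 <- relu_bwd(a1, b2$dx)
    b1 <- conv3_bwd(cache[[sprintf("enc%d.in", l)]], params[[sprintf("enc%d.conv1", l)]], d1)
    g[[sprintf("enc%d.conv1", l)]] <- list(W = b1$dW, b = b1$db)
    dcur <- b1$dx
  }
  g
}

# ---- losses -----------------------------------------------------------------

# Cross-entropy over two classes (channel 1 = positive, channel 2 = negative)
# with unknown pixels carrying zero weight. `masks` is (H, W, N) with
# annotation codes. With `class_balance` the two classes are reweighted to
# equal total weight, which matters because structures of interest often
# cover a few percent of the pixels. Returns loss and dlogits.
seg_loss_grad <- function(logits, masks, class_balance = TRUE) {
  a1 <- logits[, , , 1L]; a2 <- logits[, , , 2L]
  mx <- pmax(a1, a2)
  e1 <- exp(a1 - mx); e2 <- exp(a2 - mx)
  z <- e1 + e2
  p1 <- e1 / z
  w <- (masks != MASK_UNKNOWN) * 1
  nw <- sum(w)
  if (nw == 0)
    return(list(loss = NA_real_, dlogits = array(0, dim(logits)), n_labeled = 0L))
  ispos <- masks == MASK_POSITIVE
  isneg <- (w > 0) & !ispos
  if (class_balance) {
    n1 <- sum(ispos); n2 <- sum(isneg)
    if (n1 > 0 && n2 > 0) w <- ispos * (nw / (2 * n1)) + isneg * (nw / (2 * n2))
  }
  logp1 <- a1 - mx - log(z); logp2 <- a2 - mx - log(z)
  loss <- -(sum((w * logp1)[ispos]) + sum((w * logp2)[isneg])) / nw
  d <- array(0, dim(logits))
  d[, , , 1L] <- (p1 - ispos) * w / nw
  d[, , , 2L] <- ((1 - p1) - isneg) * w / nw
  list(loss = loss, dlogits = d, n_labeled = sum(w > 0))
}

ae_loss_grad <- function(out, x) {
  diff <- out - x
  list(loss = mean(diff^2), dout = 2 * diff / length(diff))
}

# ---- optimizer --------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(mW = p$W * 0, vW = p$W * 0,
                                  mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (nm in names(grads)) {
    s <- state[[nm]]; gr <- grads[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * gr$W
    s$vW <- beta2 * s$vW + (1 - beta2) * gr$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * gr$b
    s$vb <- beta2 * s$vb + (1 - beta2) * gr$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) / (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

# Stack a list of H x W x 3 pixel arrays into an (H, W, N, 3) batch tensor.
stack_batch <- function(pixel_list) {
  d <- dim(pixel_list[[1L]])
  x <- array(0, c(d[1L], d[2L], length(pixel_list), d[3L]))
  for (n in seq_along(pixel_list)) x[, , n, ] <- pixel_list[[n]]
  x
}

stack_masks <- function(mask_list) {
  d <- dim(mask_list[[1L]])
  m <- array(MASK_UNKNOWN, c(d[1L], d[2L], length(mask_list)))
  for (n in seq_along(mask_list)) m[, , n] <- mask_list[[n]]
  m
}
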