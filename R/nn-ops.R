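# Differentiable tensor operations. Each op_* takes a tape and parent node ids,
# runs the forward computation immediately, and registers a VJP closure.

op_conv2d <- function(tp, x, w, b, stride = 1L, pad = 0L, need_dx = TRUE) {
  xv <- tg_value(tp, x); wv <- tg_value(tp, w); bv <- tg_value(tp, b)
  y <- cpp_conv2d_fw(xv, wv, bv, as.integer(stride), as.integer(pad))
  tg_push(tp, y, c(x, w, b), function(dy) {
    r <- cpp_conv2d_bw(xv, wv, dy, as.integer(stride), as.integer(pad), need_dx)
    list(if (need_dx) r$dx, r$dw, r$db)
  })
}

op_tconv2d <- function(tp, x, w, b, stride = 2L) {
  xv <- tg_value(tp, x); wv <- tg_value(tp, w); bv <- tg_value(tp, b)
  y <- cpp_tconv2d_fw(xv, wv, bv, as.integer(stride))
  tg_push(tp, y, c(x, w, b), function(dy) {
    r <- cpp_tconv2d_bw(xv, wv, dy, as.integer(stride))
    list(r$dx, r$dw, r$db)
  })
}

op_conv3d <- function(tp, x, w, b, stride = 1L, pad = 0L, need_dx = TRUE) {
  xv <- tg_value(tp, x); wv <- tg_value(tp, w); bv <- tg_value(tp, b)
  y <- cpp_conv3d_fw(xv, wv, bv, as.integer(stride), as.integer(pad))
  tg_push(tp, y, c(x, w, b), function(dy) {
    r <- cpp_conv3d_bw(xv, wv, dy, as.integer(stride), as.integer(pad), need_dx)
    list(if (need_dx) r$dx, r$dw, r$db)
  })
}

op_maxpool2 <- function(tp, x) {
  xv <- tg_value(tp, x)
  r <- cpp_maxpool2_fw(xv)
  dimx <- dim(xv)
  tg_push(tp, r$y, x, function(dy) list(cpp_maxpool2_bw(dy, r$idx, dimx)))
}

op_maxpool3 <- function(tp, x) {
  xv <- tg_value(tp, x)
  r <- cpp_maxpool3_fw(xv)
  dimx <- dim(xv)
  tg_push(tp, r$y, x, function(dy) list(cpp_maxpool3_bw(dy, r$idx, dimx)))
}

# Nearest-neighbour 2x upsampling of (H, W, C, N) arrays.
op_upnearest2 <- function(tp, x) {
  xv <- tg_value(tp, x)
  d <- dim(xv)
  ih <- rep(seq_len(d[1]), each = 2L); iw <- rep(seq_len(d[2]), each = 2L)
  y <- xv[ih, iw, , , drop = FALSE]
  tg_push(tp, y, x, function(dy) {
    o1 <- seq(1L, 2L * d[1], 2L); e1 <- o1 + 1L
    o2 <- seq(1L, 2L * d[2], 2L); e2 <- o2 + 1L
    list(dy[o1, o2, , , drop = FALSE] + dy[e1, o2, , , drop = FALSE] +
         dy[o1, e2, , , drop = FALSE] + dy[e1, e2, , , drop = FALSE])
  })
}

op_relu <- function(tp, x) {
  xv <- tg_value(tp, x)
  y <- cpp_relu_fw(xv)
  tg_push(tp, y, x, function(dy) list(cpp_relu_bw(y, dy)))
}

op_sigmoid <- function(tp, x) {
  xv <- tg_value(tp, x)
  y <- array(plogis(xv), dim(xv))
  tg_push(tp, y, x, function(dy) list(dy * y * (1 - y)))
}

op_add <- function(tp, a, b) {
  av <- tg_value(tp, a); bv <- tg_value(tp, b)
  tg_push(tp, av + bv, c(a, b), function(dy) list(dy, dy))
}

# x: (H, W, C, N) gated by a single-channel attention map a: (H, W, 1, N).
op_attn_mul <- function(tp, x, a) {
  xv <- tg_value(tp, x); av <- tg_value(tp, a)
  C <- dim(xv)[3]
  arep <- av[, , rep(1L, C), , drop = FALSE]
  tg_push(tp, xv * arep, c(x, a), function(dy) {
    da_full <- dy * xv
    d <- dim(da_full)
    m <- aperm(array(da_full, c(d[1] * d[2], d[3], d[4])), c(2, 1, 3))
    da <- array(colSums(m), c(d[1], d[2], 1L, d[4]))
    list(dy * arep, da)
  })
}

op_concat_ch <- function(tp, a, b) {
  av <- tg_value(tp, a); bv <- tg_value(tp, b)
  da <- dim(av); db_ <- dim(bv)
  y <- array(0, c(da[1], da[2], da[3] + db_[3], da[4]))
  y[, , seq_len(da[3]), ] <- av
  y[, , da[3] + seq_len(db_[3]), ] <- bv
  tg_push(tp, y, c(a, b), function(dy)
    list(dy[, , seq_len(da[3]), , drop = FALSE],
         dy[, , da[3] + seq_len(db_[3]), , drop = FALSE]))
}

# Flatten a (..., N) array into an N x F matrix (features within an image stay
# contiguous in the original column-major order).
op_flatten <- function(tp, x) {
  xv <- tg_value(tp, x)
  d <- dim(xv)
  N <- d[length(d)]
  f <- prod(d[-length(d)])
  y <- t(array(xv, c(f, N)))
  tg_push(tp, y, x, function(dy) list(array(t(dy), d)))
}

# Dense layer: x (N x Fin) %*% w (Fin x U) + b.
op_dense <- function(tp, x, w, b) {
  xv <- tg_value(tp, x); wv <- tg_value(tp, w); bv <- tg_value(tp, b)
  y <- sweep(xv %*% wv, 2, bv, "+")
  tg_push(tp, y, c(x, w, b), function(dy)
    list(dy %*% t(wv), t(xv) %*% dy, colSums(dy)))
}

# Inverted dropout; identity when train = FALSE. Uses the R RNG.
op_dropout <- function(tp, x, rate, train) {
  if (!train || rate <= 0) return(x)
  xv <- tg_value(tp, x)
  keep <- array(runif(length(xv)) >= rate, dim(xv)) / (1 - rate)
  tg_push(tp, xv * keep, x, function(dy) list(dy * keep))
}

# Mean binary cross-entropy evaluated on logits (numerically stable form).
op_bce_logits <- function(tp, logits, target) {
  zv <- tg_value(tp, logits)
  m <- length(zv)
  loss <- sum(pmax(zv, 0) - zv * target + log1p(exp(-abs(zv)))) / m
  tg_push(tp, loss, logits, function(dy) list(dy * (plogis(zv) - target) / m))
}

# Soft Dice loss on logits, computed over the whole batch.
op_dice_loss <- function(tp, logits, target, smooth = 1) {
  zv <- tg_value(tp, logits)
  p <- plogis(zv)
  num <- 2 * sum(p * target) + smooth
  den <- sum(p) + sum(target) + smooth
  loss <- 1 - num / den
  tg_push(tp, loss, logits, function(dy) {
    dp <- -(2 * target * den - num) / den^2
    list(dy * dp * p * (1 - p))
  })
}

op_scale_add <- function(tp, a, b, wa = 1, wb = 1) {
  av <- tg_value(tp, a); bv <- tg_value(tp, b)
  tg_push(tp, wa * av + wb * bv, c(a, b), function(dy) list(dy * wa, dy * wb))
}

seg_loss_op <- function(tp, logits, target, type = c("bce", "dice", "bce+dice")) {
  type <- match.arg(type)
  switch(type,
    "bce"  = op_bce_logits(tp, logits, target),
    "dice" = op_dice_loss(tp, logits, target),
    "bce+dice" = op_scale_add(tp, op_bce_logits(tp, logits, target),
                              op_dice_loss(tp, logits, target)))
}

# Nearest-neighbour 2x upsampling of (D1, D2, D3, C, N) volumes.
op_upnearest3 <- function(tp, x) {
  xv <- tg_value(tp, x)
  d <- dim(xv)
  i1 <- rep(seq_len(d[1]), each = 2L)
  i2 <- rep(seq_len(d[2]), each = 2L)
  i3 <- rep(seq_len(d[3]), each = 2L)
  y <- xv[i1, i2, i3, , , drop = FALSE]
  tg_push(tp, y, x, function(dy) {
    dx <- array(0, d)
    for (a in 0:1) for (b in 0:1) for (cc in 0:1)
      dx <- dx + dy[seq(1L + a, 2L * d[1], 2L), seq(1L + b, 2L * d[2], 2L),
                    seq(1L + cc, 2L * d[3], 2L), , , drop = FALSE]
    list(dx)
  })
}

# Inverse of op_flatten: N x F matrix -> (dims..., N) array.
op_unflatten <- function(tp, x, dims) {
  xv <- tg_value(tp, x)
  N <- nrow(xv)
  y <- array(t(xv), c(dims, N))
  tg_push(tp, y, x, function(dy) list(t(array(dy, c(prod(dims), N)))))
}
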