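#' Attention U-Net specification
#'
#' Describes the segmentation network: a four-level convolutional encoder
#' (two 3x3 convolutions + ReLU per level, 2x2 max pooling between levels), a
#' bottleneck block, and a mirrored decoder that upsamples with 2x2-stride
#' transposed convolutions and fuses skip connections through additive soft
#' attention gates. A final 1x1 convolution with sigmoid activation produces a
#' per-pixel foreground probability. With the default widths the network has
#' 33,123,781 trainable parameters for a 5-channel input.
#'
#' The attention gate at each decoder level compares the skip feature map
#' (via a bias-free 2x2 stride-2 convolution) with the coarser decoder feature
#' acting as gating signal (via a 1x1 convolution), passes the sum through
#' ReLU and a 1x1 convolution to a single sigmoid attention map, upsamples it,
#' and gates the skip connection multiplicatively before concatenation.
#'
#' @param in_channels input channels: 5 for the texture-augmented tensor,
#'   3 for raw RGB, 1 for the mask-refinement stage.
#' @param encoder_filters widths of the four encoder levels.
#' @param bottleneck_filters width of the bottleneck block.
#' @param input_size expected square input size; must be divisible by 16.
#' @return an object of class `aunet_spec`.
#' @export
aunet_spec <- function(in_channels = 5L, encoder_filters = c(64L, 128L, 256L, 512L),
                       bottleneck_filters = 2L * encoder_filters[4],
                       input_size = 256L) {
  if (input_size %% 16L != 0L) stop("input_size must be divisible by 16")
  if (length(encoder_filters) != 4L) stop("encoder_filters must have length 4")
  structure(list(in_channels = as.integer(in_channels),
                 encoder_filters = as.integer(encoder_filters),
                 bottleneck_filters = as.integer(bottleneck_filters),
                 input_size = as.integer(input_size)),
            class = "aunet_spec")
}

#' Build an attention U-Net
#'
#' Allocates and initialises (He initialisation) all trainable parameters for
#' the architecture described by [aunet_spec()].
#'
#' @param spec an [aunet_spec()].
#' @param seed optional integer seed for reproducible initialisation.
#' @return an object of class `aunet` with elements `spec`, `params` and
#'   `trained`.
#' @export
build_aunet <- function(spec = aunet_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ef <- spec$encoder_filters
  p <- list()
  prev <- spec$in_channels
  for (i in seq_len(4L)) {
    f <- ef[i]
    p[[paste0("enc", i, "_w1")]] <- he_conv(3, 3, prev, f)
    p[[paste0("enc", i, "_b1")]] <- numeric(f)
    p[[paste0("enc", i, "_w2")]] <- he_conv(3, 3, f, f)
    p[[paste0("enc", i, "_b2")]] <- numeric(f)
    prev <- f
  }
  bf <- spec$bottleneck_filters
  p$bot_w1 <- he_conv(3, 3, prev, bf); p$bot_b1 <- numeric(bf)
  p$bot_w2 <- he_conv(3, 3, bf, bf);   p$bot_b2 <- numeric(bf)
  prev <- bf
  for (j in seq_len(4L)) {
    f <- rev(ef)[j]
    p[[paste0("dec", j, "_up_w")]] <- he_tconv(2, 2, f, prev)
    p[[paste0("dec", j, "_up_b")]] <- numeric(f)
    p[[paste0("dec", j, "_theta_w")]] <- he_conv(2, 2, f, f)  # bias-free
    p[[paste0("dec", j, "_phi_w")]] <- he_conv(1, 1, prev, f)
    p[[paste0("dec", j, "_phi_b")]] <- numeric(f)
    p[[paste0("dec", j, "_psi_w")]] <- he_conv(1, 1, f, 1)
    p[[paste0("dec", j, "_psi_b")]] <- numeric(1)
    p[[paste0("dec", j, "_w1")]] <- he_conv(3, 3, 2 * f, f)
    p[[paste0("dec", j, "_b1")]] <- numeric(f)
    p[[paste0("dec", j, "_w2")]] <- he_conv(3, 3, f, f)
    p[[paste0("dec", j, "_b2")]] <- numeric(f)
    prev <- f
  }
  p$final_w <- he_conv(1, 1, ef[1], 1)
  p$final_b <- numeric(1)
  structure(list(spec = spec, params = p, trained = FALSE), class = "aunet")
}

#' Count trainable parameters
#'
#' @param model an `aunet`, `saunet`, `autoencoder`, `cnn3d`, `gan_classifier`
#'   or any object with a `params` list of numeric arrays.
#' @return number of trainable parameters, in millions.
#' @export
count_parameters <- function(model) {
  collect <- function(m) {
    if (!is.null(m$params)) return(sum(vapply(m$params, length, 0)))
    if (!is.null(m$stage1)) return(collect(m$stage1) + collect(m$stage2))
    stop("no parameters found")
  }
  collect(model) / 1e6
}

# conv block: two 3x3 same-padding convolutions, each followed by ReLU
.cb <- function(tp, x, ids, pre, need_dx = TRUE) {
  h <- op_relu(tp, op_conv2d(tp, x, ids[[paste0(pre, "_w1")]],
                             ids[[paste0(pre, "_b1")]], 1L, 1L, need_dx))
  op_relu(tp, op_conv2d(tp, h, ids[[paste0(pre, "_w2")]],
                        ids[[paste0(pre, "_b2")]], 1L, 1L))
}

# Forward pass; returns the logits node id. `ids` maps parameter names to
# already-registered tape leaves.
aunet_forward <- function(tp, ids, x_id) {
  skips <- list()
  h <- x_id
  for (i in seq_len(4L)) {
    h <- .cb(tp, h, ids, paste0("enc", i), need_dx = i > 1L)
    skips[[i]] <- h
    h <- op_maxpool2(tp, h)
  }
  h <- .cb(tp, h, ids, "bot")
  for (j in seq_len(4L)) {
    pre <- paste0("dec", j)
    skip <- skips[[5L - j]]
    up <- op_tconv2d(tp, h, ids[[paste0(pre, "_up_w")]],
                     ids[[paste0(pre, "_up_b")]], 2L)
    f <- dim(tg_value(tp, ids[[paste0(pre, "_theta_w")]]))[4]
    zero_b <- tg_leaf(tp, numeric(f))
    theta <- op_conv2d(tp, skip, ids[[paste0(pre, "_theta_w")]], zero_b, 2L, 0L)
    phi <- op_conv2d(tp, h, ids[[paste0(pre, "_phi_w")]],
                     ids[[paste0(pre, "_phi_b")]], 1L, 0L)
    q <- op_relu(tp, op_add(tp, theta, phi))
    a <- op_sigmoid(tp, op_conv2d(tp, q, ids[[paste0(pre, "_psi_w")]],
                                  ids[[paste0(pre, "_psi_b")]], 1L, 0L))
    att <- op_attn_mul(tp, skip, op_upnearest2(tp, a))
    h <- .cb(tp, op_concat_ch(tp, up, att), ids, pre)
  }
  op_conv2d(tp, h, ids$final_w, ids$final_b, 1L, 0L)
}

# Register params on a fresh tape and run forward + loss; returns everything
# needed for one optimisation step.
aunet_step <- function(params, x, y, loss_type) {
  tp <- tg_new()
  ids <- lapply(params, function(p) tg_leaf(tp, p))
  x_id <- tg_leaf(tp, x)
  logits <- aunet_forward(tp, ids, x_id)
  loss_id <- seg_loss_op(tp, logits, y, loss_type)
  grads_all <- tg_backward(tp, loss_id)
  grads <- lapply(ids, function(i) grads_all[[i]])
  list(loss = tg_value(tp, loss_id), grads = grads)
}

aunet_infer <- function(params, x) {
  tp <- tg_new()
  ids <- lapply(params, function(p) tg_leaf(tp, p))
  logits <- aunet_forward(tp, ids, tg_leaf(tp, x))
  array(plogis(tg_value(tp, logits)), dim(tg_value(tp, logits)))
}

# Minibatched inference to bound memory.
aunet_infer_batched <- function(params, x, batch = 16L) {
  n <- dim(x)[4]
  out <- NULL
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    p <- aunet_infer(params, x[, , , s, drop = FALSE])
    if (is.null(out)) out <- array(0, c(dim(p)[1:3], n))
    out[, , , s] <- p
  }
  out
}

#' Train a segmentation model
#'
#' Fits an [build_aunet()] model (or each stage of a [build_saunet()] pair) to
#' a dataset of input tensors and binary masks by minimising the configured
#' loss with Adam. For the sequential model the first stage is trained on the
#' input tensors, its predicted soft masks are then computed for the whole
#' training set, and the second stage is trained to map those soft masks onto
#' the same ground truth (stage-wise training).
#'
#' @param model an `aunet` or `saunet`.
#' @param x numeric array `(H, W, C, N)` of network inputs in `[0, 1]`.
#' @param y numeric array `(H, W, 1, N)` of binary masks.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return the trained model, with a `history` element (per-epoch mean
#'   training loss; for `saunet`, one history per stage).
#' @export
train_segmenter <- function(model, x, y, cfg = train_config(), verbose = FALSE) {
  stopifnot(length(dim(x)) == 4L, length(dim(y)) == 4L,
            dim(x)[4] == dim(y)[4], dim(x)[4] >= 1L)
  if (inherits(model, "saunet")) return(train_saunet_(model, x, y, cfg, verbose))
  if (!inherits(model, "aunet")) stop("model must be an aunet or saunet")
  if (dim(x)[3] != model$spec$in_channels)
    stop("input has ", dim(x)[3], " channels; spec expects ", model$spec$in_channels)
  empty <- mean(apply(y, 4, sum) == 0)
  if (empty > 0.5) warning("more than half of the training masks are empty")
  set.seed(cfg$seed)
  fit <- nn_fit(model$params, dim(x)[4], cfg, function(params, idx) {
    aunet_step(params, x[, , , idx, drop = FALSE], y[, , , idx, drop = FALSE],
               cfg$loss)
  }, verbose)
  model$params <- fit$params
  model$history <- fit$history
  model$trained <- TRUE
  model
}

#' Sequential attention U-Net (two stages)
#'
#' The first stage maps the (possibly texture-augmented) input to a soft mask;
#' the second stage takes that single-channel soft mask and refines boundary
#' detail. Both stages share the same architecture apart from the input width.
#'
#' @param in_channels input channels of the first stage.
#' @param encoder_filters,bottleneck_filters,input_size passed to [aunet_spec()].
#' @param seed optional seed for reproducible initialisation.
#' @return an object of class `saunet` with `stage1` and `stage2`.
#' @export
build_saunet <- function(in_channels = 5L, encoder_filters = c(64L, 128L, 256L, 512L),
                         bottleneck_filters = 2L * encoder_filters[4],
                         input_size = 256L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s1 <- build_aunet(aunet_spec(in_channels, encoder_filters, bottleneck_filters,
                               input_size))
  s2 <- build_aunet(aunet_spec(1L, encoder_filters, bottleneck_filters,
                               input_size))
  structure(list(stage1 = s1, stage2 = s2, trained = FALSE), class = "saunet")
}

train_saunet_ <- function(model, x, y, cfg, verbose) {
  model$stage1 <- train_segmenter(model$stage1, x, y, cfg, verbose)
  soft1 <- aunet_infer_batched(model$stage1$params, x)
  cfg2 <- cfg
  cfg2$seed <- cfg$seed + 1L
  model$stage2 <- train_segmenter(model$stage2, soft1, y, cfg2, verbose)
  model$history <- list(stage1 = model$stage1$history, stage2 = model$stage2$history)
  model$trained <- TRUE
  model
}

#' Predict a segmentation mask
#'
#' Runs a trained model on one or more images. For 5-channel models the
#' texture-augmented input tensor is built internally from the RGB image; for
#' 3-channel models the RGB planes are used directly. For a sequential model
#' the stage-1 soft mask is passed through stage 2 and the stage-2 output is
#' returned.
#'
#' @param model trained `aunet` or `saunet`.
#' @param image either an `H x W x 3` integer RGB image (0-255) or a
#'   pre-built `(H, W, C, N)` input array in `[0, 1]`.
#' @param threshold probability threshold for the binary mask.
#' @return list with `probs` (`H x W x N` array, or `H x W` for one image)
#'   and `mask` (same shape, values 0/1).
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  trained <- isTRUE(model$trained)
  if (!trained) warning("model has not been trained; predictions are from random weights")
  in_ch <- if (inherits(model, "saunet")) model$stage1$spec$in_channels
           else model$spec$in_channels
  x <- prep_input(image, in_ch)
  probs <- if (inherits(model, "saunet")) {
    soft1 <- aunet_infer_batched(model$stage1$params, x)
    aunet_infer_batched(model$stage2$params, soft1)
  } else {
    aunet_infer_batched(model$params, x)
  }
  squeeze <- function(a) if (dim(a)[4] == 1L) a[, , 1L, 1L] else a[, , 1L, ]
  list(probs = squeeze(probs), mask = squeeze((probs >= threshold) * 1))
}

prep_input <- function(image, in_ch) {
  if (length(dim(image)) == 4L) {
    if (dim(image)[3] != in_ch) stop("input channel mismatch")
    return(image)
  }
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be H x W x 3 (RGB) or a prepared (H, W, C, N) array")
  if (in_ch == 5L) {
    t5 <- build_input_tensor(image)
    array(t5, c(dim(t5), 1L))
  } else if (in_ch == 3L) {
    array(image / 255, c(dim(image), 1L))
  } else {
    stop("cannot build a ", in_ch, "-channel input from an RGB image")
  }
}
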