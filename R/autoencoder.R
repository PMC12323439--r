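# Convolutional autoencoder compressing segmented masks into a spatial
# latent volume, plus the latent-space analysis tools (2D projection, group
# means, nearest-mean scoring).

#' Build the mask autoencoder
#'
#' Encoder: two 3x3 convolutions (32 and 64 filters by default), each
#' followed by ReLU and 2x2 max pooling; for a 256 x 256 mask the latent is
#' therefore 64 x 64 with 64 channels -- a 64 x 64 x 64 volume. Decoder:
#' mirrored convolutions with 2x nearest upsampling and a final 3x3
#' reconstruction head (sigmoid).
#'
#' @param filters encoder filter counts (length 2).
#' @param input_size mask side in pixels (divisible by 4).
#' @param seed optional initialisation seed.
#' @return object of class `autoencoder`.
#' @export
build_autoencoder <- function(filters = c(32L, 64L), input_size = 256L,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (input_size %% 4L != 0L) stop("input_size must be divisible by 4")
  f1 <- filters[1]; f2 <- filters[2]
  p <- list(
    e1_w = he_conv(3, 3, 1, f1), e1_b = numeric(f1),
    e2_w = he_conv(3, 3, f1, f2), e2_b = numeric(f2),
    d1_w = he_conv(3, 3, f2, f2), d1_b = numeric(f2),
    d2_w = he_conv(3, 3, f2, f1), d2_b = numeric(f1),
    out_w = he_conv(3, 3, f1, 1), out_b = numeric(1))
  structure(list(spec = list(filters = as.integer(filters),
                             input_size = as.integer(input_size)),
                 params = p, trained = FALSE),
            class = "autoencoder")
}

ae_encode_graph <- function(tp, ids, x_id) {
  h <- op_maxpool2(tp, op_relu(tp, op_conv2d(tp, x_id, ids$e1_w, ids$e1_b, 1L, 1L, need_dx = FALSE)))
  op_maxpool2(tp, op_relu(tp, op_conv2d(tp, h, ids$e2_w, ids$e2_b, 1L, 1L)))
}

ae_forward <- function(tp, ids, x_id) {
  z <- ae_encode_graph(tp, ids, x_id)
  h <- op_upnearest2(tp, op_relu(tp, op_conv2d(tp, z, ids$d1_w, ids$d1_b, 1L, 1L)))
  h <- op_upnearest2(tp, op_relu(tp, op_conv2d(tp, h, ids$d2_w, ids$d2_b, 1L, 1L)))
  op_conv2d(tp, h, ids$out_w, ids$out_b, 1L, 1L)
}

#' Fit the autoencoder to binary masks
#'
#' Minimises the reconstruction loss (binary cross-entropy by default,
#' `loss = "mse"` optionally) with Adam.
#'
#' @param ae an [build_autoencoder()] model.
#' @param masks list of `H x W` binary matrices, or an `(H, W, 1, N)` array.
#' @param cfg a [train_config()]; its `loss` field selects `"bce"` or
#'   `"mse"`.
#' @param verbose print per-epoch losses.
#' @return trained autoencoder with `history`.
#' @export
fit_autoencoder <- function(ae, masks, cfg = train_config(), verbose = FALSE) {
  x <- masks_to_array(masks)
  if (dim(x)[1] != ae$spec$input_size)
    stop("masks are ", dim(x)[1], " px; autoencoder expects ", ae$spec$input_size)
  if (dim(x)[4] == 0L) stop("empty dataset")
  loss_type <- if (identical(cfg$loss, "mse")) "mse" else "bce"
  set.seed(cfg$seed)
  fit <- nn_fit(ae$params, dim(x)[4], cfg, function(params, idx) {
    xb <- x[, , , idx, drop = FALSE]
    tp <- tg_new()
    ids <- lapply(params, function(p) tg_leaf(tp, p))
    logits <- ae_forward(tp, ids, tg_leaf(tp, xb))
    loss_id <- if (loss_type == "bce") op_bce_logits(tp, logits, xb)
               else op_mse(tp, op_sigmoid(tp, logits), xb)
    grads_all <- tg_backward(tp, loss_id)
    list(loss = tg_value(tp, loss_id),
         grads = lapply(ids, function(i) grads_all[[i]]))
  }, verbose)
  ae$params <- fit$params
  ae$history <- fit$history
  ae$trained <- TRUE
  ae
}

masks_to_array <- function(masks) {
  if (is.list(masks)) {
    if (length(masks) == 0L) stop("empty mask list")
    d <- dim(masks[[1]])
    x <- array(0, c(d[1], d[2], 1L, length(masks)))
    for (i in seq_along(masks)) x[, , 1L, i] <- (masks[[i]] != 0) * 1
    x
  } else if (length(dim(masks)) == 4L) masks
  else stop("masks must be a list of matrices or an (H, W, 1, N) array")
}

#' Encode masks into latent volumes
#'
#' @param ae trained [build_autoencoder()].
#' @param masks list of masks or `(H, W, 1, N)` array.
#' @param batch minibatch size for inference.
#' @return `(H/4, W/4, C, N)` array of latents (64 x 64 x 64 x N for
#'   256 x 256 masks with default filters).
#' @export
encode_masks <- function(ae, masks, batch = 8L) {
  x <- masks_to_array(masks)
  n <- dim(x)[4]
  out <- NULL
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    tp <- tg_new()
    ids <- lapply(ae$params, function(p) tg_leaf(tp, p))
    z <- tg_value(tp, ae_encode_graph(tp, ids, tg_leaf(tp, x[, , , s, drop = FALSE])))
    if (is.null(out)) out <- array(0, c(dim(z)[1:3], n))
    out[, , , s] <- z
  }
  out
}

#' Reconstruct masks through the autoencoder
#'
#' @param ae trained autoencoder.
#' @param masks list of masks or array.
#' @return `(H, W, 1, N)` array of reconstruction probabilities.
#' @export
reconstruct_masks <- function(ae, masks) {
  x <- masks_to_array(masks)
  tp <- tg_new()
  ids <- lapply(ae$params, function(p) tg_leaf(tp, p))
  logits <- ae_forward(tp, ids, tg_leaf(tp, x))
  v <- tg_value(tp, logits)
  array(plogis(v), dim(v))
}

# mean squared error loss node
op_mse <- function(tp, pred, target) {
  pv <- tg_value(tp, pred)
  m <- length(pv)
  tg_push(tp, sum((pv - target)^2) / m, pred,
          function(dy) list(dy * 2 * (pv - target) / m))
}

#' Project a latent volume to 2D
#'
#' Averages the latent across its channel (z) axis.
#' @param latent `(H, W, C)` array (one subject) or `(H, W, C, N)`.
#' @return `H x W` matrix, or `(H, W, N)` array for multiple subjects.
#' @export
project_2d <- function(latent) {
  d <- dim(latent)
  if (length(d) == 3L) return(apply(latent, c(1, 2), mean))
  if (length(d) == 4L) {
    out <- array(0, c(d[1], d[2], d[4]))
    for (i in seq_len(d[4])) out[, , i] <- apply(latent[, , , i], c(1, 2), mean)
    return(out)
  }
  stop("latent must be 3D or 4D")
}

#' Group-average 2D latent
#'
#' Channel-averages each subject's latent and then averages across the
#' subjects of one group.
#'
#' @param latents `(H, W, C, N)` array of latent volumes.
#' @param labels length-N vector of group labels.
#' @param label group to average.
#' @return `H x W` matrix.
#' @export
group_mean_latent <- function(latents, labels, label) {
  sel <- which(labels == label)
  if (length(sel) == 0L) stop("no subjects with label ", label)
  p <- project_2d(latents[, , , sel, drop = FALSE])
  apply(p, c(1, 2), mean)
}

#' Nearest-mean latent score
#'
#' Frobenius distance of a subject's 2D latent to the control and case group
#' means; the predicted label is the nearer mean (ties go to control).
#'
#' @param latent2d `H x W` matrix (see [project_2d()]).
#' @param control_mean,case_mean group means from [group_mean_latent()].
#' @return list with `distance_control`, `distance_case`, `label`.
#' @export
nearest_mean_score <- function(latent2d, control_mean, case_mean) {
  dc <- sqrt(sum((latent2d - control_mean)^2))
  df <- sqrt(sum((latent2d - case_mean)^2))
  list(distance_control = dc, distance_case = df,
       label = if (dc <= df) "control" else "case")
}
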