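# Parameter initialisation and the Adam optimizer.

he_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / fan_in)), c(kh, kw, cin, cout))
}

# transposed-conv weights, layout (kh, kw, cout, cin)
he_tconv <- function(kh, kw, cout, cin) {
  fan_in <- kh * kw * cin
  array(rnorm(kh * kw * cout * cin, 0, sqrt(2 / fan_in)), c(kh, kw, cout, cin))
}

he_conv3 <- function(k, cin, cout) {
  fan_in <- k^3 * cin
  array(rnorm(k^3 * cin * cout, 0, sqrt(2 / fan_in)), c(k, k, k, cin, cout))
}

he_dense <- function(fin, fout) {
  matrix(rnorm(fin * fout, 0, sqrt(2 / fin)), fin, fout)
}

zeros_like_params <- function(params) lapply(params, function(p) p * 0)

adam_new <- function(params) {
  list(m = zeros_like_params(params), v = zeros_like_params(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Hyperparameters shared by every trainable model in the package. Defaults
#' follow the reference training protocol: Adam with learning rate 0.001,
#' beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7, and minibatches of 32; one
#' fifth of the data is held out for testing wherever a split is performed.
#'
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param lr,beta1,beta2,eps Adam parameters.
#' @param loss segmentation loss: `"bce"`, `"dice"` or `"bce+dice"`.
#' @param seed integer seed controlling initialisation, shuffling and dropout.
#' @param split_fraction held-out fraction used by train/test splits.
#' @return a list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
                         loss = "bce", seed = 1L, split_fraction = 0.2) {
  stopifnot(split_fraction > 0, split_fraction < 1, epochs >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, loss = loss,
                 seed = as.integer(seed), split_fraction = split_fraction),
            class = "train_config")
}

# Generic minibatch loop. `step_fn(params, idx)` must return
# list(loss = scalar, grads = named list); data indices are reshuffled each
# epoch with the configured seed.
nn_fit <- function(params, n_obs, cfg, step_fn, verbose = FALSE) {
  state <- adam_new(params)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_obs)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bi in seq_along(batches)) {
      r <- step_fn(params, batches[[bi]])
      if (!is.finite(r$loss))
        stop("training aborted: non-finite loss at epoch ", ep, ", batch ", bi)
      upd <- adam_step(params, r$grads, state, cfg$lr, cfg$beta1, cfg$beta2, cfg$eps)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + r$loss * length(batches[[bi]])
    }
    history[ep] <- ep_loss / n_obs
    if (verbose) message(sprintf("epoch %d/%d  loss %.5f", ep, cfg$epochs, history[ep]))
  }
  list(params = params, history = history)
}

# Deterministic stratified train/test split; returns test indices.
stratified_test_idx <- function(labels, fraction) {
  idx <- integer(0)
  for (lv in unique(labels)) {
    pool <- which(labels == lv)
    k <- max(1L, round(length(pool) * fraction))
    idx <- c(idx, sample(pool, k))
  }
  sort(idx)
}
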