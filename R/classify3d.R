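# Case/control classification of latent volumes: a 3D CNN and a
# GAN-discriminator classifier, plus the classification metric report.

#' Build the 3D CNN classifier
#'
#' Three 3D convolutions (32/64/128 filters by default, 3x3x3 kernels, ReLU),
#' each followed by 2x2x2 max pooling; flatten; dense layer (512 neurons);
#' dropout 0.5; a single sigmoid output neuron. `first_stride = 2` makes the
#' first convolution strided, an optional cost-reducing variant used by the
#' scaled-down training protocols.
#'
#' @param filters conv filter counts (length 3).
#' @param dense width of the fully connected layer.
#' @param input_dim latent dimensions: either one side length (cubic) or a
#'   length-3 vector.
#' @param dropout dropout rate applied after the dense layer.
#' @param first_stride stride of the first convolution (1 or 2).
#' @param seed optional initialisation seed.
#' @return object of class `cnn3d`.
#' @export
build_cnn3d <- function(filters = c(32L, 64L, 128L), dense = 512L,
                        input_dim = 64L, dropout = 0.5, first_stride = 1L,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- as.integer(filters)
  dims <- rep(as.integer(input_dim), length.out = 3L)
  sides <- dims %/% first_stride %/% 8L        # three 2x pools
  if (any(sides < 1L)) stop("input_dim too small for three pooling stages")
  flat <- prod(sides) * f[3]
  p <- list(c1_w = he_conv3(3, 1, f[1]), c1_b = numeric(f[1]),
            c2_w = he_conv3(3, f[1], f[2]), c2_b = numeric(f[2]),
            c3_w = he_conv3(3, f[2], f[3]), c3_b = numeric(f[3]),
            fc_w = he_dense(flat, dense), fc_b = numeric(dense),
            out_w = he_dense(dense, 1L), out_b = numeric(1))
  structure(list(spec = list(filters = f, dense = as.integer(dense),
                             input_dim = dims, dropout = dropout,
                             first_stride = as.integer(first_stride)),
                 params = p, trained = FALSE),
            class = "cnn3d")
}

cnn3d_forward <- function(tp, ids, x_id, spec, train) {
  h <- op_relu(tp, op_conv3d(tp, x_id, ids$c1_w, ids$c1_b, spec$first_stride, 1L, need_dx = FALSE))
  h <- op_maxpool3(tp, h)
  h <- op_maxpool3(tp, op_relu(tp, op_conv3d(tp, h, ids$c2_w, ids$c2_b, 1L, 1L)))
  h <- op_maxpool3(tp, op_relu(tp, op_conv3d(tp, h, ids$c3_w, ids$c3_b, 1L, 1L)))
  h <- op_relu(tp, op_dense(tp, op_flatten(tp, h), ids$fc_w, ids$fc_b))
  h <- op_dropout(tp, h, spec$dropout, train)
  op_dense(tp, h, ids$out_w, ids$out_b)
}

latents_to_5d <- function(latents) {
  d <- dim(latents)
  if (length(d) == 4L) array(latents, c(d[1], d[2], d[3], 1L, d[4]))
  else if (length(d) == 5L) latents
  else stop("latents must be (D, D, D, N) or (D, D, D, 1, N)")
}

cnn3d_scores <- function(model, x5, batch = 16L) {
  n <- dim(x5)[5]
  scores <- numeric(n)
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    tp <- tg_new()
    ids <- lapply(model$params, function(p) tg_leaf(tp, p))
    z <- cnn3d_forward(tp, ids, tg_leaf(tp, x5[, , , , s, drop = FALSE]),
                       model$spec, train = FALSE)
    scores[s] <- plogis(as.numeric(tg_value(tp, z)))
  }
  scores
}

#' Train the 3D CNN classifier
#'
#' Performs a stratified train/test split (fraction `cfg$split_fraction`
#' held out), trains with Adam on binary cross-entropy, and reports
#' train/test loss, accuracy and the full metric panel on the held-out set.
#'
#' @param model a [build_cnn3d()].
#' @param latents `(D, D, D, N)` array of latent volumes.
#' @param labels length-N vector, `"case"`/`"control"` (or 0/1).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return list with `model`, `report` (a [classification_metrics()] result
#'   augmented with train/test loss and accuracy) and `split` (held-out
#'   indices).
#' @export
train_cnn3d <- function(model, latents, labels, cfg = train_config(epochs = 10L),
                        verbose = FALSE) {
  x5 <- latents_to_5d(latents)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  set.seed(cfg$seed)
  test_idx <- stratified_test_idx(y, cfg$split_fraction)
  tr_idx <- setdiff(seq_along(y), test_idx)
  xtr <- x5[, , , , tr_idx, drop = FALSE]; ytr <- y[tr_idx]
  fit <- nn_fit(model$params, length(tr_idx), cfg, function(params, idx) {
    tp <- tg_new()
    ids <- lapply(params, function(p) tg_leaf(tp, p))
    z <- cnn3d_forward(tp, ids, tg_leaf(tp, xtr[, , , , idx, drop = FALSE]),
                       model$spec, train = TRUE)
    loss_id <- op_bce_logits(tp, z, matrix(ytr[idx], ncol = 1))
    grads_all <- tg_backward(tp, loss_id)
    list(loss = tg_value(tp, loss_id),
         grads = lapply(ids, function(i) grads_all[[i]]))
  }, verbose)
  model$params <- fit$params
  model$history <- fit$history
  model$trained <- TRUE
  report <- held_out_report(function(x) cnn3d_scores(model, x), x5, y,
                            tr_idx, test_idx)
  list(model = model, report = report, split = test_idx)
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(labels == "case")
}

bce_of_scores <- function(y, p) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

held_out_report <- function(score_fn, x5, y, tr_idx, test_idx) {
  str_ <- score_fn(x5[, , , , tr_idx, drop = FALSE])
  ste <- score_fn(x5[, , , , test_idx, drop = FALSE])
  rep <- classification_metrics(y[test_idx], ste)
  rep$train_loss <- bce_of_scores(y[tr_idx], str_)
  rep$test_loss <- bce_of_scores(y[test_idx], ste)
  rep$train_accuracy <- mean((str_ >= 0.5) == (y[tr_idx] == 1))
  rep$test_accuracy <- rep$accuracy
  rep
}

#' Build the GAN classifier
#'
#' A 3D generative adversarial pair operating on latent volumes. The
#' generator maps a noise vector through a dense projection and three
#' convolutional stages (256/128/64 filters by default, nearest upsampling
#' between stages) to a synthetic latent volume; the discriminator applies
#' four strided 3D convolutions (32/64/128/256) and ends in two sigmoid
#' heads: one adversarial (real vs generated) and one supervised (case vs
#' control). After adversarial pretraining the supervised head is trained as
#' the classifier, so the discriminator's features are shaped by both tasks.
#'
#' @param gen_filters generator conv filters (coarse to fine, length 3).
#' @param disc_filters discriminator conv filters (length 4).
#' @param input_dim latent dimensions (side length or length-3 vector).
#' @param noise_dim generator input dimension.
#' @param seed optional initialisation seed.
#' @return object of class `gan_classifier` with `gen` and `disc` parameter
#'   lists.
#' @export
build_gan_classifier <- function(gen_filters = c(256L, 128L, 64L),
                                 disc_filters = c(32L, 64L, 128L, 256L),
                                 input_dim = 64L, noise_dim = 32L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gf <- as.integer(gen_filters); df <- as.integer(disc_filters)
  dims <- rep(as.integer(input_dim), length.out = 3L)
  base <- dims %/% 8L                           # three upsampling stages
  if (any(base < 1L)) stop("input_dim too small")
  gen <- list(fc_w = he_dense(noise_dim, prod(base) * gf[1]),
              fc_b = numeric(prod(base) * gf[1]),
              g1_w = he_conv3(3, gf[1], gf[2]), g1_b = numeric(gf[2]),
              g2_w = he_conv3(3, gf[2], gf[3]), g2_b = numeric(gf[3]),
              g3_w = he_conv3(3, gf[3], 1L), g3_b = numeric(1))
  dside <- dims %/% 16L                         # four stride-2 convolutions
  if (any(dside < 1L)) stop("input_dim too small for the discriminator")
  disc <- list(d1_w = he_conv3(3, 1, df[1]), d1_b = numeric(df[1]),
               d2_w = he_conv3(3, df[1], df[2]), d2_b = numeric(df[2]),
               d3_w = he_conv3(3, df[2], df[3]), d3_b = numeric(df[3]),
               d4_w = he_conv3(3, df[3], df[4]), d4_b = numeric(df[4]),
               adv_w = he_dense(prod(dside) * df[4], 1L), adv_b = numeric(1),
               cls_w = he_dense(prod(dside) * df[4], 1L), cls_b = numeric(1))
  structure(list(spec = list(gen_filters = gf, disc_filters = df,
                             input_dim = dims,
                             noise_dim = as.integer(noise_dim), base = base),
                 gen = gen, disc = disc, trained = FALSE),
            class = "gan_classifier")
}

gan_gen_forward <- function(tp, ids, z_id, spec) {
  h <- op_relu(tp, op_dense(tp, z_id, ids$fc_w, ids$fc_b))
  h <- op_unflatten(tp, h, c(spec$base, spec$gen_filters[1]))
  h <- op_upnearest3(tp, h)
  h <- op_relu(tp, op_conv3d(tp, h, ids$g1_w, ids$g1_b, 1L, 1L))
  h <- op_upnearest3(tp, h)
  h <- op_relu(tp, op_conv3d(tp, h, ids$g2_w, ids$g2_b, 1L, 1L))
  h <- op_upnearest3(tp, h)
  op_sigmoid(tp, op_conv3d(tp, h, ids$g3_w, ids$g3_b, 1L, 1L))
}

gan_disc_features <- function(tp, ids, x_id, input_grad = FALSE) {
  h <- op_relu(tp, op_conv3d(tp, x_id, ids$d1_w, ids$d1_b, 2L, 1L, need_dx = input_grad))
  h <- op_relu(tp, op_conv3d(tp, h, ids$d2_w, ids$d2_b, 2L, 1L))
  h <- op_relu(tp, op_conv3d(tp, h, ids$d3_w, ids$d3_b, 2L, 1L))
  h <- op_relu(tp, op_conv3d(tp, h, ids$d4_w, ids$d4_b, 2L, 1L))
  op_flatten(tp, h)
}

gan_disc_scores <- function(model, x5, head = c("cls", "adv"), batch = 16L) {
  head <- match.arg(head)
  n <- dim(x5)[5]
  scores <- numeric(n)
  wn <- paste0(head, "_w"); bn <- paste0(head, "_b")
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    tp <- tg_new()
    ids <- lapply(model$disc, function(p) tg_leaf(tp, p))
    f <- gan_disc_features(tp, ids, tg_leaf(tp, x5[, , , , s, drop = FALSE]))
    z <- op_dense(tp, f, ids[[wn]], ids[[bn]])
    scores[s] <- plogis(as.numeric(tg_value(tp, z)))
  }
  scores
}

#' Train the GAN classifier
#'
#' Alternates discriminator and generator adversarial updates on the training
#' latents (`adv_epochs` passes), then trains the discriminator's supervised
#' sigmoid head (together with its convolutional trunk) for case/control for
#' `cfg$epochs` passes. Reports held-out metrics like [train_cnn3d()]. If the
#' generator loss becomes non-finite the adversarial phase stops with a
#' warning and classification proceeds.
#'
#' @param model a [build_gan_classifier()].
#' @param latents `(D, D, D, N)` array.
#' @param labels length-N vector.
#' @param cfg a [train_config()].
#' @param adv_epochs adversarial pretraining epochs.
#' @param verbose print progress.
#' @return list with `model`, `report`, `split`.
#' @export
train_gan_classifier <- function(model, latents, labels,
                                 cfg = train_config(epochs = 10L),
                                 adv_epochs = 2L, verbose = FALSE) {
  x5 <- latents_to_5d(latents)
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  set.seed(cfg$seed)
  test_idx <- stratified_test_idx(y, cfg$split_fraction)
  tr_idx <- setdiff(seq_along(y), test_idx)
  xtr <- x5[, , , , tr_idx, drop = FALSE]; ytr <- y[tr_idx]
  spec <- model$spec

  # ---- adversarial phase ----
  gstate <- adam_new(model$gen)
  dstate <- adam_new(model$disc)
  ntr <- length(tr_idx)
  for (ep in seq_len(adv_epochs)) {
    ord <- sample.int(ntr)
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      nb <- length(b)
      zn <- matrix(rnorm(nb * spec$noise_dim), nb, spec$noise_dim)
      # generator sample (values only)
      tp <- tg_new()
      gids <- lapply(model$gen, function(p) tg_leaf(tp, p))
      fake <- tg_value(tp, gan_gen_forward(tp, gids, tg_leaf(tp, zn), spec))
      # discriminator update on real + fake
      tp <- tg_new()
      dids <- lapply(model$disc, function(p) tg_leaf(tp, p))
      xb <- xtr[, , , , b, drop = FALSE]
      both <- array(c(xb, fake), c(dim(xb)[1:4], 2L * nb))
      f <- gan_disc_features(tp, dids, tg_leaf(tp, both))
      adv <- op_dense(tp, f, dids$adv_w, dids$adv_b)
      dloss <- op_bce_logits(tp, adv, matrix(rep(c(1, 0), c(nb, nb)), ncol = 1))
      ga <- tg_backward(tp, dloss)
      upd <- adam_step(model$disc, lapply(dids, function(i) ga[[i]]), dstate,
                       cfg$lr, cfg$beta1, cfg$beta2, cfg$eps)
      model$disc <- upd$params; dstate <- upd$state
      # generator update (non-saturating: D(fake) -> 1)
      tp <- tg_new()
      gids <- lapply(model$gen, function(p) tg_leaf(tp, p))
      dids <- lapply(model$disc, function(p) tg_leaf(tp, p))
      fake_id <- gan_gen_forward(tp, gids, tg_leaf(tp, zn), spec)
      f <- gan_disc_features(tp, dids, fake_id, input_grad = TRUE)
      adv <- op_dense(tp, f, dids$adv_w, dids$adv_b)
      gloss <- op_bce_logits(tp, adv, matrix(1, nb, 1))
      if (!is.finite(tg_value(tp, gloss))) {
        warning("generator loss non-finite; stopping adversarial phase early")
        break
      }
      ga <- tg_backward(tp, gloss)
      upd <- adam_step(model$gen, lapply(gids, function(i) ga[[i]]), gstate,
                       cfg$lr, cfg$beta1, cfg$beta2, cfg$eps)
      model$gen <- upd$params; gstate <- upd$state
    }
    if (verbose) message("adversarial epoch ", ep, "/", adv_epochs)
  }

  # ---- supervised phase: classification head on the discriminator ----
  fit <- nn_fit(model$disc, ntr, cfg, function(params, idx) {
    tp <- tg_new()
    dids <- lapply(params, function(p) tg_leaf(tp, p))
    f <- gan_disc_features(tp, dids, tg_leaf(tp, xtr[, , , , idx, drop = FALSE]))
    z <- op_dense(tp, f, dids$cls_w, dids$cls_b)
    loss_id <- op_bce_logits(tp, z, matrix(ytr[idx], ncol = 1))
    grads_all <- tg_backward(tp, loss_id)
    list(loss = tg_value(tp, loss_id),
         grads = lapply(dids, function(i) grads_all[[i]]))
  }, verbose)
  model$disc <- fit$params
  model$history <- fit$history
  model$trained <- TRUE
  report <- held_out_report(function(x) gan_disc_scores(model, x, "cls"),
                            x5, y, tr_idx, test_idx)
  list(model = model, report = report, split = test_idx)
}

#' Classification metric report
#'
#' Confusion-matrix rates at a fixed threshold plus the ROC curve (threshold
#' sweep over the observed scores) and its trapezoidal AUC.
#'
#' @param y_true 0/1 vector (1 = case).
#' @param y_score predicted probabilities.
#' @param threshold decision threshold.
#' @return list of class `classification_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`, `auc`, `roc` (data frame fpr/tpr),
#'   `confusion` (tp/fp/tn/fn), `precision_defined`.
#' @export
classification_metrics <- function(y_true, y_score, threshold = 0.5) {
  y <- as_binary_labels(y_true)
  stopifnot(length(y) == length(y_score))
  pred <- as.integer(y_score >= threshold)
  tp <- sum(y == 1 & pred == 1); fn <- sum(y == 1 & pred == 0)
  fp <- sum(y == 0 & pred == 1); tn <- sum(y == 0 & pred == 0)
  prec_def <- (tp + fp) > 0
  prec <- if (prec_def) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  # ROC: sweep thresholds over the observed scores
  ths <- c(Inf, sort(unique(y_score), decreasing = TRUE))
  tpr <- vapply(ths, function(t) sum(y == 1 & y_score >= t) / max(sum(y == 1), 1), 0)
  fpr <- vapply(ths, function(t) sum(y == 0 & y_score >= t) / max(sum(y == 0), 1), 0)
  auc <- if (length(unique(y)) == 2L)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2) else NA_real_
  structure(list(accuracy = (tp + tn) / length(y), sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1, auc = auc,
                 roc = data.frame(fpr = fpr, tpr = tpr),
                 confusion = list(tp = tp, fp = fp, tn = tn, fn = fn),
                 precision_defined = prec_def, threshold = threshold),
            class = "classification_report")
}
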