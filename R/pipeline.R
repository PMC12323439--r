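# End-to-end pipeline: synthetic cohort -> landmark-derived masks -> texture
# tensors -> segmentation training -> prediction -> evaluation -> latent
# encoding -> classification. One configuration list drives everything.

#' Pipeline configuration
#'
#' Returns the default configuration, optionally overridden by a YAML file
#' and/or a named list. All texture and training defaults follow the
#' reference protocol (P = 8, R = 1, Adam lr 0.001, batch 32); the cohort and
#' network sizes default to a small demonstration scale so the full pipeline
#' runs on a laptop CPU.
#'
#' @param path optional YAML file with overrides.
#' @param overrides optional named list of overrides (applied last).
#' @return nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    out_dir = "lipseg_run",
    seed = 1L,
    synth = list(size = 64L, n_case = 12L, n_control = 52L, cohort = "A",
                 n_landmarks = 13L),
    texture = list(P = 8L, R = 1, interp = "nearest", grad = "sobel"),
    maskgen = list(template = "default", pts_per_segment = 10L,
                   mode = "chord_frame", trajectory = "polyline"),
    train = list(model = "saunet_t", encoder_filters = c(8L, 16L, 32L, 64L),
                 epochs = 12L, batch_size = 32L, lr = 1e-3, loss = "bce",
                 split_fraction = 0.2),
    classify = list(enabled = TRUE, ae_filters = c(8L, 16L), ae_epochs = 8L,
                    cnn_filters = c(4L, 8L, 16L), cnn_dense = 64L,
                    cnn_epochs = 6L, gan_enabled = FALSE,
                    gan_gen_filters = c(16L, 8L, 4L),
                    gan_disc_filters = c(4L, 8L, 16L, 32L), gan_epochs = 6L,
                    adv_epochs = 2L)
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- modify_list_deep(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- modify_list_deep(cfg, overrides)
  if (identical(cfg$maskgen$template, "")) stop("maskgen$template must be set")
  structure(cfg, class = "pipeline_config")
}

modify_list_deep <- function(base, new) {
  for (k in names(new)) {
    base[[k]] <- if (is.list(new[[k]]) && is.list(base[[k]]))
      modify_list_deep(base[[k]], new[[k]]) else new[[k]]
  }
  base
}

#' Stable configuration hash
#'
#' FNV-1a hash of the canonical JSON serialisation; semantically equal
#' configurations hash equal regardless of list ordering.
#'
#' @param cfg a [pipeline_config()].
#' @return hex string.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      return(lapply(x, canon))
    }
    x
  }
  s <- jsonlite::toJSON(canon(unclass(cfg)), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    # FNV-1a; the xor only touches the low byte, which keeps bitwXor in range
    low <- h %% 256
    h <- ((h - low + bitwXor(low, b)) * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Run the full pipeline
#'
#' Executes, in order: synthetic cohort generation; mask generation from the
#' emitted landmarks via the lip template; input tensor construction;
#' segmentation training (with a held-out split); prediction and metric
#' evaluation on the held-out images; latent encoding of the predicted masks;
#' and case/control classification. Each stage writes its artifacts under
#' `cfg$out_dir` and logs its seed and the configuration hash; a stage
#' failure halts with the stage name.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose log stage progress.
#' @return invisible list with the evaluation data frame, summary table and
#'   (if enabled) the classification report.
#' @export
run_pipeline <- function(cfg = pipeline_config(), verbose = TRUE) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(...) if (verbose) message("[lipseg ", config_hash(cfg),
                                                 "] ", ...)
  stage <- function(name, expr) {
    log_line("stage ", name, " (seed ", cfg$seed, ")")
    tryCatch(expr, error = function(e)
      stop("pipeline halted in stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  samples <- stage("synth", {
    co <- generate_cohort(cfg$synth$n_case, cfg$synth$n_control,
                          cfg$synth$cohort, cfg$seed, cfg$synth$size,
                          cfg$synth$n_landmarks)
    write_cohort(co, file.path(cfg$out_dir, "data"))
    co
  })

  template <- if (identical(cfg$maskgen$template, "default")) lip_template()
              else read_template(cfg$maskgen$template)

  masks <- stage("make-mask", {
    lapply(samples, function(s)
      generate_mask_from_landmarks(s$landmarks,
                                   dim(s$mask), template,
                                   cfg$maskgen$pts_per_segment,
                                   cfg$maskgen$mode, cfg$maskgen$trajectory))
  })

  tensors <- stage("features", {
    n <- length(samples)
    sz <- cfg$synth$size
    x <- array(0, c(sz, sz, 5L, n))
    for (i in seq_len(n))
      x[, , , i] <- build_input_tensor(samples[[i]]$image, cfg$texture$P,
                                       cfg$texture$R, cfg$texture$interp,
                                       cfg$texture$grad)
    x
  })

  n <- length(samples)
  y <- array(0, c(cfg$synth$size, cfg$synth$size, 1L, n))
  for (i in seq_len(n)) y[, , 1, i] <- masks[[i]]

  tcfg <- train_config(epochs = cfg$train$epochs,
                       batch_size = cfg$train$batch_size, lr = cfg$train$lr,
                       loss = cfg$train$loss, seed = cfg$seed,
                       split_fraction = cfg$train$split_fraction)
  labels <- vapply(samples, function(s) s$label, "")
  set.seed(cfg$seed)
  test_idx <- stratified_test_idx(labels, cfg$train$split_fraction)
  tr_idx <- setdiff(seq_len(n), test_idx)

  model <- stage("train", {
    in_ch <- if (grepl("_t$", cfg$train$model)) 5L else 3L
    xin <- if (in_ch == 5L) tensors else tensors[, , 1:3, , drop = FALSE]
    m <- if (grepl("^saunet", cfg$train$model))
      build_saunet(in_ch, cfg$train$encoder_filters,
                   input_size = cfg$synth$size, seed = cfg$seed)
    else build_aunet(aunet_spec(in_ch, cfg$train$encoder_filters,
                                input_size = cfg$synth$size), seed = cfg$seed)
    m <- train_segmenter(m, xin[, , , tr_idx, drop = FALSE],
                         y[, , , tr_idx, drop = FALSE], tcfg)
    save_model(m, file.path(cfg$out_dir, "segmenter"))
    hist <- if (inherits(m, "saunet")) m$history$stage1 else m$history
    write.csv(data.frame(epoch = seq_along(hist), loss = hist),
              file.path(cfg$out_dir, "train_log.csv"), row.names = FALSE)
    m
  })

  pred <- stage("predict", {
    in_ch <- if (grepl("_t$", cfg$train$model)) 5L else 3L
    xte <- if (in_ch == 5L) tensors[, , , test_idx, drop = FALSE]
           else tensors[, , 1:3, test_idx, drop = FALSE]
    pm <- predict_mask(model, xte)
    lapply(seq_along(test_idx), function(i) pm$mask[, , i])
  })

  eval_out <- stage("eval", {
    truths <- lapply(test_idx, function(i) masks[[i]])
    per_image <- evaluate_masks(truths, pred)
    summary <- summarize_metrics(list(model = per_image))
    write.csv(per_image, file.path(cfg$out_dir, "eval_per_image.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(cfg$out_dir, "eval_summary.csv"),
              row.names = FALSE)
    list(per_image = per_image, summary = summary)
  })

  class_report <- NULL
  if (isTRUE(cfg$classify$enabled)) {
    class_report <- stage("encode+classify", {
      ae <- build_autoencoder(cfg$classify$ae_filters, cfg$synth$size,
                              seed = cfg$seed)
      ae <- fit_autoencoder(ae, masks,
                            train_config(epochs = cfg$classify$ae_epochs,
                                         seed = cfg$seed))
      latents <- encode_masks(ae, masks)
      cnn <- build_cnn3d(cfg$classify$cnn_filters, cfg$classify$cnn_dense,
                         input_dim = dim(latents)[1], seed = cfg$seed)
      res <- train_cnn3d(cnn, latents, labels,
                         train_config(epochs = cfg$classify$cnn_epochs,
                                      seed = cfg$seed))
      out <- list(cnn3d = res$report)
      if (isTRUE(cfg$classify$gan_enabled)) {
        gan <- build_gan_classifier(cfg$classify$gan_gen_filters,
                                    cfg$classify$gan_disc_filters,
                                    input_dim = dim(latents)[1],
                                    seed = cfg$seed)
        gres <- train_gan_classifier(gan, latents, labels,
                                     train_config(epochs = cfg$classify$gan_epochs,
                                                  seed = cfg$seed),
                                     adv_epochs = cfg$classify$adv_epochs)
        out$gan <- gres$report
      }
      jsonlite::write_json(
        lapply(out, function(r) r[c("accuracy", "sensitivity", "specificity",
                                    "precision", "f1", "auc")]),
        file.path(cfg$out_dir, "classification.json"),
        auto_unbox = TRUE, digits = NA)
      out
    })
  }
  log_line("done")
  invisible(list(eval = eval_out, classification = class_report,
                 model = model, test_idx = test_idx))
}
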