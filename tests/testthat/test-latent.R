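# Autoencoder latents, 2D projections, and classifiers.

test_that("the encoder compresses a 256x256 mask into a 64x64x64 latent", {
  ae <- build_autoencoder(seed = 81)        # reference filters 32/64
  m <- generate_sample(lip_shape_params(), seed = 82)$mask
  z <- encode_masks(ae, list(m))
  expect_equal(dim(z), c(64L, 64L, 64L, 1L))
  rec <- reconstruct_masks(ae, list(m))
  expect_equal(dim(rec), c(256L, 256L, 1L, 1L))
  expect_true(all(rec > 0 & rec < 1))
})

test_that("reconstruction loss decreases and overfits small sets", {
  set.seed(83)
  co <- generate_cohort(0, 3, "A", seed = 84, size = 64)
  masks <- lapply(co, `[[`, "mask")
  ae <- build_autoencoder(c(8L, 16L), input_size = 64L, seed = 85)
  ae <- fit_autoencoder(ae, masks, train_config(epochs = 250L, seed = 86L, lr = 5e-3))
  expect_lt(tail(ae$history, 1), ae$history[1])
  rec <- reconstruct_masks(ae, masks)
  d <- vapply(1:3, function(i) dice(masks[[i]], (rec[, , 1, i] >= 0.5) * 1), 0)
  expect_gte(mean(d), 0.95)
  expect_error(fit_autoencoder(build_autoencoder(c(4L, 8L), 64L), list()),
               "empty")
})

test_that("2D projection and group means follow their definitions", {
  z <- array(3, c(4, 4, 5))
  expect_equal(project_2d(z), matrix(3, 4, 4))
  set.seed(87)
  zs <- array(rnorm(4 * 4 * 5 * 6), c(4, 4, 5, 6))
  labs <- rep(c("case", "control"), each = 3)
  gm <- group_mean_latent(zs, labs, "case")
  manual <- apply(zs[, , , 1:3], c(1, 2), mean)
  expect_equal(gm, manual, tolerance = 1e-12)
  one <- group_mean_latent(zs[, , , 1, drop = FALSE], "case", "case")
  expect_equal(one, project_2d(zs[, , , 1]))
  expect_error(group_mean_latent(zs, labs, "other"), "no subjects")
})

test_that("nearest-mean scoring labels by distance with control ties", {
  cm <- matrix(0, 4, 4); fm <- matrix(1, 4, 4)
  r <- nearest_mean_score(cm, cm, fm)
  expect_equal(r$label, "control"); expect_equal(r$distance_control, 0)
  equi <- matrix(0.5, 4, 4)
  expect_equal(nearest_mean_score(equi, cm, fm)$label, "control")
  expect_equal(nearest_mean_score(matrix(0.9, 4, 4), cm, fm)$label, "case")
})

test_that("latent geometry separates thin from normal lips", {
  # thin-lip cases leave a smaller activation footprint than controls
  co <- generate_cohort(10, 10, "A", seed = 88, size = 64)
  masks <- lapply(co, `[[`, "mask")
  labs <- vapply(co, `[[`, "", "label")
  ae <- build_autoencoder(c(8L, 16L), input_size = 64L, seed = 89)
  ae <- fit_autoencoder(ae, masks, train_config(epochs = 30L, seed = 90L))
  z <- encode_masks(ae, masks)
  cm <- group_mean_latent(z, labs, "control")
  fm <- group_mean_latent(z, labs, "case")
  lip_region <- which(Reduce(`+`, masks) > 0, arr.ind = TRUE)
  # compare on the downsampled lip support
  lr <- unique(cbind(ceiling(lip_region[, 1] / 4), ceiling(lip_region[, 2] / 4)))
  expect_gt(sum(cm[lr]) - sum(fm[lr]), 0)
  # held-out nearest-mean labelling beats chance
  co2 <- generate_cohort(8, 8, "A", seed = 91, size = 64)
  z2 <- encode_masks(ae, lapply(co2, `[[`, "mask"))
  pred <- vapply(seq_len(dim(z2)[4]), function(i)
    nearest_mean_score(project_2d(z2[, , , i]), cm, fm)$label, "")
  truth <- vapply(co2, `[[`, "", "label")
  expect_gt(mean(pred == truth), 0.5)
})

test_that("classification metrics match the enumerated example", {
  r <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(r$accuracy, 0.5)
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$specificity, 0.5)
  expect_equal(r$precision, 0.5)
  expect_equal(r$f1, 0.5)
  expect_equal(r$auc, 0.75)           # 3 of 4 positive/negative pairs ordered
  perfect <- classification_metrics(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "precision", "f1", "auc")]) == 1))
  const <- classification_metrics(c(1, 0, 1, 0), rep(0.5, 4))
  expect_equal(const$auc, 0.5)
  nopos <- classification_metrics(c(1, 0), c(0.1, 0.2))
  expect_false(nopos$precision_defined)
  expect_equal(nopos$precision, 0)
})

test_that("ROC curves are monotone and AUC matches an independent oracle", {
  set.seed(92)
  y <- rep(c(0, 1), 25)
  sc <- runif(50) + 0.4 * y
  r <- classification_metrics(y, sc)
  expect_true(all(diff(r$roc$fpr) >= 0))
  expect_true(all(diff(r$roc$tpr) >= 0))
  # Mann-Whitney pair-counting oracle
  pos <- sc[y == 1]; neg <- sc[y == 0]
  auc_mw <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(r$auc, auc_mw, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(r$auc, as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE))),
               tolerance = 1e-12)
  # f1 recomputable from the stored confusion matrix
  cm <- r$confusion
  prec <- cm$tp / (cm$tp + cm$fp); sens <- cm$tp / (cm$tp + cm$fn)
  expect_equal(r$f1, 2 * prec * sens / (prec + sens))
})

test_that("3D CNN classifier learns thin-vs-normal latents and is honest about nulls", {
  set.seed(93)
  co <- generate_cohort(14, 26, "A", seed = 94, size = 64)
  masks <- lapply(co, `[[`, "mask")
  labs <- vapply(co, `[[`, "", "label")
  ae <- build_autoencoder(c(8L, 16L), input_size = 64L, seed = 95)
  ae <- fit_autoencoder(ae, masks, train_config(epochs = 20L, seed = 96L))
  z <- encode_masks(ae, masks)                      # 16 x 16 x 16 latents
  cnn <- build_cnn3d(c(4L, 8L, 16L), dense = 32L, input_dim = 16L, seed = 97)
  res <- train_cnn3d(cnn, z, labs, train_config(epochs = 10L, seed = 98L))
  expect_gt(res$report$accuracy, mean(labs[res$split] == "control") - 1e-9)
  expect_true(res$model$trained)
  expect_equal(res$report$test_accuracy, res$report$accuracy)
  # deterministic: same seed twice gives the same report
  res2 <- train_cnn3d(cnn, z, labs, train_config(epochs = 10L, seed = 98L))
  expect_identical(res$report$accuracy, res2$report$accuracy)
  # shuffled labels stay near chance on the training set fit
  set.seed(99)
  shuffled <- sample(labs)
  res3 <- train_cnn3d(cnn, z, shuffled, train_config(epochs = 4L, seed = 100L))
  expect_lt(res3$report$accuracy, 1)
  expect_error(train_cnn3d(cnn, z, rep("case", length(labs)),
                           train_config(epochs = 1L)), "both classes")
})

test_that("GAN discriminator is unsaturated at init and trains a class head", {
  set.seed(101)
  co <- generate_cohort(12, 24, "A", seed = 102, size = 64)
  masks <- lapply(co, `[[`, "mask")
  labs <- vapply(co, `[[`, "", "label")
  ae <- build_autoencoder(c(8L, 16L), input_size = 64L, seed = 103)
  ae <- fit_autoencoder(ae, masks, train_config(epochs = 15L, seed = 104L))
  z <- encode_masks(ae, masks)
  gan <- build_gan_classifier(c(16L, 8L, 4L), c(4L, 8L, 16L, 32L),
                              input_dim = 16L, noise_dim = 8L, seed = 105)
  # discriminator scores on generator output at initialisation: not saturated
  ns <- asNamespace("lipseg")
  tp <- ns$tg_new()
  gids <- lapply(gan$gen, function(p) ns$tg_leaf(tp, p))
  zn <- matrix(rnorm(4 * 8), 4, 8)
  fake <- ns$tg_value(tp, ns$gan_gen_forward(tp, gids, ns$tg_leaf(tp, zn), gan$spec))
  sc <- ns$gan_disc_scores(gan, fake, "adv")
  expect_true(all(sc > 0.01 & sc < 0.99))
  res <- train_gan_classifier(gan, z, labs,
                              train_config(epochs = 8L, seed = 106L),
                              adv_epochs = 1L)
  expect_gt(res$report$accuracy, mean(labs[res$split] == "control") - 1e-9)
  expect_true(is.finite(res$report$auc))
})
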