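# Shared fixtures. Heavy artifacts (trained models, cohorts) are built once
# per test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small deterministic cohort at full face scale
fixture_cohort_256 <- function() memo("cohort256", generate_cohort(4, 12, "A", seed = 5, size = 256))

# tensors + landmark-derived masks for a cohort
cohort_arrays <- function(samples, template = lip_template()) {
  n <- length(samples)
  size <- nrow(samples[[1]]$mask)
  x <- array(0, c(size, size, 5L, n))
  y <- array(0, c(size, size, 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- build_input_tensor(samples[[i]]$image)
    y[, , 1, i] <- generate_mask_from_landmarks(samples[[i]]$landmarks,
                                                c(size, size), template)
  }
  list(x = x, y = y, labels = vapply(samples, `[[`, "", "label"))
}

# scaled-down segmentation study: 200 synthetic faces at 64 px, tiny-filter
# networks (8/16/32/64), 30 epochs, fixed seeds throughout
fixture_seg_suite <- function() memo("seg_suite", {
  size <- 64L
  co <- generate_cohort(36L, 164L, "A", seed = 101L, size = size)
  arr <- cohort_arrays(co)
  set.seed(202L)
  te <- lipseg:::stratified_test_idx(arr$labels, 0.2)
  tr <- setdiff(seq_along(co), te)
  cfg <- train_config(epochs = 30L, loss = "bce+dice", seed = 303L)
  sa <- build_saunet(5L, c(8L, 16L, 32L, 64L), input_size = size, seed = 303L)
  sa <- train_segmenter(sa, arr$x[, , , tr, drop = FALSE],
                        arr$y[, , , tr, drop = FALSE], cfg)
  au <- build_aunet(aunet_spec(3L, c(8L, 16L, 32L, 64L), input_size = size),
                    seed = 303L)
  au <- train_segmenter(au, arr$x[, , 1:3, tr, drop = FALSE],
                        arr$y[, , , tr, drop = FALSE], cfg)
  pm_sa <- predict_mask(sa, arr$x[, , , te, drop = FALSE])
  pm_s1 <- predict_mask(sa$stage1, arr$x[, , , te, drop = FALSE])
  pm_au <- predict_mask(au, arr$x[, , 1:3, te, drop = FALSE])
  truth <- lapply(te, function(i) arr$y[, , 1, i])
  dice_of <- function(pm) vapply(seq_along(te),
                                 function(i) dice(truth[[i]], pm$mask[, , i]), 0)
  list(saunet = sa, aunet_rgb = au, test_idx = te,
       dice_saunet = dice_of(pm_sa), dice_stage1 = dice_of(pm_s1),
       dice_aunet_rgb = dice_of(pm_au),
       truth = truth, mask_saunet = pm_sa$mask, mask_stage1 = pm_s1$mask)
})

# random binary mask helper
random_mask <- function(h, w, p = 0.3) matrix(runif(h * w) < p, h, w) * 1

# strip texture-map attributes down to a bare matrix for exact comparisons
bare <- function(m) { a <- unclass(m); attributes(a) <- list(dim = dim(a)); a }
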