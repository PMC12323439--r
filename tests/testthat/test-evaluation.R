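# Segmentation metric suite.

test_that("dice handles identity, disjoint and partial overlap", {
  a <- matrix(0, 8, 8); a[1:2, 1:2] <- 1
  expect_equal(dice(a, a), 1)
  b <- matrix(0, 8, 8); b[5:6, 5:6] <- 1
  expect_equal(dice(a, b), 0)
  shifted <- matrix(0, 8, 8); shifted[1:2, 2:3] <- 1   # one column over
  expect_equal(dice(a, shifted), 0.5)                  # |I|=2, 4/8
  expect_equal(iou(a, shifted), 2 / 6)
  expect_equal(voe(a, shifted), 1 - 2 / 6)
  expect_equal(dice(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(dice(a, matrix(0, 4, 4)), "dimensions")
})

test_that("iou/voe identities hold on random mask pairs", {
  set.seed(21)
  for (k in 1:1000) {
    a <- random_mask(12, 12); b <- random_mask(12, 12)
    d <- dice(a, b); i <- iou(a, b)
    expect_lt(abs(i - d / (2 - d)), 1e-12)
    expect_lt(abs(voe(a, b) - (1 - i)), 1e-12)
  }
})

test_that("hausdorff distance matches hand-computed cases and is symmetric", {
  a <- matrix(0, 10, 10); a[1, 1] <- 1
  b <- matrix(0, 10, 10); b[4, 5] <- 1            # offset (3, 4) -> 5
  expect_equal(hausdorff(a, b), 5)
  c1 <- matrix(0, 12, 12); c1[1, 1] <- 1; c1[1, 11] <- 1
  c2 <- matrix(0, 12, 12); c2[1, 1] <- 1
  expect_equal(hausdorff(c1, c2), 10)             # asymmetry resolved by max
  expect_equal(hausdorff(c2, c1), 10)
  expect_equal(hausdorff(a, a), 0)
  expect_error(hausdorff(a, matrix(0, 10, 10)), "empty")
  set.seed(22)
  for (k in 1:20) {
    x <- random_mask(15, 15, 0.2); y <- random_mask(15, 15, 0.2)
    if (sum(x) == 0 || sum(y) == 0) next
    expect_equal(hausdorff(x, y), hausdorff(y, x))
  }
})

test_that("hausdorff agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  set.seed(23)
  for (k in 1:10) {
    x <- random_mask(20, 20, 0.1); y <- random_mask(20, 20, 0.1)
    if (sum(x) == 0 || sum(y) == 0) next
    ref <- pracma::hausdorff_dist(which(x == 1, arr.ind = TRUE),
                                  which(y == 1, arr.ind = TRUE))
    expect_equal(hausdorff(x, y), ref)
  }
})

test_that("pixel accuracy follows the confusion-count formulas", {
  cc <- list(tp = 10, tn = 80, fp = 5, fn = 5, tpc = 10, fnc = 5)
  pa <- pixel_accuracy(cc)
  expect_equal(pa$pa, 0.90)
  expect_equal(pa$pa_class, 10 / 15)
  truth <- matrix(0, 6, 6); truth[2:3, 2:4] <- 1
  expect_equal(pixel_accuracy(confusion_counts(truth, truth)),
               list(pa = 1, pa_class = 1))
  none <- matrix(0, 6, 6)
  expect_equal(pixel_accuracy(confusion_counts(truth, none))$pa_class, 0)
  counts <- confusion_counts(truth, none)
  expect_equal(counts$tp + counts$tn + counts$fp + counts$fn, 36)
})

test_that("metric suite agrees with per-pixel loop oracles on random masks", {
  set.seed(24)
  x <- random_mask(32, 32, 0.2); y <- random_mask(32, 32, 0.25)
  inter <- 0; ux <- 0; uy <- 0; uni <- 0
  for (r in 1:32) for (cc in 1:32) {
    inter <- inter + (x[r, cc] == 1 && y[r, cc] == 1)
    ux <- ux + x[r, cc]; uy <- uy + y[r, cc]
    uni <- uni + (x[r, cc] == 1 || y[r, cc] == 1)
  }
  expect_equal(dice(x, y), 2 * inter / (ux + uy))
  expect_equal(iou(x, y), inter / uni)
  px <- which(x == 1, arr.ind = TRUE); py <- which(y == 1, arr.ind = TRUE)
  worst <- 0
  for (i in seq_len(nrow(px))) {
    best <- Inf
    for (j in seq_len(nrow(py)))
      best <- min(best, sqrt(sum((px[i, ] - py[j, ])^2)))
    worst <- max(worst, best)
  }
  for (j in seq_len(nrow(py))) {
    best <- Inf
    for (i in seq_len(nrow(px)))
      best <- min(best, sqrt(sum((px[i, ] - py[j, ])^2)))
    worst <- max(worst, best)
  }
  expect_equal(hausdorff(x, y), worst)
})

test_that("dilating a nested prediction towards truth never lowers dice", {
  truth <- matrix(0, 20, 20); truth[5:15, 5:15] <- 1
  prev <- matrix(0, 20, 20); prev[9:11, 9:11] <- 1
  d_prev <- dice(truth, prev)
  for (g in 1:3) {
    nxt <- matrix(0, 20, 20); nxt[(9 - g):(11 + g), (9 - g):(11 + g)] <- 1
    expect_gte(dice(truth, nxt), d_prev)
    d_prev <- dice(truth, nxt); prev <- nxt
  }
})

test_that("summaries report mean/median/IQR on the percent scale", {
  df <- data.frame(image = 1:5, dice = c(0.1, 0.2, 0.3, 0.4, 0.5),
                   iou = 0.5, voe = 0.5, hd = c(1, 2, 3, 4, 5),
                   pa = 0.99, pa_class = 0.9)
  s <- summarize_metrics(list(m = df))
  expect_equal(s$dice[s$statistic == "median"], 30)
  expect_equal(s$hd[s$statistic == "median"], 3)
  expect_equal(s$hd[s$statistic == "iqr"], 2)
  one <- summarize_metrics(list(m = df[1, ]))
  expect_equal(one$dice[one$statistic == "iqr"], 0)
  # quantile oracle: manual linear interpolation
  set.seed(25)
  v <- runif(17)
  q <- function(p) { h <- (length(v) - 1) * p + 1
    sv <- sort(v); lo <- floor(h); sv[lo] + (h - lo) * (sv[min(lo + 1, 17)] - sv[lo]) }
  df2 <- df[rep(1, 17), ]; df2$dice <- v
  s2 <- summarize_metrics(list(m = df2))
  expect_equal(s2$dice[s2$statistic == "iqr"], 100 * (q(0.75) - q(0.25)),
               tolerance = 1e-9)
})

test_that("paired wilcoxon matches its contracts", {
  expect_warning(p <- paired_wilcoxon(1:10, 1:10), "zero")
  expect_equal(p, 1)
  set.seed(26)
  a <- runif(20)
  b <- a + seq(9, 11, length.out = 20)      # distinct, all-positive shifts
  expect_lt(paired_wilcoxon(a, b), 0.01)
  # all-same-sign statistic for n = 20 has exact p = 2 * 2^-20
  expect_equal(paired_wilcoxon(a, b), 2 * 2^-20, tolerance = 1e-12)
  # small n uses the exact branch: known two-sided p for n = 4, all positive
  expect_equal(paired_wilcoxon(c(1, 2, 3, 4), c(2, 4, 6, 8)), 2 * 2^-4)
  ref <- suppressWarnings(wilcox.test(b, a, paired = TRUE)$p.value)
  expect_equal(paired_wilcoxon(a, b), ref)
})

test_that("evaluate_masks produces a complete per-image table", {
  set.seed(27)
  truths <- replicate(3, random_mask(16, 16, 0.3), simplify = FALSE)
  preds <- lapply(truths, function(m) { m[1:2, ] <- 0; m })
  df <- evaluate_masks(truths, preds)
  expect_equal(nrow(df), 3)
  expect_true(all(c("dice", "iou", "voe", "hd", "pa", "pa_class") %in% names(df)))
  expect_true(all(df$voe == 1 - df$iou))
})
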