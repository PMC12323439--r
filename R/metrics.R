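# Segmentation metric suite: overlap scores, Hausdorff distance, pixel
# accuracies, per-method summaries and paired significance testing.

as_binary_mask <- function(m) {
  if (is.null(dim(m)) || length(dim(m)) != 2L) stop("mask must be a matrix")
  (m != 0) * 1
}

check_same_dims <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("mask dimensions differ: ",
                                   paste(dim(x), collapse = "x"), " vs ",
                                   paste(dim(y), collapse = "x"))
}

#' Dice score between two binary masks
#'
#' `2|X intersect Y| / (|X| + |Y|)`; by convention 1 when both masks are
#' empty.
#'
#' @param x,y binary matrices of equal dimensions (nonzero = foreground).
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(x, y) {
  x <- as_binary_mask(x); y <- as_binary_mask(y)
  check_same_dims(x, y)
  s <- sum(x) + sum(y)
  if (s == 0) return(1)
  2 * sum(x * y) / s
}

#' Intersection over union
#'
#' `|X intersect Y| / |X union Y|`; 1 when both masks are empty.
#' @inheritParams dice
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(x, y) {
  x <- as_binary_mask(x); y <- as_binary_mask(y)
  check_same_dims(x, y)
  u <- sum(pmax(x, y))
  if (u == 0) return(1)
  sum(x * y) / u
}

#' Volumetric overlap error: `1 - IoU`
#' @inheritParams dice
#' @return VOE in `[0, 1]`.
#' @export
voe <- function(x, y) 1 - iou(x, y)

#' Symmetric Hausdorff distance between mask foregrounds
#'
#' `max(d(X, Y), d(Y, X))` where `d(A, B)` is the largest Euclidean distance
#' from a foreground pixel of A to its nearest foreground pixel of B. By
#' default the full foreground pixel sets are compared; `boundary = TRUE`
#' restricts both sets to their boundary pixels (4-neighbourhood erosion),
#' a cheaper contour-based variant that agrees with the set-based value for
#' solid, simply-connected shapes.
#'
#' @inheritParams dice
#' @param boundary compare boundary pixels only.
#' @return Hausdorff distance in pixels.
#' @export
hausdorff <- function(x, y, boundary = FALSE) {
  x <- as_binary_mask(x); y <- as_binary_mask(y)
  check_same_dims(x, y)
  if (sum(x) == 0 || sum(y) == 0) stop("Hausdorff distance undefined for empty masks")
  if (boundary) { x <- boundary_pixels(x); y <- boundary_pixels(y) }
  px <- which(x != 0, arr.ind = TRUE)
  py <- which(y != 0, arr.ind = TRUE)
  max(directed_hausdorff(px, py), directed_hausdorff(py, px))
}

directed_hausdorff <- function(a, b, chunk = 512L) {
  worst <- 0
  for (s in split(seq_len(nrow(a)), ceiling(seq_len(nrow(a)) / chunk))) {
    d2 <- outer(a[s, 1], b[, 1], "-")^2 + outer(a[s, 2], b[, 2], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1, min))))
  }
  worst
}

boundary_pixels <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  m * (!interior)
}

#' Confusion counts between ground truth and prediction
#'
#' @param truth,pred binary matrices (nonzero = lip class).
#' @return list with `tp`, `tn`, `fp`, `fn` (and per-class aliases `tpc`,
#'   `fnc` for the lip class).
#' @export
confusion_counts <- function(truth, pred) {
  truth <- as_binary_mask(truth); pred <- as_binary_mask(pred)
  check_same_dims(truth, pred)
  tp <- sum(truth * pred)
  fn <- sum(truth * (1 - pred))
  fp <- sum((1 - truth) * pred)
  tn <- sum((1 - truth) * (1 - pred))
  list(tp = tp, tn = tn, fp = fp, fn = fn, tpc = tp, fnc = fn)
}

#' Pixel accuracy and per-class (lip) pixel accuracy
#'
#' `PA = (TP + TN) / (TP + TN + FP + FN)`;
#' `PAc = TPc / (TPc + FNc)` for the lip class.
#'
#' @param counts output of [confusion_counts()].
#' @return list with `pa` and `pa_class`.
#' @export
pixel_accuracy <- function(counts) {
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  if (tot == 0) stop("empty confusion counts")
  if (counts$tpc + counts$fnc == 0) stop("no lip pixels in ground truth")
  list(pa = (counts$tp + counts$tn) / tot,
       pa_class = counts$tpc / (counts$tpc + counts$fnc))
}

#' Per-image metric suite
#'
#' Computes Dice, IoU, VOE, Hausdorff distance, pixel accuracy and per-class
#' pixel accuracy for each ground-truth/prediction pair.
#'
#' @param truths,preds lists of binary matrices, paired by index.
#' @return data frame with one row per image.
#' @export
evaluate_masks <- function(truths, preds) {
  stopifnot(length(truths) == length(preds), length(truths) >= 1L)
  rows <- lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]; pr <- preds[[i]]
    cc <- confusion_counts(tr, pr)
    pa <- pixel_accuracy(cc)
    hd <- if (sum(pr != 0) == 0 || sum(tr != 0) == 0) NA_real_
          else hausdorff(tr, pr)
    data.frame(image = i, dice = dice(tr, pr), iou = iou(tr, pr),
               voe = voe(tr, pr), hd = hd, pa = pa$pa, pa_class = pa$pa_class)
  })
  do.call(rbind, rows)
}

#' Summarise per-image metrics per method
#'
#' Mean, median and interquartile range (linear-interpolation quantiles,
#' `Q3 - Q1`) for each metric, with the overlap and accuracy metrics reported
#' on the 0-100 scale and the Hausdorff distance in pixels.
#'
#' @param reports named list of data frames from [evaluate_masks()], one per
#'   method.
#' @return long-format data frame: method, statistic, then one column per
#'   metric.
#' @export
summarize_metrics <- function(reports) {
  pct <- c("dice", "iou", "voe", "pa", "pa_class")
  mets <- c("dice", "hd", "iou", "pa", "pa_class", "voe")
  rows <- lapply(names(reports), function(m) {
    df <- reports[[m]]
    one <- function(stat, f) {
      vals <- vapply(mets, function(k) {
        v <- df[[k]][is.finite(df[[k]])]
        s <- f(v)
        if (k %in% pct) 100 * s else s
      }, 0)
      cbind(data.frame(method = m, statistic = stat), as.data.frame(as.list(vals)))
    }
    rbind(one("mean", mean),
          one("median", median),
          one("iqr", function(v) diff(unname(quantile(v, c(0.25, 0.75), type = 7)))))
  })
  do.call(rbind, rows)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired per-image metrics. Zero differences
#' are dropped (with a warning if all of them are zero, in which case p = 1).
#' The exact null distribution is used for small samples without ties.
#'
#' @param metric_a,metric_b equal-length numeric vectors paired by image.
#' @return two-sided p-value.
#' @export
paired_wilcoxon <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b))
  d <- metric_b - metric_a
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; returning p = 1")
    return(1)
  }
  suppressWarnings(wilcox.test(d, alternative = "two.sided", exact = length(d) < 50)$p.value)
}
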