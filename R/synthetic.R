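# Synthetic face-like images with a parametric upper lip, ordered anatomical
# landmarks, ground-truth masks and case/control labels. The generator
# emulates the statistical structure of the study cohort (imbalanced thin-lip
# cases vs normal controls, two cohorts differing in tone distributions, low
# and variable lip/skin contrast, nostril-like distractors, illumination
# gradients and sensor noise) without attempting photorealism.

#' Lip shape parameters
#'
#' Geometry and appearance of one synthetic upper lip, in pixels of the
#' target image. Defaults describe a face-framed lip in a 256 x 256 image;
#' pass `size` to rescale every geometric default proportionally.
#'
#' @param size image side in pixels (geometry defaults scale with `size/256`).
#' @param center lip centre (x, y), 0-based pixel coordinates.
#' @param width chelion-to-chelion distance in pixels.
#' @param upper_thickness vermilion height at the philtrum, pixels.
#' @param cupid_bow_depth dip of the central notch below the bow peaks,
#'   pixels; must be `< upper_thickness`.
#' @param bow_peak_offset horizontal bow-peak position, pixels.
#' @param rotation in-plane rotation, degrees.
#' @param skin_tone,lip_tone RGB triples (0-255).
#' @param noise_sigma additive Gaussian pixel noise, gray levels.
#' @param contrast lip/skin blend factor in (0, 1]; low values give a faint
#'   vermilion border.
#' @return list of class `lip_shape_params`.
#' @export
lip_shape_params <- function(size = 256L,
                             center = c(size / 2, 0.66 * size),
                             width = 0.35 * size,
                             upper_thickness = 14 * size / 256,
                             cupid_bow_depth = 0.25 * upper_thickness,
                             bow_peak_offset = 0.13 * width,
                             rotation = 0,
                             skin_tone = c(224, 172, 148),
                             lip_tone = c(150, 70, 75),
                             noise_sigma = 8,
                             contrast = 0.8) {
  p <- list(size = as.integer(size), center = center, width = width,
            upper_thickness = upper_thickness, cupid_bow_depth = cupid_bow_depth,
            bow_peak_offset = bow_peak_offset, rotation = rotation,
            skin_tone = skin_tone, lip_tone = lip_tone,
            noise_sigma = noise_sigma, contrast = contrast)
  validate_params(p)
  structure(p, class = "lip_shape_params")
}

validate_params <- function(p) {
  if (p$width <= 0) stop("width must be positive")
  if (p$upper_thickness <= 0) stop("upper_thickness must be positive")
  if (p$cupid_bow_depth < 0 || p$cupid_bow_depth >= p$upper_thickness)
    stop("cupid_bow_depth must be in [0, upper_thickness)")
  if (p$noise_sigma < 0) stop("noise_sigma must be non-negative")
  invisible(p)
}

# outline of the parametric lip in image coordinates
lip_outline <- function(p, n = 400L) {
  poly <- lip_polygon_local(p$width, p$upper_thickness, p$cupid_bow_depth,
                            p$bow_peak_offset, n)
  th <- p$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(poly %*% t(R), 2, p$center, "+")
}

#' Generate one synthetic sample
#'
#' Draws a face-like image containing a parametric upper lip (closed
#' polygon from two cubic Bezier outer-border arcs meeting at the cupid's-bow
#' notch plus a shallow mouth-line arc), the matching binary mask, and
#' ordered anatomical landmarks on the polygon (chelions, bow peaks, labiale
#' superius, stomion plus intermediates). Deterministic given
#' `(params, seed)`.
#'
#' @param params a [lip_shape_params()].
#' @param seed integer seed.
#' @param n_landmarks number of emitted landmarks (>= 6).
#' @return object of class `lip_sample`: list with `image` (H x W x 3
#'   integer array, 0-255), `landmarks` (named N x 2 matrix), `mask`
#'   (H x W 0/1), `label` (`"case"`/`"control"`), `cohort`, `vbls_grade`,
#'   `params`.
#' @export
generate_sample <- function(params, seed = 0L, n_landmarks = 13L) {
  validate_params(params)
  set.seed(as.integer(seed))
  size <- params$size
  poly <- lip_outline(params)
  if (min(poly) < 0 || max(poly) > size - 1) {
    bad <- if (max(abs(poly[, 1] - params$center[1])) > size / 2 - 1 ||
               max(abs(poly[, 2] - params$center[2])) > size / 2 - 1)
      "width/upper_thickness" else "center"
    stop("lip extends outside the image; adjust ", bad)
  }
  mask <- rasterize_polygon(poly, c(size, size))
  lm <- outline_landmarks(poly, n_landmarks)

  xg <- matrix(seq_len(size) - 1, size, size, byrow = TRUE) / (size - 1)
  yg <- matrix(seq_len(size) - 1, size, size) / (size - 1)
  grad_dir <- runif(1, 0, 2 * pi)
  illum <- 1 + 0.12 * ((xg - 0.5) * cos(grad_dir) + (yg - 0.5) * sin(grad_dir))
  lip_eff <- params$skin_tone + params$contrast * (params$lip_tone - params$skin_tone)

  img <- array(0, c(size, size, 3L))
  nostril <- nostril_mask(params, size)
  shadow_tone <- 0.55 * params$skin_tone
  for (ch in 1:3) {
    plane <- params$skin_tone[ch] * illum
    plane[nostril == 1] <- shadow_tone[ch] * illum[nostril == 1]
    plane[mask == 1] <- lip_eff[ch] * illum[mask == 1]
    plane <- plane + rnorm(size * size, 0, params$noise_sigma)
    img[, , ch] <- pmin(pmax(round(plane), 0), 255)
  }
  label <- if (params$upper_thickness <= thin_lip_threshold(size)) "case" else "control"
  structure(list(image = img, landmarks = lm, mask = mask, label = label,
                 cohort = attr(params, "cohort") %||% "A",
                 vbls_grade = vbls_from_thickness(params$upper_thickness, size),
                 params = params),
            class = "lip_sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thin-lip class threshold
#'
#' A sample is labelled `case` when its vermilion thickness at the philtrum
#' is at most this many pixels (8 at 256 x 256, scaled with image size).
#' @param size image side in pixels.
#' @export
thin_lip_threshold <- function(size = 256L) 8 * size / 256

# 5-point thickness grade; 4-5 = thin
vbls_from_thickness <- function(u, size) {
  u256 <- u * 256 / size
  if (u256 >= 18) 1L else if (u256 >= 14) 2L else if (u256 > 8) 3L
  else if (u256 >= 6) 4L else 5L
}

nostril_mask <- function(p, size) {
  m <- matrix(0, size, size)
  cx <- p$center[1]; cy <- p$center[2] - 2.2 * p$upper_thickness - 0.10 * size
  rx <- 0.035 * size; ry <- 0.022 * size
  xs <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  ys <- matrix(seq_len(size) - 1, size, size)
  for (sgn in c(-1, 1)) {
    ex <- cx + sgn * 0.08 * size
    m[((xs - ex) / rx)^2 + ((ys - cy) / ry)^2 <= 1] <- 1
  }
  m
}

#' Generate a synthetic cohort
#'
#' Case samples are drawn from a thin-lip parameter distribution (thickness
#' 4-8 px at 256 scale), controls from a normal-thickness distribution
#' (9-22 px). Default sizes mirror the imbalanced study cohort (82 cases,
#' 371 controls). Cohorts `"A"` and `"B"` differ only in their skin/lip tone
#' distributions. Per-sample seeds are derived reproducibly from `seed`.
#'
#' @param n_case,n_control class sizes.
#' @param cohort `"A"` or `"B"`.
#' @param seed master seed.
#' @param size image side in pixels.
#' @param n_landmarks landmarks per sample.
#' @return list of [generate_sample()] objects (cases first).
#' @export
generate_cohort <- function(n_case = 82L, n_control = 371L,
                            cohort = c("A", "B"), seed = 1L, size = 256L,
                            n_landmarks = 13L) {
  cohort <- match.arg(cohort)
  stopifnot(n_case >= 0, n_control >= 0)
  set.seed(as.integer(seed))
  n <- n_case + n_control
  labels <- rep(c("case", "control"), c(n_case, n_control))
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  sc <- size / 256
  skin_base <- if (cohort == "A") c(224, 172, 148) else c(120, 85, 70)
  lip_base <- if (cohort == "A") c(150, 70, 75) else c(80, 45, 45)
  lapply(seq_len(n), function(i) {
    u <- if (labels[i] == "case") clip(rnorm(1, 6, 1), 4, 8)
         else clip(rnorm(1, 14, 2.5), 9, 22)
    w <- clip(rnorm(1, 90, 8), 70, 110)
    p <- lip_shape_params(
      size = size,
      center = c(size / 2 + runif(1, -8, 8) * sc, 0.66 * size + runif(1, -8, 8) * sc),
      width = w * sc,
      upper_thickness = u * sc,
      cupid_bow_depth = runif(1, 0.15, 0.3) * u * sc,
      bow_peak_offset = runif(1, 0.10, 0.16) * w * sc,
      rotation = rnorm(1, 0, 2),
      skin_tone = clip(skin_base + runif(3, -18, 18), 0, 255),
      lip_tone = clip(lip_base + runif(3, -15, 15), 0, 255),
      noise_sigma = 8,
      contrast = runif(1, 0.3, 0.9))
    attr(p, "cohort") <- cohort
    generate_sample(p, seeds[i], n_landmarks)
  })
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Augment a sample
#'
#' Applies each requested augmentation separately to the image, mask and
#' landmarks, keeping all three consistent: `hflip` mirrors x coordinates and
#' reverses the landmark traversal (swapping left/right names); `rotate5`
#' rotates by 5 degrees about the image centre (bilinear for the image,
#' nearest for the mask, exact for the landmarks); `brightness_0.8` /
#' `brightness_1.1` multiply the RGB values, round half-to-even and clip to
#' the 0-255 range. Augmentation operates on the raw RGB image, before any texture
#' features are computed. A rotation that pushes landmarks out of frame drops
#' that variant with a warning.
#'
#' @param sample a [generate_sample()] result.
#' @param ops subset of `c("hflip", "rotate5", "brightness_0.8",
#'   "brightness_1.1")`.
#' @return list of augmented `lip_sample` objects, one per surviving op.
#' @export
augment_sample <- function(sample, ops = c("hflip", "rotate5",
                                           "brightness_0.8", "brightness_1.1")) {
  ops <- match.arg(ops, several.ok = TRUE)
  out <- list()
  for (op in ops) {
    s2 <- switch(op,
      hflip = aug_hflip(sample),
      rotate5 = aug_rotate(sample, 5),
      brightness_0.8 = aug_brightness(sample, 0.8),
      brightness_1.1 = aug_brightness(sample, 1.1))
    if (!is.null(s2)) out[[length(out) + 1L]] <- s2
  }
  out
}

aug_hflip <- function(s) {
  W <- ncol(s$mask)
  s$image <- s$image[, W:1, , drop = FALSE]
  s$mask <- s$mask[, W:1, drop = FALSE]
  lm <- s$landmarks
  lm[, 1] <- (W - 1) - lm[, 1]
  lm <- lm[nrow(lm):1, , drop = FALSE]
  swap <- grepl("_(l|r)$", rownames(lm))
  rownames(lm)[swap] <- ifelse(grepl("_l$", rownames(lm)[swap]),
                               sub("_l$", "_r", rownames(lm)[swap]),
                               sub("_r$", "_l", rownames(lm)[swap]))
  s$landmarks <- lm
  s
}

aug_rotate <- function(s, angle) {
  H <- nrow(s$mask); W <- ncol(s$mask)
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  lm <- s$landmarks
  lm[] <- sweep(sweep(unclass(lm), 2, ctr) %*% t(R), 2, ctr, "+")
  if (min(lm[, 1]) < 0 || max(lm[, 1]) > W - 1 ||
      min(lm[, 2]) < 0 || max(lm[, 2]) > H - 1) {
    warning("rotation pushed landmarks out of frame; sample dropped")
    return(NULL)
  }
  s$image <- rotate_image(s$image, th, ctr, bilinear = TRUE)
  # box-filter the binary mask first so bilinear sampling sees a sub-pixel
  # boundary ramp; thresholding then recovers the rotated contour closely
  soft <- rotate_image(box3(s$mask), th, ctr, bilinear = TRUE)
  s$mask <- (soft >= 0.5) * 1
  s$landmarks <- lm
  s
}

# 3x3 box filter with edge replication
box3 <- function(m) {
  p <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  p <- cbind(p[, 1, drop = FALSE], p, p[, ncol(p), drop = FALSE])
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2)
    out <- out + p[dr + seq_len(nr), dc + seq_len(nc)]
  out / 9
}

# inverse-mapping rotation about ctr; bilinear with edge clamping, or nearest
rotate_image <- function(img, th, ctr, bilinear = TRUE) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  xs <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  ys <- matrix(seq_len(H) - 1, H, W)
  dx <- xs - ctr[1]; dy <- ys - ctr[2]
  sx <- cos(th) * dx + sin(th) * dy + ctr[1]   # R(-th) applied to (dx, dy)
  sy <- -sin(th) * dx + cos(th) * dy + ctr[2]
  svx <- as.vector(sx); svy <- as.vector(sy)
  sample_plane <- function(plane) {
    if (bilinear) {
      x0 <- clip(floor(svx), 0, W - 1); y0 <- clip(floor(svy), 0, H - 1)
      x1 <- clip(x0 + 1, 0, W - 1); y1 <- clip(y0 + 1, 0, H - 1)
      fx <- clip(svx - x0, 0, 1); fy <- clip(svy - y0, 0, 1)
      v00 <- plane[cbind(y0 + 1, x0 + 1)]; v01 <- plane[cbind(y0 + 1, x1 + 1)]
      v10 <- plane[cbind(y1 + 1, x0 + 1)]; v11 <- plane[cbind(y1 + 1, x1 + 1)]
      v <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
      matrix(v, H, W)
    } else {
      xr <- round(svx); yr <- round(svy)
      ok <- xr >= 0 & xr <= W - 1 & yr >= 0 & yr <= H - 1
      v <- numeric(H * W)
      v[ok] <- plane[cbind(yr[ok] + 1, xr[ok] + 1)]
      matrix(v, H, W)
    }
  }
  if (length(d) == 2L) return(sample_plane(img))
  out <- img
  for (ch in seq_len(d[3])) out[, , ch] <- round(sample_plane(img[, , ch]))
  out
}

aug_brightness <- function(s, factor) {
  s$image[] <- clip(round(s$image * factor), 0, 255)
  s
}
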