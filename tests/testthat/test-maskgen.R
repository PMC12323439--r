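# Landmark-to-template mask generation.

template_landmarks <- function(n = 13) {
  tmpl <- lip_template()
  idx <- round(seq(1, nrow(tmpl$contour), length.out = n + 1))[1:n]
  list(template = tmpl, idx = idx, pts = tmpl$contour[idx, ])
}

similarity <- function(pts, th, sc, tx, ty) {
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sc * pts %*% t(R), 2, c(tx, ty), "+")
}

test_that("the canonical template is closed, simple, dense and bow-shaped", {
  tmpl <- lip_template()
  expect_gte(nrow(tmpl$contour), 200)
  expect_false(lipseg:::polygon_self_intersects(tmpl$contour))
  expect_true(all(diff(tmpl$arc) > 0))
  # cupid's bow: the upper border has a local y dip between the two peaks
  upper <- tmpl$contour[tmpl$contour[, 2] < -0.1, ]
  notch_y <- upper[which.min(abs(upper[, 1])), 2]
  expect_gt(notch_y, min(upper[, 2]))  # notch sits below (greater y) the peaks
})

test_that("correspondence reproduces coincident landmarks exactly", {
  tl <- template_landmarks()
  corr <- correspond(tl$pts, tl$template)
  expect_lt(max(sqrt(rowSums((corr$points - tl$pts)^2))), 1e-6)
  scaled <- tl$pts * 2
  corr2 <- correspond(scaled, tl$template)
  expect_lt(max(sqrt(rowSums((corr2$points - scaled)^2))), 1e-6)
})

test_that("correspondence validates degenerate and unordered landmarks", {
  expect_error(correspond(matrix(c(0, 0, 1, 1), 2, 2)), "3 landmarks")
  line <- cbind(seq(0, 1, length.out = 6), seq(0, 2, length.out = 6))
  expect_error(correspond(line), "collinear")
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(0, 1))
  expect_error(correspond(dup), "distinct")
  tl <- template_landmarks()
  lm <- similarity(tl$pts, 0, 30, 100, 100)
  swapped <- lm; swapped[c(3, 9), ] <- swapped[c(9, 3), ]
  expect_error(correspond(swapped, tl$template), "ordered")
  fixed <- correspond(swapped, tl$template, reorder = TRUE)
  expect_true(lipseg:::circularly_monotone(fixed$vertex_idx,
                                           nrow(tl$template$contour)))
})

test_that("template densification projects chord points onto the contour", {
  tl <- template_landmarks()
  corr <- correspond(tl$pts, tl$template)
  # pts_per_segment = 0 leaves only the landmark polygon
  expect_equal(nrow(discretize_template(corr, 0)), 0)
  interp <- discretize_template(corr, 10)
  expect_equal(nrow(interp), 10 * 13)
  # mouth-line arc is almost straight: a = 0.5 lands near the chord midpoint
  interp9 <- discretize_template(corr, 9)       # grid k/10 contains a = 0.5
  mouth <- interp9[interp9$segment == 12 & interp9$a == 0.5, ]
  mid <- (corr$points[12, ] + corr$points[13, ]) / 2
  expect_lt(sqrt((mouth$x - mid[1])^2 + (mouth$y - mid[2])^2), 0.02)
  # strongly curved synthetic arc: the projection picks the apex
  semi <- new_semi <- NULL
  th <- seq(pi, 0, length.out = 181)
  semicirc <- cbind(cos(th), -sin(th))
  closing <- cbind(seq(1, -1, length.out = 60)[-c(1, 60)], 0)
  poly <- rbind(semicirc, closing)
  tmpl2 <- lipseg:::new_lip_template(poly)
  lms <- poly[c(1, 91, 181, 210), ]
  corr2 <- correspond(lms, tmpl2)
  i2 <- discretize_template(corr2, 1)           # a = 0.5 on each segment
  apex <- i2[i2$segment == 1, ]                 # between (-1,0) and (0,-1)
  d_apex <- sqrt(apex$x^2 + apex$y^2)
  expect_equal(d_apex, 1, tolerance = 1e-3)     # on the unit arc
})

test_that("interpolated landmarks keep strictly increasing contour positions", {
  set.seed(31)
  for (k in 1:5) {
    s <- generate_sample(lip_shape_params(rotation = runif(1, -8, 8)), seed = k)
    corr <- correspond(s$landmarks)
    interp <- discretize_template(corr, 10)
    pos <- interp$arc_pos + 0  # within-segment positions
    expect_true(all(tapply(pos, interp$segment, function(v) all(diff(v) > 0))))
    A <- project_to_trajectory(corr, interp)
    expect_equal(nrow(A), nrow(interp))
  }
})

test_that("projection modes satisfy their geometric contracts", {
  tl <- template_landmarks()
  corr <- correspond(tl$pts, tl$template)
  interp <- discretize_template(corr, 10)
  # identity: chord_frame returns the interpolated template points exactly
  A <- project_to_trajectory(corr, interp, "chord_frame")
  expect_lt(max(abs(A - cbind(interp$x, interp$y))), 1e-6)
  # straight-chord midpoint with zero deviation -> midpoint in both modes
  interp9 <- discretize_template(corr, 9)
  r <- which(interp9$segment == 12 & interp9$a == 0.5)
  Ar <- project_to_trajectory(corr, interp9, "ratio", "polyline")
  mid <- (corr$landmarks[12, ] + corr$landmarks[13, ]) / 2
  expect_lt(sqrt(sum((Ar[r, ] - mid)^2)), 0.05)
  # equivariance: generate-then-transform == transform-then-generate
  Q <- function(p) similarity(p, 0.35, 37, 110, 140)
  corrQ <- correspond(Q(tl$pts), tl$template)
  AQ <- project_to_trajectory(corrQ, discretize_template(corrQ, 10), "chord_frame")
  expect_lt(max(abs(Q(A) - AQ)), 1e-6)
})

test_that("ratio mode supports a spline trajectory", {
  tl <- template_landmarks()
  lm <- similarity(tl$pts, 0.1, 40, 120, 120)
  corr <- correspond(lm, tl$template)
  interp <- discretize_template(corr, 5)
  As <- project_to_trajectory(corr, interp, "ratio", "spline")
  Ap <- project_to_trajectory(corr, interp, "ratio", "polyline")
  expect_equal(dim(As), dim(Ap))
  # the spline passes near the polyline for a densely sampled contour
  expect_lt(max(sqrt(rowSums((As - Ap)^2))), 6)
})

test_that("rasterization follows the documented pixel-centre even-odd rule", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  m <- rasterize_polygon(sq, c(20, 20))
  expect_equal(sum(m), 100)
  # point-in-polygon oracle over all pixel centres (half-open boundaries)
  oracle <- matrix(0, 20, 20)
  for (y in 0:19) for (x in 0:19)
    oracle[y + 1, x + 1] <- (x >= 0 && x < 10 && y >= 0 && y < 10) * 1
  expect_identical(m, oracle)
  # shifted by half a pixel: centres 0..9 remain inside [-0.5, 9.5)
  sq2 <- sq - 0.5
  expect_equal(sum(rasterize_polygon(sq2, c(20, 20))), 100)
  expect_identical(rasterize_polygon(sq, c(20, 20)), m)  # deterministic
  outside <- sq + 100
  expect_warning(m2 <- assemble_and_rasterize(outside,
    structure(matrix(numeric(0), 0, 2), segment = integer(0)), c(20, 20)),
    "outside")
  expect_equal(sum(m2), 0)
})

test_that("self-intersecting contours are rejected with segment indices", {
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(assemble_and_rasterize(bowtie,
    structure(matrix(numeric(0), 0, 2), segment = integer(0)), c(20, 20)),
    "self-intersects")
})

test_that("mask generation is similarity-equivariant (Dice >= 0.98)", {
  tl <- template_landmarks()
  base <- similarity(tl$pts, 0, 40, 128, 128)
  m0 <- generate_mask_from_landmarks(base, c(256, 256))
  poly0 <- attr(m0, "contour")
  set.seed(33)
  for (k in 1:6) {
    th <- runif(1, -30, 30) * pi / 180
    sc <- runif(1, 0.7, 1.5)
    tx <- runif(1, 100, 156); ty <- runif(1, 100, 156)
    mq <- generate_mask_from_landmarks(similarity(tl$pts, th, 40 * sc, tx, ty),
                                       c(256, 256))
    ctr <- c(128, 128)
    ref_poly <- similarity(sweep(poly0, 2, ctr), th, sc, tx, ty)
    mref <- rasterize_polygon(ref_poly, c(256, 256))
    expect_gte(dice(mq, mref), 0.98)
  }
})

test_that("denser interpolation approaches the aligned template contour", {
  # landmarks anchored at the anatomical positions (chelions sit on the
  # contour corners, as in real annotations)
  tl <- list(template = lip_template())
  tl$pts <- unclass(lipseg:::outline_landmarks(tl$template$contour, 13))
  lm <- similarity(tl$pts, 0.15, 42, 125, 130)
  corr <- correspond(lm, tl$template)
  hd_contour <- function(k) {
    interp <- discretize_template(corr, k)
    A <- project_to_trajectory(corr, interp, "chord_frame")
    contour <- lipseg:::interleave_contour(corr$landmarks, A)
    closed <- rbind(contour, contour[1, ])
    d <- vapply(seq_len(nrow(corr$aligned)), function(i) {
      pr <- lipseg:::project_point_polyline(corr$aligned[i, ], closed)
      sqrt(sum((pr$point - corr$aligned[i, ])^2))
    }, 0)
    max(d)
  }
  hs <- vapply(c(0, 2, 5, 10), hd_contour, 0)
  expect_true(all(diff(hs) <= 1e-9))
  expect_lt(hs[4], 0.5 * hs[1])
})

test_that("end-to-end landmark masks closely match generator ground truth", {
  set.seed(34)
  co <- generate_cohort(2, 6, "A", seed = 35, size = 256)
  d <- vapply(co, function(s)
    dice(s$mask, generate_mask_from_landmarks(s$landmarks, dim(s$mask))), 0)
  expect_gt(mean(d), 0.88)
  expect_true(all(d > 0.8))
})
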