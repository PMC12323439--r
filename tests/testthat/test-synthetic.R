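# Synthetic cohort generator and augmentations.

test_that("samples are deterministic with plausible lip geometry", {
  p <- lip_shape_params()
  s1 <- generate_sample(p, seed = 0)
  s2 <- generate_sample(p, seed = 0)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  expect_equal(dim(s1$image), c(256L, 256L, 3L))
  frac <- mean(s1$mask)
  expect_gt(frac, 0.005); expect_lt(frac, 0.10)
  expect_true(all(s1$image >= 0 & s1$image <= 255))
  s3 <- generate_sample(p, seed = 1)
  expect_false(identical(s1$image, s3$image))
})

test_that("thinner lips give smaller masks and parameter validation fires", {
  thin <- generate_sample(lip_shape_params(upper_thickness = 4,
                                           cupid_bow_depth = 1), seed = 2)
  thick <- generate_sample(lip_shape_params(upper_thickness = 16,
                                            cupid_bow_depth = 4), seed = 2)
  expect_lt(sum(thin$mask), sum(thick$mask))
  expect_equal(thin$label, "case")
  expect_equal(thick$label, "control")
  expect_error(lip_shape_params(width = -1), "width")
  expect_error(lip_shape_params(upper_thickness = 5, cupid_bow_depth = 5),
               "cupid_bow_depth")
  expect_error(generate_sample(lip_shape_params(width = 300), 0), "outside")
})

test_that("landmarks lie on the mask boundary", {
  set.seed(41)
  co <- generate_cohort(6, 18, "A", seed = 42, size = 256)
  for (s in co) {
    # exact: every landmark is a vertex of the generating contour
    poly <- lipseg:::lip_outline(s$params)
    closed <- rbind(poly, poly[1, ])
    for (i in seq_len(nrow(s$landmarks))) {
      pr <- lipseg:::project_point_polyline(s$landmarks[i, ], closed)
      expect_lt(sqrt(sum((pr$point - s$landmarks[i, ])^2)), 1e-9)
    }
    # and within a pixel of the rasterized boundary wherever the thin wedge
    # near the chelions did not vanish entirely under rasterization
    bd <- which(lipseg:::boundary_pixels(s$mask) != 0, arr.ind = TRUE)
    fg <- which(s$mask != 0, arr.ind = TRUE)
    for (i in seq_len(nrow(s$landmarks))) {
      near_fg <- min(sqrt((fg[, 2] - 1 - s$landmarks[i, 1])^2 +
                          (fg[, 1] - 1 - s$landmarks[i, 2])^2))
      if (near_fg > 1.5) next
      d <- min(sqrt((bd[, 2] - 1 - s$landmarks[i, 1])^2 +
                    (bd[, 1] - 1 - s$landmarks[i, 2])^2))
      expect_lte(d, 1.5)
    }
  }
})

test_that("cohorts have the requested composition and thickness separation", {
  co <- generate_cohort(0, 5, "A", seed = 1)
  expect_length(co, 5)
  expect_true(all(vapply(co, `[[`, "", "label") == "control"))
  co2 <- generate_cohort(10, 10, "A", seed = 3)
  u <- vapply(co2, function(s) s$params$upper_thickness, 0)
  lab <- vapply(co2, `[[`, "", "label")
  expect_equal(sum(lab == "case"), 10)
  expect_lt(mean(u[lab == "case"]), mean(u[lab == "control"]))
  expect_true(all(vapply(co2[lab == "case"], `[[`, 1L, "vbls_grade") >= 4))
  expect_true(all(vapply(co2[lab == "control"], `[[`, 1L, "vbls_grade") <= 3))
  # identical seeds give identical cohorts
  co3 <- generate_cohort(10, 10, "A", seed = 3)
  expect_identical(co2, co3)
  # cohorts differ in tone distributions
  coB <- generate_cohort(2, 2, "B", seed = 3)
  expect_false(identical(coB[[1]]$params$skin_tone, co2[[1]]$params$skin_tone))
})

test_that("horizontal flip is an involution that relabels sides", {
  s <- generate_sample(lip_shape_params(), seed = 7)
  f1 <- augment_sample(s, "hflip")[[1]]
  expect_false(identical(f1$image, s$image))
  expect_equal(rownames(f1$landmarks)[nrow(f1$landmarks)],
               sub("_l$", "_r", rownames(s$landmarks)[1]))
  f2 <- augment_sample(f1, "hflip")[[1]]
  expect_identical(f2$image, s$image)
  expect_identical(f2$mask, s$mask)
  expect_equal(matrix(f2$landmarks, ncol = 2), matrix(s$landmarks, ncol = 2))
})

test_that("brightness augmentation is exact integer arithmetic", {
  s <- generate_sample(lip_shape_params(), seed = 8)
  gray <- s; gray$image[] <- 128
  b <- augment_sample(gray, "brightness_1.1")[[1]]
  expect_true(all(b$image == 141))          # round-half-to-even of 140.8
  b2 <- augment_sample(gray, "brightness_0.8")[[1]]
  expect_true(all(b2$image == 102))
  sat <- s; sat$image[] <- 250
  expect_true(all(augment_sample(sat, "brightness_1.1")[[1]]$image == 255))
  expect_identical(b$mask, gray$mask)
  expect_identical(b$landmarks, gray$landmarks)
})

test_that("all four augmentations yield four consistent variants", {
  s <- generate_sample(lip_shape_params(), seed = 9)
  out <- augment_sample(s)
  expect_length(out, 4)
  # each variant keeps image/mask dimensions and landmark count
  for (v in out) {
    expect_equal(dim(v$image), dim(s$image))
    expect_equal(dim(v$mask), dim(s$mask))
    expect_equal(nrow(v$landmarks), nrow(s$landmarks))
  }
})

test_that("rotation keeps image, mask and landmarks consistent", {
  set.seed(43)
  for (k in 1:6) {
    s <- generate_sample(lip_shape_params(), seed = 100 + k)
    r <- augment_sample(s, "rotate5")[[1]]
    # rotated ground-truth polygon must match the rotated raster mask
    th <- 5 * pi / 180
    ctr <- c((ncol(s$mask) - 1) / 2, (nrow(s$mask) - 1) / 2)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    poly <- lipseg:::lip_outline(s$params)
    polyr <- sweep(sweep(poly, 2, ctr) %*% t(R), 2, ctr, "+")
    mref <- rasterize_polygon(polyr, dim(s$mask))
    expect_gte(dice(r$mask, mref), 0.98)
    # landmarks stay near the rotated mask boundary (the chelion wedge tips
    # can lose their last pixel under resampling, hence the looser bound)
    bd <- which(lipseg:::boundary_pixels(r$mask) != 0, arr.ind = TRUE)
    dmax <- max(vapply(seq_len(nrow(r$landmarks)), function(i)
      min(sqrt((bd[, 2] - 1 - r$landmarks[i, 1])^2 +
               (bd[, 1] - 1 - r$landmarks[i, 2])^2)), 0))
    expect_lte(dmax, 2.5)
  }
})

test_that("rotation that pushes landmarks out of frame drops the sample", {
  p <- lip_shape_params(center = c(247, 247), width = 14, upper_thickness = 5,
                        cupid_bow_depth = 1)
  s <- generate_sample(p, seed = 10)
  expect_warning(out <- augment_sample(s, "rotate5"), "dropped")
  expect_length(out, 0)
})
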