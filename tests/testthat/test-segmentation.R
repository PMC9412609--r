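# Two-phase segmentation: channel unification, weighted threshold,
# morphological passes, boundary band, neutrosophic refinement, and the
# orchestrated path against a brute-force oracle.

test_that("channel unification is the cube root of the channel product", {
  expect_equal(unify_channels(array(100, c(3, 3, 3))), matrix(100, 3, 3))
  expect_equal(unify_channels(array(255, c(2, 2, 3))), matrix(255, 2, 2))
  expect_equal(unify_channels(array(c(64, 125, 216), c(1, 1, 3)))[1, 1], 120)
})

test_that("the global threshold is the weighted blend of the extremes", {
  g <- matrix(c(0, 255, 10, 90), 2, 2)
  expect_equal(global_threshold(g), (0 * .4 + 255 * .6) / 1)   # 153
  expect_equal(global_threshold(matrix(77, 4, 4), 0.9, 0.1), 77)
  g2 <- matrix(c(50, 200, 120, 130), 2, 2)
  expect_equal(global_threshold(g2), 140)
  expect_error(global_threshold(matrix(numeric(0), 0, 0)), "empty")
  # gamma always sits between the extremes
  set.seed(8)
  for (i in 1:10) {
    m <- matrix(runif(64, 0, 255), 8, 8)
    gm <- global_threshold(m)
    expect_gte(gm, min(m)); expect_lte(gm, max(m))
  }
})

test_that("the initial mask keeps strictly darker pixels", {
  g <- matrix(c(100, 140, 200, 160), 2, 2)
  expect_equal(initial_mask(g, 153), matrix(c(255, 255, 0, 0), 2, 2))
  expect_equal(initial_mask(matrix(10, 2, 2), 153), matrix(255, 2, 2))
  expect_equal(initial_mask(matrix(200, 2, 2), 153), matrix(0, 2, 2))
  # constant image at its own threshold: nothing is strictly below
  expect_equal(initial_mask(matrix(80, 2, 2), 80), matrix(0, 2, 2))
})

test_that("min and max passes are sliding rank filters with replication", {
  full <- matrix(255, 9, 9)
  expect_equal(min_pass(full), full)
  zero <- matrix(0, 9, 9)
  expect_equal(max_pass(zero), zero)
  # isolated foreground pixel dies under the 3x3 minimum
  solo <- zero; solo[5, 5] <- 255
  expect_equal(min_pass(solo), zero)
  # a 3x3 block erodes to its centre
  blk <- zero; blk[4:6, 4:6] <- 255
  ctr <- zero; ctr[5, 5] <- 255
  expect_equal(min_pass(blk), ctr)
  # a single pixel dilates to the full 7x7 square
  expect_equal(sum(max_pass(solo) > 0), 49)
  expect_true(all(max_pass(solo)[2:8, 2:8] == 255))
  # erosion is anti-extensive, dilation extensive
  set.seed(2)
  m <- (matrix(runif(400), 20, 20) > 0.6) * 255
  expect_true(all(min_pass(m) <= m))
  expect_true(all(max_pass(m) >= m))
})

test_that("the boundary band rings the mask boundary at the given width", {
  zero <- matrix(0, 15, 15)
  expect_equal(boundary_band(zero, 3), zero)
  # full-image mask: the band hugs the image border
  full <- matrix(255, 15, 15)
  b <- boundary_band(full, 1)
  expect_true(all(b[1, ] == 255) && all(b[, 1] == 255))
  expect_true(all(b[2:14, 2:14] == 0))
  # disc, width 1: exactly the 8-connected inner boundary, by brute force
  d <- matrix(0, 21, 21)
  for (i in 1:21) for (j in 1:21)
    if ((i - 11)^2 + (j - 11)^2 <= 49) d[i, j] <- 255
  b1 <- boundary_band(d, 1)
  expected <- matrix(0, 21, 21)
  for (i in 1:21) for (j in 1:21) {
    if (d[i, j] == 0) next
    nb <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > 21 || jj < 1 || jj > 21 || d[ii, jj] == 0) nb <- TRUE
    }
    if (nb) expected[i, j] <- 255
  }
  expect_equal(b1, expected)
  # wider band contains the narrow one
  expect_true(all(boundary_band(d, 3) >= b1))
})

test_that("refinement keeps dark band pixels against the threshold", {
  gray <- matrix(c(20, 40, 60, 80, 150, 150), 2, 3)
  phase1 <- matrix(c(255, 255, 255, 255, 0, 0), 2, 3)
  band <- matrix(c(255, 255, 255, 255, 0, 0), 2, 3)
  # normalized darkness of the four band pixels: 1, 2/3, 1/3, 0
  out <- refine(gray, phase1, band, spec = pnn_spec(rep(0.5, 5), 1, 0, 0))
  expect_equal(attr(out, "theta"), 0.5)
  expect_equal(out[1:4], c(255, 255, 0, 0))           # exactly two accepted
  expect_equal(out[5:6], c(0, 0))                     # outside band untouched
  # theta = 0 accepts every band pixel
  out0 <- refine(gray, phase1, band, spec = pnn_spec(rep(0, 5), 1, 0, 0))
  expect_equal(out0[1:4], rep(255, 4))
  # theta at the top of the scale keeps only the very darkest band pixel
  out1 <- refine(gray, phase1, band, spec = pnn_spec(rep(1, 5), 1, 0, 0))
  expect_equal(attr(out1, "theta"), 1)
  expect_equal(out1[1:4], c(255, 0, 0, 0))
  # degenerate band keeps phase-1 labels
  outd <- refine(matrix(50, 2, 3), phase1, band)
  expect_equal(outd[1:6], phase1[1:6])
})

test_that("raising the threshold never adds foreground", {
  set.seed(31)
  img <- random_rgb(24, 24, 31)
  prev <- NULL
  for (th in c(0, 0.25, 0.5, 0.75, 1)) {
    cfg <- seg_config(pnn = pnn_spec(rep(th, 5), 1, 0, 0), keep_largest = FALSE)
    fin <- segment(img, cfg)$final_mask
    if (!is.null(prev)) expect_true(all(fin <= prev))
    prev <- fin
  }
})

test_that("phase 1 matches the brute-force pixel-loop implementation", {
  set.seed(77)
  for (rep in 1:10) {
    img <- array(runif(32 * 32 * 3, 0, 255), c(32, 32, 3))
    o <- oracle_phase1(img)
    gray <- unify_channels(img)
    expect_equal(gray, o$gray)
    gm <- global_threshold(gray)
    expect_equal(gm, o$gamma)
    m <- max_pass(min_pass(initial_mask(gray, gm), 3L), 7L)
    expect_identical(m, o$mask)
  }
})

test_that("segment finds a dark disc and honours its structural invariants", {
  s <- generate_scene(scene_spec(size = 256, boundary_irregularity = 0,
                                 noise_sigma = 0, seed = 9))
  seg <- segment(s$image)
  m <- classification_metrics(confusion_from_masks(seg$final_mask,
                                                   s$lesion_mask))
  expect_gte(m$dice, 0.95)
  expect_gte(seg$gamma, min(unify_channels(s$image)))
  expect_lte(seg$gamma, max(unify_channels(s$image)))
  # phase 2 only ever relabels band pixels
  outside <- seg$band == 0
  expect_equal(seg$final_mask[outside], seg$phase1_mask[outside])
  expect_true(all(seg$final_mask <= pmax(seg$phase1_mask, seg$band)))
  # determinism
  seg2 <- segment(s$image)
  expect_identical(seg$final_mask, seg2$final_mask)
  expect_identical(seg$gamma, seg2$gamma)
})

test_that("a constant image segments to an empty mask", {
  img <- array(120, c(32, 32, 3))
  seg <- segment(img)
  expect_equal(sum(seg$final_mask), 0)
  expect_equal(seg$gamma, 120)
})

test_that("segmentation result prints and summarises", {
  s <- generate_scene(scene_spec(size = 128, seed = 5))
  seg <- segment(s$image)
  expect_output(print(seg), "global threshold")
  sm <- summary(seg, truth = s$lesion_mask)
  expect_output(print(sm), "Dice")
  expect_true(sm$metrics$dice > 0.9)
})
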