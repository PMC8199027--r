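test_that("crop_patch handles identity, padding and linear images", {
  set.seed(1)
  img <- matrix(runif(61 * 61, 0, 255), 61, 61)
  # identity: crop_side == out_size at the integer centre reproduces pixels
  out <- crop_patch(img, c(30, 30), 61, 61)
  expect_equal(out, img, tolerance = 1e-12)
  sub <- crop_patch(img, c(20, 30), 21, 21)
  expect_equal(sub, img[(30 - 10):(30 + 10) + 1, (20 - 10):(20 + 10) + 1],
               tolerance = 1e-12)
  # fully outside: constant at the image mean
  far <- crop_patch(img, c(500, 500), 40, 40)
  expect_true(all(abs(far - mean(img)) < 1e-9))
  # a linear image stays linear under 2x decimation: constant column step
  # of 2 px and row step of 2*gradient, centred on the crop centre
  lin <- outer(0:60, 0:60, function(y, x) x + 2 * y)
  dec <- crop_patch(lin, c(29.5, 29.5), 40, 20)
  expect_equal(unique(round(diff(dec[1, ]), 9)), 2)
  expect_equal(unique(round(diff(dec[, 1]), 9)), 4)
  # centre of the patch equals the value at the crop centre
  expect_equal(mean(dec[10:11, 10:11]), lin[30, 30] + 0.5 * 3,
               tolerance = 1e-9)
  expect_error(crop_patch(img, c(NA, 3), 10, 10), "finite")
  expect_error(crop_patch(img, c(3, 3), -1, 10), "positive")
})

test_that("bicubic upsampling preserves constants, peaks and raw samples", {
  set.seed(2)
  g <- matrix(rnorm(17 * 17), 17, 17)
  expect_identical(upsample_score(g, 1), g)
  expect_error(upsample_score(g, 0), "factor")
  cst <- matrix(3.7, 9, 9)
  expect_equal(upsample_score(cst, 8), matrix(3.7, 65, 65),
               tolerance = 1e-12)
  # corner-aligned: raw samples reproduced exactly
  up <- upsample_score(g, 16)
  expect_identical(dim(up), c(257L, 257L))
  expect_equal(up[seq(1, 257, 16), seq(1, 257, 16)], g, tolerance = 1e-9)
  # single-peak grids: upsampled argmax within 1 raw cell of raw argmax
  for (s in 1:10) {
    set.seed(s)
    r <- matrix(0, 11, 11)
    pk <- sample(2:10, 2)
    r[pk[1], pk[2]] <- 1
    r <- r + matrix(rnorm(121, 0, 0.05), 11, 11)
    rawpk <- arrayInd(which.max(r), dim(r))
    uppk <- arrayInd(which.max(upsample_score(r, 8)), c(81L, 81L))
    expect_lte(max(abs((uppk - 1) / 8 - (rawpk - 1))), 1)
  }
})

test_that("cross-correlation matches the brute-force oracle", {
  set.seed(3)
  ex <- array(rnorm(3 * 3 * 2), c(3, 3, 2))
  se <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  expect_equal(cross_correlate(ex, se), bf_xcorr(ex, se),
               tolerance = 1e-9)
  # search == exemplar: 1x1 inner product
  expect_equal(cross_correlate(ex, ex)[1, 1], sum(ex * ex),
               tolerance = 1e-9)
  # plant-and-recover: exact copy on zero background peaks at its offset
  se0 <- array(0, c(10, 10, 2))
  se0[4:6, 7:9, ] <- ex
  pk <- arrayInd(which.max(cross_correlate(ex, se0)),
                 c(8L, 8L))
  expect_identical(as.integer(pk), c(4L, 7L))
  # all-zero exemplar: all-zero grid
  expect_true(all(cross_correlate(array(0, c(3, 3, 2)), se) == 0))
  expect_error(cross_correlate(se, ex), "larger")
})

test_that("select_peak applies window, penalty and the tie rule", {
  g1 <- matrix(0, 9, 9); g1[3, 7] <- 1
  w <- cosine_window(9)
  # window weight 0: plain argmax
  p <- select_peak(list(g1), w, window_weight = 0)
  expect_identical(as.integer(p$peak), c(3L, 7L))
  # window weight 1: centre regardless of scores
  p1 <- select_peak(list(g1), w, window_weight = 1)
  expect_identical(as.integer(p1$peak), c(5L, 5L))
  # scale penalty demotes non-central scales
  g2 <- matrix(0, 9, 9); g2[6, 2] <- 1
  p2 <- select_peak(list(g1, g2, g1 * 0), w, window_weight = 0,
                    scale_penalty = 0.9)
  expect_identical(p2$scale_index, 2L)
  # exact ties break to the smallest (scale, row, col)
  ga <- matrix(0, 9, 9); ga[4, 8] <- 1
  gb <- matrix(0, 9, 9); gb[2, 2] <- 1
  pt <- select_peak(list(ga, gb, gb), w, window_weight = 0,
                    scale_penalty = 1)
  expect_identical(pt$scale_index, 1L)
  expect_identical(as.integer(pt$peak), c(4L, 8L))
  gtie <- matrix(0, 9, 9); gtie[5, 3] <- 1; gtie[7, 2] <- 1
  pt2 <- select_peak(list(gtie), w, window_weight = 0)
  expect_identical(as.integer(pt2$peak), c(5L, 3L))
  expect_error(select_peak(list(), w), "no score maps")
})

test_that("displacement arithmetic is exact", {
  ctr <- c(129, 129)
  expect_equal(displacement_to_image(c(129, 129), ctr, 8, 16, 1),
               c(dx = 0, dy = 0))
  # 16 upsampled cells right of centre, stride 8, factor 16 -> dx = 8 px
  expect_equal(displacement_to_image(c(129, 145), ctr, 8, 16, 1),
               c(dx = 8, dy = 0))
  d1 <- displacement_to_image(c(121, 137), ctr, 8, 16, 1)
  d2 <- displacement_to_image(c(121, 137), ctr, 8, 16, 2)
  expect_equal(d2, d1 * 2)
})

test_that("score-map labels are balanced and geometrically correct", {
  l0 <- make_label(9, 0, 8)
  expect_identical(sum(l0$label == 1), 1L)
  expect_identical(which(l0$label == 1), 41L)  # centre cell of 9x9
  # weight balance: positive and negative classes carry equal mass
  l1 <- make_label(17, 16, 8)
  expect_equal(sum(l1$weights[l1$label > 0]),
               sum(l1$weights[l1$label < 0]), tolerance = 1e-12)
  expect_equal(sum(l1$weights), 1, tolerance = 1e-12)
  # radius covering the grid: all positive
  lfull <- make_label(5, 1000, 8)
  expect_true(all(lfull$label == 1))
  # off-centre target moves the positive disc
  loff <- make_label(17, 8, 8, center_offset_cells = c(3, -2))
  pos <- arrayInd(which(loff$label == 1), c(17L, 17L))
  expect_equal(colMeans(pos), c(9 - 2, 9 + 3), tolerance = 0.5)
})

test_that("weighted BCE matches the analytic values and a hand oracle", {
  u <- matrix(1, 3, 3)
  lab <- matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1), 3, 3)
  expect_equal(weighted_bce_loss(matrix(0, 3, 3), lab, u), log(2),
               tolerance = 1e-12)
  # separability limit: confident correct scores drive the loss to 0
  expect_lt(weighted_bce_loss(lab * 50, lab, u), 1e-12)
  # random case vs an independently coded sum
  set.seed(4)
  s <- matrix(rnorm(9), 3, 3)
  w <- matrix(runif(9), 3, 3)
  oracle <- sum(w * log(1 + exp(-lab * s))) / sum(w)
  expect_equal(weighted_bce_loss(s, lab, w), oracle, tolerance = 1e-9)
  expect_error(weighted_bce_loss(s, lab[1:2, 1:2], w), "dimensions")
})
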