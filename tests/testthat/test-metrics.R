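# independent brute-force recomputations of every metric (oracles)
oracle_delta <- function(p, g) {
  n <- nrow(p)
  out <- numeric(n)
  for (t in seq_len(n))
    out[t] <- sqrt((p[t, 1] - g[t, 1])^2 + (p[t, 2] - g[t, 2])^2)
  out
}
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- sum((a - sum(a) / n) * (b - sum(b) / n))
  den <- sqrt(sum((a - sum(a) / n)^2) * sum((b - sum(b) / n)^2))
  num / den
}
oracle_rom <- function(m, on, off) {
  rx <- ry <- rl <- 0
  for (t in (on:off) + 1L) {
    dx <- abs(m[t, 1] - m[on + 1L, 1])
    dy <- abs(m[t, 2] - m[on + 1L, 2])
    rx <- max(rx, dx); ry <- max(ry, dy)
    rl <- max(rl, sqrt(dx^2 + dy^2))
  }
  list(rom_x = rx, rom_y = ry, rom_line = rl)
}

test_that("centre error, precision, RMSE and AE match hand values", {
  p <- rbind(c(3, 4), c(0, 0), c(1, 1))
  g <- rbind(c(0, 0), c(0, 0), c(1, 1))
  d <- center_error(p, g)
  expect_equal(d, c(5, 0, 0))
  expect_length(center_error(p[1, , drop = FALSE], g[1, , drop = FALSE]),
                1L)
  expect_error(center_error(p, g[1:2, ]), "differ in length")

  dd <- c(3, 6, 12)
  expect_equal(precision_at(dd, 5), 1 / 3)
  expect_equal(precision_at(dd, Inf), 1)
  expect_equal(precision_at(c(0, 0), 0), 1)   # inclusive boundary
  expect_error(precision_at(numeric(), 5), "empty")
  expect_error(precision_at(dd, -1), ">= 0")

  cv <- precision_curve(dd, c(5, 10, 15))
  expect_equal(cv$precision, c(1 / 3, 2 / 3, 1))
  expect_equal(precision_curve(rep(7, 5), c(6, 7, 8))$precision,
               c(0, 1, 1))
  expect_equal(precision_curve(dd, c(5, 5))$precision, c(1 / 3, 1 / 3))
  expect_error(precision_curve(dd, c(10, 5)), "ascending")

  expect_equal(rmse(c(3, 4)), sqrt(12.5))
  expect_equal(ae(c(3, 4)), 3.5)
  expect_equal(rmse(rep(2.5, 7)), 2.5)
  expect_equal(ae(rep(2.5, 7)), 2.5)
  expect_error(rmse(numeric()), "empty")
})

test_that("Pearson correlation handles signs and degenerate input", {
  t1 <- cbind(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5))
  expect_equal(pearson_axis(t1, t1, "x"), 1)
  neg <- t1; neg[, 1] <- -t1[, 1]
  expect_equal(pearson_axis(neg, t1, "x"), -1)
  a <- c(1.2, 0.7, 3.4, 2.2, 5.0); b <- c(2.0, 1.1, 2.9, 2.4, 4.4)
  expect_equal(pearson_axis(cbind(x = a, y = a), cbind(x = b, y = b), "y"),
               oracle_pearson(a, b), tolerance = 1e-12)
  flat <- cbind(x = rep(1, 5), y = 1:5)
  expect_warning(r <- pearson_axis(flat, t1, "x"), "zero variance")
  expect_true(is.na(r))
})

test_that("ROM and its relative error follow the definitions", {
  tr <- rbind(c(0, 0), c(-10, 10), c(-30, 40), c(-5, 5))
  r <- rom(tr, 0, 2)
  expect_equal(r, list(rom_x = 30, rom_y = 40, rom_line = 50))
  st <- matrix(3, 5, 2)
  expect_equal(rom(st, 0, 4), list(rom_x = 0, rom_y = 0, rom_line = 0))
  expect_error(rom(tr, 2, 2), "onset < offset")
  expect_error(rom(tr, NA, 2), "missing")

  expect_equal(rom_relative_error(50, 50), 0)
  expect_equal(rom_relative_error(50, 45), 10)
  expect_equal(rom_relative_error(50, 55), 10)
  expect_warning(z <- rom_relative_error(0, 5), "zero")
  expect_true(is.na(z))
})

test_that("every metric matches its brute-force oracle on random input", {
  for (rep in 1:20) {
    set.seed(rep)
    p <- matrix(rnorm(20, 50, 10), 10, 2)
    g <- matrix(rnorm(20, 50, 10), 10, 2)
    d <- center_error(p, g)
    expect_equal(d, oracle_delta(p, g), tolerance = 1e-9)
    for (th in c(1, 5, 20))
      expect_equal(precision_at(d, th), sum(d <= th) / 10,
                   tolerance = 1e-12)
    expect_equal(rmse(d), sqrt(sum(d^2) / 10), tolerance = 1e-9)
    expect_equal(ae(d), sum(d) / 10, tolerance = 1e-9)
    expect_equal(pearson_axis(p, g, "x"), oracle_pearson(p[, 1], g[, 1]),
                 tolerance = 1e-9)
    expect_equal(rom(p, 1, 8), oracle_rom(p, 1, 8), tolerance = 1e-9)
    rg <- rom(g, 0, 9)$rom_line
    expect_equal(rom_relative_error(rg, rom(p, 0, 9)$rom_line),
                 abs(rg - rom(p, 0, 9)$rom_line) / rg * 100,
                 tolerance = 1e-9)
  }
})

test_that("metric invariants hold on random series", {
  for (rep in 1:10) {
    set.seed(100 + rep)
    p <- matrix(rnorm(24, 100, 15), 12, 2)
    g <- matrix(rnorm(24, 100, 15), 12, 2)
    d <- center_error(p, g)
    # swap symmetry
    expect_equal(d, center_error(g, p), tolerance = 1e-12)
    # rigid translation of both leaves everything unchanged
    sh <- matrix(rep(c(7, -3), each = 12), 12, 2)
    expect_equal(center_error(p + sh, g + sh), d, tolerance = 1e-9)
    expect_equal(rom(p + sh, 0, 11), rom(p, 0, 11), tolerance = 1e-9)
    # power-mean and norm inequalities
    expect_gte(rmse(d), ae(d) - 1e-12)
    r <- rom(p, 0, 11)
    expect_gte(r$rom_line, max(r$rom_x, r$rom_y) - 1e-12)
    # precision curve is non-decreasing with values in [0, 1]
    cv <- precision_curve(d, 1:30)
    expect_true(all(diff(cv$precision) >= 0))
    expect_true(all(cv$precision >= 0 & cv$precision <= 1))
  }
})

test_that("unit calibration reproduces the printed conversions", {
  cal <- unit_calibration()
  expect_equal(cal$mm_per_px * cal$px_per_mm, 1, tolerance = 1e-3)
  expect_error(unit_calibration(0.325, 4), "reciprocal")
  expect_equal(round_mm(convert_px_mm(10, cal)), 3.25)
  expect_equal(round_mm(convert_px_mm(5, cal)), 1.63)
  expect_equal(convert_px_mm(convert_px_mm(77, cal), cal, "mm_to_px"), 77,
               tolerance = 1e-9)
  # 30 x 30 px init box is ~95 mm^2
  expect_equal(convert_px_mm(30, cal)^2, 95.0625, tolerance = 1e-12)
})

test_that("evaluate_trace and aggregation compose the suite correctly", {
  set.seed(9)
  n <- 30L
  g <- cbind(x = 100 + cumsum(rnorm(n)), y = 80 + cumsum(rnorm(n)))
  p <- g + matrix(rnorm(2 * n, 0, 2), n, 2)
  ev <- list(hyoid_onset = 3L, hyoid_offset = 20L)
  r <- evaluate_trace(data.frame(frame = 0:(n - 1), x = p[, 1],
                                 y = p[, 2]), g, ev)
  expect_s3_class(r, "hyoid_eval")
  expect_equal(r$rmse, rmse(center_error(p, g)), tolerance = 1e-12)
  expect_equal(r$precision_at_10,
               precision_at(center_error(p, g), 10), tolerance = 1e-12)
  expect_equal(r$rom_gt, rom(g, 3, 20), tolerance = 1e-12)

  # aggregation: single report has SD 0 by convention
  a1 <- aggregate_reports(list(r))
  expect_true(all(a1$summary$sd[is.finite(a1$summary$sd)] == 0))
  # two reports: plain mean
  r2 <- r; r2$precision_at_10 <- 0.8; r$precision_at_10 <- 1.0
  a2 <- aggregate_reports(list(r, r2))
  expect_equal(a2$summary$mean[a2$summary$metric == "precision_at_10"],
               0.9, tolerance = 1e-12)
  # SD matches the hand-computed sample SD on three values
  r3 <- r; r3$rmse <- 1; rb <- r; rb$rmse <- 2; rc <- r; rc$rmse <- 4
  a3 <- aggregate_reports(list(r3, rb, rc))
  m <- (1 + 2 + 4) / 3
  hand_sd <- sqrt(((1 - m)^2 + (2 - m)^2 + (4 - m)^2) / 2)
  expect_equal(a3$summary$sd[a3$summary$metric == "rmse"], hand_sd,
               tolerance = 1e-12)
  # per-sequence averaging weights sequences equally, pooling does not
  short <- evaluate_trace(g[1:5, ] + 20, g[1:5, ],
                          list(hyoid_onset = 0L, hyoid_offset = 3L))
  mixed <- aggregate_reports(list(r, short))
  expect_equal(mixed$curve$precision,
               (r$precision_curve$precision +
                short$precision_curve$precision) / 2, tolerance = 1e-12)
  pooled <- aggregate_reports(list(r, short), pool_frames = TRUE)
  expect_equal(pooled$curve$precision,
               precision_curve(c(r$ce_series, short$ce_series),
                               1:50)$precision, tolerance = 1e-12)
})
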