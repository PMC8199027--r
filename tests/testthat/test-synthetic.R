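test_that("trajectory phases follow the elevation/anterior/return pattern", {
  sc <- test_scene()
  tp <- test_traj(sc, rom_x = 13, rom_y = 14, jitter = 0)
  pts <- generate_trajectory(tp)
  ev <- attr(pts, "events")

  # rest before onset, exactly at the rest point with zero jitter
  expect_true(all(pts[1:tp$onset_frame, 1] == tp$rest_point[1]))
  expect_true(all(pts[1:tp$onset_frame, 2] == tp$rest_point[2]))

  # elevation: monotone -x from the onset frame, y untouched
  el <- (tp$onset_frame:(tp$onset_frame + tp$elevation_frames)) + 1L
  expect_true(all(diff(pts[el, 1]) < 0))
  expect_true(all(pts[el, 2] == tp$rest_point[2]))
  expect_equal(unname(pts[tp$onset_frame + 1L, 1]), tp$rest_point[1])

  # anterior: monotone +y at fixed x
  an <- ((tp$onset_frame + tp$elevation_frames):ev$hyoid_offset) + 1L
  expect_true(all(diff(pts[an, 2]) > 0))
  expect_true(all(pts[an, 1] == pts[ev$hyoid_offset + 1L, 1]))

  # 13 mm at 0.325 mm/px must give exactly 40 px of x excursion
  tp2 <- trajectory_params(n_frames = 120L, rest_point = c(300, 200),
                           onset_frame = 20L, elevation_frames = 15L,
                           anterior_frames = 15L, return_frames = 25L,
                           rom_x_mm = 13, rom_y_mm = 13, jitter_sd = 0,
                           mm_per_px = 0.325)
  p2 <- generate_trajectory(tp2)
  e2 <- attr(p2, "events")
  win <- (e2$hyoid_onset:e2$hyoid_offset) + 1L
  expect_equal(max(abs(p2[win, 1] - p2[e2$hyoid_onset + 1L, 1])), 40,
               tolerance = 1e-12)

  # straight-line displacement equals sqrt(rom_x^2 + rom_y^2) px
  romx <- tp$rom_x_mm / tp$mm_per_px
  romy <- tp$rom_y_mm / tp$mm_per_px
  won <- (ev$hyoid_onset:ev$hyoid_offset) + 1L
  d <- sqrt((pts[won, 1] - pts[ev$hyoid_onset + 1L, 1])^2 +
            (pts[won, 2] - pts[ev$hyoid_onset + 1L, 2])^2)
  expect_lt(abs(max(d) - sqrt(romx^2 + romy^2)), 1)

  # return ends back at rest (zero jitter: exactly)
  expect_equal(unname(pts[ev$swallow_end + 1L, ]),
               tp$rest_point, tolerance = 1e-9)
})

test_that("zero-amplitude trajectory stays at rest and seeds reproduce", {
  sc <- test_scene()
  tp <- test_traj(sc, rom_x = 0, rom_y = 0, jitter = 0)
  pts <- generate_trajectory(tp)
  expect_true(all(pts[, 1] == tp$rest_point[1]))
  expect_true(all(pts[, 2] == tp$rest_point[2]))

  tpj <- test_traj(sc, jitter = 0.7, seed = 11L)
  expect_identical(generate_trajectory(tpj), generate_trajectory(tpj))
})

test_that("invalid phase lengths are rejected with a clear message", {
  expect_error(trajectory_params(n_frames = 50L, onset_frame = 20L,
                                 elevation_frames = 15L,
                                 anterior_frames = 15L,
                                 return_frames = 15L),
               "exceed n_frames")
  expect_error(trajectory_params(rom_x_mm = -1), "non-negative")
})

test_that("mm/px conversions round-trip to 1e-9", {
  cal <- unit_calibration(0.65, 1 / 0.65)
  x <- c(0.1, 1, 12.34, 500)
  expect_equal(convert_px_mm(convert_px_mm(x, cal, "px_to_mm"), cal,
                             "mm_to_px"), x, tolerance = 1e-9)
})

test_that("rendered frames have the stated structure", {
  sc <- test_scene(speckle_scale = 0, shadow_attenuation = 1,
                   frame_noise_sd = 0)
  p <- c(130, 90)
  img <- render_frame(p, sc)
  # noise-free, shadow-free: background is constant away from echo + line
  far <- img[180:200, 200:240]   # region below/right of everything
  expect_true(all(far == far[1, 1]))
  expect_identical(far[1, 1], as.integer(round(sc$base_intensity)))
  # echo makes the annotation point the local max (brute-force search)
  sc2 <- test_scene(frame_noise_sd = 0)
  img2 <- render_frame(p, sc2, seed = 5)
  rx <- sc2$echo_radii[1]; ry <- sc2$echo_radii[2]
  win <- img2[(p[2] - 2 * ry):(p[2] + 2 * ry) + 1,
              (p[1] - 2 * rx):(p[1] + 2 * rx) + 1]
  pk <- arrayInd(which.max(win), dim(win))
  expect_lte(abs(pk[1] - (2 * ry + 1)), ry)
  expect_lte(abs(pk[2] - (2 * rx + 1)), rx)
  # determinism: same point/seed twice is bit-identical
  expect_identical(render_frame(p, sc2, seed = 9),
                   render_frame(p, sc2, seed = 9))
  # shadow darkens the column above the echo
  sc3 <- test_scene(speckle_scale = 0, frame_noise_sd = 0,
                    shadow_attenuation = 0.3)
  img3 <- render_frame(p, sc3)
  above <- img3[10:40, p[1] + 1]
  beside <- img3[10:40, p[1] + 1 + round(2 * sc3$shadow_width)]
  expect_true(mean(above) < 0.6 * mean(beside))
  # out-of-frame point rejected
  expect_error(render_frame(c(-5, 50), sc), "outside")
  expect_error(render_frame(c(NA, 50), sc), "finite")
})

test_that("generate_sequence builds consistent sequences", {
  sc <- test_scene()
  tp <- test_traj(sc, n_frames = 40L, onset = 5L, ne = 8L, na = 8L,
                  nr = 10L)
  sq <- generate_sequence(tp, sc, seed = 3)
  expect_s3_class(sq, "usv_sequence")
  expect_length(sq$frames, tp$n_frames)
  expect_identical(nrow(sq$gt), tp$n_frames)
  ev <- sq$events
  expect_true(ev$hyoid_onset < ev$hyoid_offset)
  expect_true(ev$hyoid_offset < ev$swallow_end)
  expect_true(ev$swallow_end < tp$n_frames)
  # every gt point sits on the echo: brighter than the frame median
  for (i in seq(1, tp$n_frames, by = 7)) {
    f <- sq$frames[[i]]
    expect_gt(f[round(sq$gt[i, 2]) + 1, round(sq$gt[i, 1]) + 1],
              stats::median(f))
  }
  # gt inside frame bounds
  expect_true(all(sq$gt[, 1] >= 0 & sq$gt[, 1] <= sc$frame_width - 1))
  expect_true(all(sq$gt[, 2] >= 0 & sq$gt[, 2] <= sc$frame_height - 1))
  # zero-amplitude: constant gt
  tp0 <- test_traj(sc, n_frames = 30L, onset = 4L, ne = 5L, na = 5L,
                   nr = 6L, rom_x = 0, rom_y = 0)
  sq0 <- generate_sequence(tp0, sc, seed = 4)
  expect_true(all(sq0$gt[, 1] == sq0$gt[1, 1]))
  # determinism
  sq2 <- generate_sequence(tp, sc, seed = 3)
  expect_identical(sq$frames, sq2$frames)
  expect_identical(sq$gt, sq2$gt)
})

test_that("an off-frame trajectory is rejected", {
  sc <- test_scene()
  tp <- test_traj(sc)
  tp$rest_point <- c(25, 100)  # elevation of ~21 px exits on the left
  expect_error(generate_sequence(tp, sc, seed = 1), "outside the frame")
})

test_that("double-shadow injection corrupts exactly one frame", {
  sc <- test_scene(frame_noise_sd = 0)
  tp <- test_traj(sc, n_frames = 30L, onset = 4L, ne = 5L, na = 5L,
                  nr = 6L)
  sq <- generate_sequence(tp, sc, seed = 8)
  expect_error(inject_double_shadow(sq, 10, c(0, 0)), "nonzero")
  expect_error(inject_double_shadow(sq, 10, c(500, 0)), "outside")
  expect_error(inject_double_shadow(sq, 99, c(20, 0)), "frame_idx")

  sq2 <- inject_double_shadow(sq, 10, c(20, 0))
  # annotation unchanged
  expect_identical(sq2$gt, sq$gt)
  # all other frames bit-identical
  for (i in seq_along(sq$frames))
    if (i != 11L) expect_identical(sq2$frames[[i]], sq$frames[[i]])
  expect_false(identical(sq2$frames[[11]], sq$frames[[11]]))
  # two local maxima ~20 px apart in x near the gt row
  p <- sq$gt[11, ]
  row <- sq2$frames[[11]][round(p[2]) + 1, ]
  near <- function(x0) max(row[(x0 - 3):(x0 + 3) + 1])
  expect_gt(near(round(p[1])), 200)
  expect_gt(near(round(p[1]) + 20), 200)
  # trough between the two echo peaks
  expect_lt(min(row[(round(p[1]) + 7):(round(p[1]) + 13) + 1]),
            near(round(p[1])) - 30)
})

test_that("write_dataset emits a reproducible split", {
  sc <- test_scene()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_dataset(d1, n_train = 1L, n_val = 1L, n_test = 1L, seed = 5,
                      scene = sc, n_frames_range = c(36L, 44L))
  m2 <- write_dataset(d2, n_train = 1L, n_val = 1L, n_test = 1L, seed = 5,
                      scene = sc, n_frames_range = c(36L, 44L))
  expect_length(m1$sequences, 3L)
  expect_identical(vapply(m1$sequences, function(s) s$split, ""),
                   c("train", "val", "test"))
  # same seed: identical manifests (modulo root path) and annotation bytes
  j1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  j2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  j1$root <- j2$root <- NULL
  expect_identical(j1, j2)
  expect_identical(readLines(file.path(d1, "seq_001", "annotations.csv")),
                   readLines(file.path(d2, "seq_001", "annotations.csv")))
  expect_identical(readBin(file.path(d1, "seq_002", "frames",
                                     "frame_000000.png"), "raw", 1e6),
                   readBin(file.path(d2, "seq_002", "frames",
                                     "frame_000000.png"), "raw", 1e6))
  # parameter draws vary across sequences
  expect_gt(stats::sd(vapply(m1$sequences, function(s) s$rom_x_mm, 0)), 0)
})
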