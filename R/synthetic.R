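#' Scene parameters for synthetic ultrasound swallowing video
#'
#' Describes the imaging geometry and appearance model of one synthetic
#' B-mode recording: frame size, pixel spacing, frame rate, speckle texture,
#' and the hyoid echo/shadow complex. Anatomical sizes default to fixed
#' millimetre values and are converted to pixels through `mm_per_px`, so a
#' half-resolution scene (e.g. 360x270 at 0.65 mm/px) renders the same
#' anatomy.
#'
#' Image coordinates are 0-based pixel centres with the origin at the top
#' left, x rightward (columns) and y downward (rows). Hyoid elevation moves
#' in -x and anterior movement in +y under this convention.
#'
#' @param frame_width,frame_height frame size in pixels.
#' @param mm_per_px pixel spacing in millimetres.
#' @param fps frame rate in frames per second.
#' @param base_intensity mean background grey level (0-255 scale).
#' @param speckle_scale dimensionless multiplicative speckle amplitude in
#'   `[0, 1]`; 0 renders a noise-free constant background.
#' @param speckle_smooth_px Gaussian smoothing radius (pixels) applied to the
#'   raw Rayleigh field; controls speckle grain size.
#' @param frame_noise_sd per-frame additive Gaussian noise SD (grey levels),
#'   emulating temporal electronic noise on top of the static tissue texture.
#' @param echo_intensity peak added brightness of the hyoid echo.
#' @param echo_radii semi-axes of the bright elliptical echo in pixels,
#'   `c(x, y)`; default 4 x 2.5 mm converted through `mm_per_px`.
#' @param shadow_width width of the posterior acoustic shadow in pixels;
#'   default 11 mm.
#' @param shadow_attenuation multiplicative attenuation inside the shadow,
#'   in `[0, 1)` (1 would disable the shadow and is allowed for tests).
#' @param muscle_line_geometry 2x2 matrix of the muscle-line endpoints as
#'   pixel offsets from the hyoid point (rows = endpoints, cols = x, y);
#'   default runs from 26 mm left / 8 mm above down to the point.
#' @param muscle_intensity peak added brightness of the muscle line.
#' @param muscle_thickness Gaussian half-thickness of the line in pixels
#'   (default 1.3 mm).
#' @return an object of class `usv_scene`.
#' @export
scene_params <- function(frame_width = 720L, frame_height = 540L,
                         mm_per_px = 0.325, fps = 32,
                         base_intensity = 60,
                         speckle_scale = 0.6,
                         speckle_smooth_px = 1.2,
                         frame_noise_sd = 2,
                         echo_intensity = 160,
                         echo_radii = c(4, 2.5) / mm_per_px,
                         shadow_width = 11 / mm_per_px,
                         shadow_attenuation = 0.35,
                         muscle_line_geometry = rbind(c(-26, -8) / mm_per_px,
                                                      c(0, 0)),
                         muscle_intensity = 90,
                         muscle_thickness = 1.3 / mm_per_px) {
  frame_width <- as.integer(frame_width)
  frame_height <- as.integer(frame_height)
  if (frame_width <= 0L || frame_height <= 0L)
    stop("frame dimensions must be positive")
  if (mm_per_px <= 0) stop("mm_per_px must be positive")
  if (shadow_attenuation < 0 || shadow_attenuation >= 1) {
    if (shadow_attenuation != 1)
      stop("shadow_attenuation must lie in [0, 1) (or exactly 1 to disable)")
  }
  if (speckle_scale < 0 || speckle_scale > 1)
    stop("speckle_scale must lie in [0, 1]")
  if (any(echo_radii <= 0)) stop("echo_radii must be positive")
  structure(list(
    frame_width = frame_width, frame_height = frame_height,
    mm_per_px = mm_per_px, fps = fps,
    base_intensity = base_intensity,
    speckle_scale = speckle_scale,
    speckle_smooth_px = speckle_smooth_px,
    frame_noise_sd = frame_noise_sd,
    echo_intensity = echo_intensity,
    echo_radii = as.numeric(echo_radii),
    shadow_width = as.numeric(shadow_width),
    shadow_attenuation = shadow_attenuation,
    muscle_line_geometry = muscle_line_geometry,
    muscle_intensity = muscle_intensity,
    muscle_thickness = as.numeric(muscle_thickness)
  ), class = "usv_scene")
}

#' Trajectory parameters for one synthetic swallow
#'
#' The hyoid trajectory follows the three-phase swallowing pattern: a rest
#' period, elevation (monotone -x), anterior movement (monotone +y), and a
#' return phase back to the rest point, with cosine ease-in/ease-out within
#' each phase. Ranges of motion are given in millimetres and converted to
#' pixels through `mm_per_px`.
#'
#' @param n_frames number of frames in the sequence.
#' @param rest_point resting hyoid position `c(x, y)` in pixels (0-based).
#' @param onset_frame 0-based frame index at which elevation starts.
#' @param elevation_frames,anterior_frames,return_frames phase durations in
#'   frames.
#' @param rom_x_mm,rom_y_mm per-axis range of motion in millimetres
#'   (physiological swallows span roughly 13-17 mm).
#' @param jitter_sd SD in pixels of the smoothed positional jitter added to
#'   the whole trajectory (0 disables jitter).
#' @param mm_per_px pixel spacing used for the mm-to-px conversion; must
#'   match the scene the trajectory is rendered into.
#' @param seed optional integer seed making the jitter reproducible.
#' @return an object of class `usv_trajectory_params`.
#' @export
trajectory_params <- function(n_frames = 382L,
                              rest_point = c(396, 243),
                              onset_frame = 60L,
                              elevation_frames = 20L,
                              anterior_frames = 20L,
                              return_frames = 40L,
                              rom_x_mm = 15, rom_y_mm = 15,
                              jitter_sd = 0.5,
                              mm_per_px = 0.325,
                              seed = NULL) {
  n_frames <- as.integer(n_frames)
  onset_frame <- as.integer(onset_frame)
  elevation_frames <- as.integer(elevation_frames)
  anterior_frames <- as.integer(anterior_frames)
  return_frames <- as.integer(return_frames)
  if (n_frames < 2L) stop("n_frames must be at least 2")
  if (onset_frame < 1L) stop("onset_frame must be >= 1 (frame 0 is at rest)")
  if (min(elevation_frames, anterior_frames, return_frames) < 1L)
    stop("phase durations must be positive")
  if (onset_frame + elevation_frames + anterior_frames + return_frames >=
      n_frames)
    stop("phase lengths exceed n_frames: onset (", onset_frame,
         ") + phases (", elevation_frames + anterior_frames + return_frames,
         ") must end before frame ", n_frames - 1L)
  if (rom_x_mm < 0 || rom_y_mm < 0) stop("rom values must be non-negative")
  if (jitter_sd < 0) stop("jitter_sd must be non-negative")
  structure(list(
    n_frames = n_frames, rest_point = as.numeric(rest_point),
    onset_frame = onset_frame,
    elevation_frames = elevation_frames,
    anterior_frames = anterior_frames,
    return_frames = return_frames,
    rom_x_mm = rom_x_mm, rom_y_mm = rom_y_mm,
    jitter_sd = jitter_sd, mm_per_px = mm_per_px, seed = seed
  ), class = "usv_trajectory_params")
}

#' Event frame indices implied by trajectory parameters
#'
#' Onset is the first elevation frame; offset is the frame of maximum
#' displacement (last frame of the anterior phase); swallow end is the frame
#' at which the return phase completes. All indices are 0-based.
#'
#' @param params a [trajectory_params()] object.
#' @return list with `hyoid_onset`, `hyoid_offset`, `swallow_end`.
#' @export
trajectory_events <- function(params) {
  on <- params$onset_frame
  off <- on + params$elevation_frames + params$anterior_frames
  end <- off + params$return_frames
  list(hyoid_onset = on, hyoid_offset = off, swallow_end = end)
}

#' Generate a ground-truth hyoid trajectory
#'
#' @param params a [trajectory_params()] object.
#' @return an `n_frames` x 2 matrix of (x, y) pixel coordinates (sub-pixel),
#'   with the event indices attached as attribute `"events"`.
#' @export
generate_trajectory <- function(params) {
  stopifnot(inherits(params, "usv_trajectory_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_frames
  x0 <- params$rest_point[1]
  y0 <- params$rest_point[2]
  romx <- params$rom_x_mm / params$mm_per_px
  romy <- params$rom_y_mm / params$mm_per_px
  on <- params$onset_frame
  ne <- params$elevation_frames
  na <- params$anterior_frames
  nr <- params$return_frames
  ease <- function(q) (1 - cos(pi * q)) / 2

  # the onset frame is still at rest (ease(0)); the phase completes at
  # onset + ne, so the displacement at the offset event is exactly the
  # full range of motion
  x <- rep(x0, n)
  y <- rep(y0, n)
  f <- 0:(n - 1)
  ie <- which(f > on & f <= on + ne)
  x[ie] <- x0 - romx * ease((f[ie] - on) / ne)
  ia <- which(f > on + ne & f <= on + ne + na)
  x[ia] <- x0 - romx
  y[ia] <- y0 + romy * ease((f[ia] - on - ne) / na)
  ir <- which(f > on + ne + na & f <= on + ne + na + nr)
  q <- ease((f[ir] - on - ne - na) / nr)
  x[ir] <- x0 - romx * (1 - q)
  y[ir] <- y0 + romy * (1 - q)

  if (params$jitter_sd > 0) {
    x <- x + smoothed_jitter(n, params$jitter_sd)
    y <- y + smoothed_jitter(n, params$jitter_sd)
  }
  pts <- cbind(x = x, y = y)
  attr(pts, "events") <- trajectory_events(params)
  pts
}

# Low-pass positional jitter: iid Gaussian smoothed with a 5-tap moving
# average, rescaled so the marginal SD equals `sd`. Smoothness mimics tissue
# motion; rescaling keeps the stated amplitude.
smoothed_jitter <- function(n, sd) {
  z <- stats::rnorm(n)
  if (n >= 5L) {
    z <- as.numeric(stats::filter(z, rep(1 / 5, 5), circular = TRUE))
  }
  s <- stats::sd(z)
  if (s > 0) z <- z / s
  z * sd
}

# Static multiplicative speckle texture: iid Rayleigh field smoothed with a
# small separable Gaussian, normalised to unit mean. First-order B-mode
# approximation; the paper gives no image model.
make_speckle_field <- function(scene) {
  h <- scene$frame_height
  w <- scene$frame_width
  u <- stats::runif(h * w)
  field <- matrix(sqrt(-2 * log(u)), h, w)
  s <- scene$speckle_smooth_px
  if (s > 0) {
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    field <- apply_sep_filter(field, k)
  }
  field / mean(field)
}

# separable circular convolution along both axes
apply_sep_filter <- function(m, k) {
  m <- stats::filter(m, k, circular = TRUE)
  t(as.matrix(stats::filter(t(as.matrix(m)), k, circular = TRUE)))
}

add_echo <- function(img, point, scene) {
  h <- nrow(img); w <- ncol(img)
  rx <- scene$echo_radii[1]; ry <- scene$echo_radii[2]
  xs <- max(0, floor(point[1] - 4 * rx)):min(w - 1, ceiling(point[1] + 4 * rx))
  ys <- max(0, floor(point[2] - 4 * ry)):min(h - 1, ceiling(point[2] + 4 * ry))
  gx <- ((xs - point[1]) / rx)^2
  gy <- ((ys - point[2]) / ry)^2
  g <- scene$echo_intensity * exp(-outer(gy, gx, `+`))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + g
  img
}

# Posterior acoustic shadow: attenuating wedge from just above the echo to
# the top edge (-y, probe-at-bottom display), slightly diverging upward,
# with smooth lateral and proximal edges.
apply_shadow <- function(img, point, scene) {
  if (scene$shadow_attenuation >= 1) return(img)
  h <- nrow(img); w <- ncol(img)
  ry <- scene$echo_radii[2]
  y_top <- point[2] - ry
  if (y_top <= 0) return(img)
  ys <- 0:min(h - 1, ceiling(y_top))
  hw <- scene$shadow_width / 2 + 0.05 * (point[2] - ys)   # divergence
  edge <- 2.5                                             # px soft edge
  xs <- max(0, floor(point[1] - max(hw) - 3 * edge)):
        min(w - 1, ceiling(point[1] + max(hw) + 3 * edge))
  if (length(xs) < 1L) return(img)
  dx <- abs(xs - point[1])
  # lateral profile in [0,1]: 1 inside the wedge, 0 outside
  lat <- sapply(seq_along(ys), function(i) {
    stats::pnorm((hw[i] - dx) / edge)
  })                                                      # |xs| x |ys|
  # proximal fade-in just above the echo
  prox <- pmin(1, pmax(0, (y_top - ys) / ry))
  mask <- lat * rep(prox, each = length(dx))              # |xs| x |ys|
  att <- 1 - (1 - scene$shadow_attenuation) * t(mask)
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] * att
  img
}

add_muscle_line <- function(img, point, scene) {
  h <- nrow(img); w <- ncol(img)
  p1 <- point + scene$muscle_line_geometry[1, ]
  p2 <- point + scene$muscle_line_geometry[2, ]
  th <- scene$muscle_thickness
  m <- ceiling(3 * th)
  xs <- max(0, floor(min(p1[1], p2[1]) - m)):min(w - 1, ceiling(max(p1[1], p2[1]) + m))
  ys <- max(0, floor(min(p1[2], p2[2]) - m)):min(h - 1, ceiling(max(p1[2], p2[2]) + m))
  if (length(xs) < 1L || length(ys) < 1L) return(img)
  d <- p2 - p1
  len2 <- sum(d^2)
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  if (len2 == 0) {
    dist2 <- (X - p1[1])^2 + (Y - p1[2])^2
  } else {
    tt <- ((X - p1[1]) * d[1] + (Y - p1[2]) * d[2]) / len2
    tt <- pmin(1, pmax(0, tt))
    dist2 <- (X - (p1[1] + tt * d[1]))^2 + (Y - (p1[2] + tt * d[2]))^2
  }
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
    scene$muscle_intensity * exp(-dist2 / th^2)
  img
}

#' Render one synthetic B-mode frame
#'
#' Composes a multiplicative speckle background, a bright oblique muscle
#' line terminating at the hyoid point, a posterior acoustic shadow
#' extending from the echo to the top edge, and a bright elliptical hyoid
#' echo, then clips to the 0-255 grey range. Deterministic given `seed`.
#'
#' @param point hyoid centre `c(x, y)` in 0-based pixel coordinates.
#' @param scene a [scene_params()] object.
#' @param seed optional integer seed for the speckle and frame noise draws.
#' @param speckle_field optional precomputed speckle field (unit mean); used
#'   by [generate_sequence()] so the tissue texture is static across frames.
#' @param extra_points optional list of additional echo centres, each
#'   rendered with its own echo + shadow complex (used for the fast-motion
#'   double-shadow artifact).
#' @return integer matrix `frame_height` x `frame_width` with values 0-255.
#' @export
render_frame <- function(point, scene, seed = NULL, speckle_field = NULL,
                         extra_points = NULL) {
  stopifnot(inherits(scene, "usv_scene"))
  if (any(!is.finite(point))) stop("hyoid point must be finite")
  w <- scene$frame_width; h <- scene$frame_height
  if (point[1] < 0 || point[1] > w - 1 || point[2] < 0 || point[2] > h - 1)
    stop("hyoid point outside frame")
  if (!is.null(seed)) set.seed(seed)
  if (scene$speckle_scale > 0) {
    if (is.null(speckle_field)) speckle_field <- make_speckle_field(scene)
    img <- scene$base_intensity *
      (1 + scene$speckle_scale * (speckle_field - 1))
  } else {
    img <- matrix(scene$base_intensity, h, w)
  }
  img <- add_muscle_line(img, point, scene)
  pts <- c(list(point), extra_points)
  for (p in pts) img <- apply_shadow(img, p, scene)
  for (p in pts) img <- add_echo(img, p, scene)
  if (scene$frame_noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, scene$frame_noise_sd)
  img[img < 0] <- 0
  img[img > 255] <- 255
  storage.mode(img) <- "integer"
  img
}

#' Generate a full synthetic ultrasound swallowing sequence
#'
#' Renders every frame of a trajectory into a shared static speckle field
#' (tissue texture) with independent per-frame sensor noise, and records the
#' exact ground-truth hyoid point and swallowing event indices.
#'
#' @param traj a [trajectory_params()] object (its `mm_per_px` must match
#'   the scene).
#' @param scene a [scene_params()] object.
#' @param seed integer seed; the whole sequence is bit-reproducible given
#'   `(traj, scene, seed)`.
#' @return an object of class `usv_sequence`: list with `frames` (list of
#'   integer matrices), `gt` (n x 2 matrix of sub-pixel points), `events`,
#'   `scene`, `trajectory`, plus the internal state needed for exact
#'   re-rendering of single frames.
#' @export
generate_sequence <- function(traj, scene, seed = 1L) {
  stopifnot(inherits(traj, "usv_trajectory_params"),
            inherits(scene, "usv_scene"))
  if (abs(traj$mm_per_px - scene$mm_per_px) > 1e-12)
    stop("trajectory mm_per_px (", traj$mm_per_px,
         ") does not match scene (", scene$mm_per_px, ")")
  set.seed(seed)
  traj_seeded <- traj
  if (is.null(traj_seeded$seed))
    traj_seeded$seed <- sample.int(.Machine$integer.max - 1L, 1L)
  pts <- generate_trajectory(traj_seeded)
  events <- attr(pts, "events")
  # echo must fit inside the frame everywhere along the trajectory
  rx <- scene$echo_radii[1]; ry <- scene$echo_radii[2]
  if (min(pts[, 1]) < rx || max(pts[, 1]) > scene$frame_width - 1 - rx ||
      min(pts[, 2]) < ry || max(pts[, 2]) > scene$frame_height - 1 - ry)
    stop("trajectory brings the echo outside the frame; move rest_point or ",
         "shrink the range of motion")
  set.seed(seed + 1L)
  speckle_field <- if (scene$speckle_scale > 0) make_speckle_field(scene)
                   else NULL
  frame_seeds <- sample.int(.Machine$integer.max - 1L, traj$n_frames)
  frames <- vector("list", traj$n_frames)
  for (i in seq_len(traj$n_frames)) {
    frames[[i]] <- render_frame(pts[i, ], scene, seed = frame_seeds[i],
                                speckle_field = speckle_field)
  }
  structure(list(
    frames = frames, gt = unclass(pts)[, , drop = FALSE], events = events,
    scene = scene, trajectory = traj_seeded,
    speckle_field = speckle_field, frame_seeds = frame_seeds, seed = seed
  ), class = "usv_sequence")
}

#' @export
print.usv_sequence <- function(x, ...) {
  cat("Synthetic USV sequence:", length(x$frames), "frames of",
      x$scene$frame_width, "x", x$scene$frame_height, "px,",
      x$scene$mm_per_px, "mm/px\n")
  cat("  events: onset", x$events$hyoid_onset, "/ offset",
      x$events$hyoid_offset, "/ end", x$events$swallow_end, "\n")
  invisible(x)
}

#' Inject the fast-motion double-shadow artifact into one frame
#'
#' Re-renders the chosen frame with a second echo + shadow complex offset
#' from the true hyoid position, emulating the line-by-line acquisition
#' artifact in which a fast-moving hyoid appears at two locations in a
#' single frame. The ground-truth annotation is kept at the unshifted
#' point; all other frames are untouched.
#'
#' @param seq a `usv_sequence`.
#' @param frame_idx 0-based index of the frame to corrupt.
#' @param offset_px `c(dx, dy)` pixel offset of the phantom echo; must be
#'   nonzero and keep the phantom echo inside the frame.
#' @return the modified `usv_sequence`.
#' @export
inject_double_shadow <- function(seq, frame_idx, offset_px) {
  stopifnot(inherits(seq, "usv_sequence"))
  n <- length(seq$frames)
  if (frame_idx < 0 || frame_idx > n - 1)
    stop("frame_idx must lie in [0, ", n - 1, "]")
  offset_px <- as.numeric(offset_px)
  if (all(offset_px == 0)) stop("offset_px must be nonzero")
  p <- seq$gt[frame_idx + 1, ]
  p2 <- p + offset_px
  sc <- seq$scene
  rx <- sc$echo_radii[1]; ry <- sc$echo_radii[2]
  if (p2[1] < rx || p2[1] > sc$frame_width - 1 - rx ||
      p2[2] < ry || p2[2] > sc$frame_height - 1 - ry)
    stop("offset_px pushes the second echo outside the frame")
  seq$frames[[frame_idx + 1]] <- render_frame(
    p, sc, seed = seq$frame_seeds[frame_idx + 1],
    speckle_field = seq$speckle_field, extra_points = list(p2))
  seq
}

# Per-sequence parameter draws for a dataset: sequence lengths uniform in
# [330, 430] frames (mean ~= 382 hits the reported average sequence length),
# physiological phase durations at 32 fps, per-axis ROM uniform in the
# 13-17 mm range reported for healthy swallows, and a rest point jittered
# around a fixed anatomical position. The swallow always completes at least
# 50 frames before the end of the recording.
draw_trajectory_params <- function(scene, seed, n_frames_range = NULL) {
  set.seed(seed)
  if (is.null(n_frames_range)) n_frames_range <- c(330L, 430L)
  n <- sample(n_frames_range[1]:n_frames_range[2], 1L)
  # phase durations drawn at the full-length scale and shrunk
  # proportionally for short test sequences
  f <- min(1, n / 380)
  onset <- max(3L, as.integer(round(sample(40:90, 1L) * f)))
  ne <- max(3L, as.integer(round(sample(15:25, 1L) * f)))
  na <- max(3L, as.integer(round(sample(15:25, 1L) * f)))
  nr <- max(4L, as.integer(round(sample(30:50, 1L) * f)))
  rom_x <- stats::runif(1, 13, 17)
  rom_y <- stats::runif(1, 13, 17)
  rest <- c(0.55 * (scene$frame_width - 1) + stats::runif(1, -15, 15) *
              0.325 / scene$mm_per_px,
            0.42 * (scene$frame_height - 1) + stats::runif(1, -15, 15) *
              0.325 / scene$mm_per_px)
  trajectory_params(n_frames = n, rest_point = rest, onset_frame = onset,
                    elevation_frames = ne, anterior_frames = na,
                    return_frames = nr, rom_x_mm = rom_x, rom_y_mm = rom_y,
                    jitter_sd = 0.5, mm_per_px = scene$mm_per_px,
                    seed = seed)
}

#' Write a synthetic USV dataset to disk
#'
#' Generates `n_train + n_val + n_test` sequences with per-sequence
#' parameter draws (lengths, phase durations, ranges of motion, rest point)
#' and writes each as a PNG image-sequence directory with a ground-truth
#' annotation CSV (`frame,x,y`) and an event JSON, plus a dataset manifest
#' recording the split. Fully reproducible given `seed`.
#'
#' @param out_dir output directory (created if missing).
#' @param n_train,n_val,n_test split sizes; the default 30/10/10 mirrors the
#'   train/validation/test design of the emulated study.
#' @param seed integer master seed.
#' @param scene a [scene_params()] object shared by all sequences.
#' @param n_frames_range optional length-2 integer vector overriding the
#'   default [330, 430] sequence-length draw (used to scale tests down).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
write_dataset <- function(out_dir, n_train = 30L, n_val = 10L, n_test = 10L,
                          seed = 1L, scene = scene_params(),
                          n_frames_range = NULL) {
  n_all <- n_train + n_val + n_test
  if (n_all < 1L) stop("empty dataset requested")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  seq_seeds <- sample.int(.Machine$integer.max - 1L, n_all)
  split <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  records <- vector("list", n_all)
  for (k in seq_len(n_all)) {
    id <- sprintf("seq_%03d", k)
    traj <- draw_trajectory_params(scene, seq_seeds[k], n_frames_range)
    sq <- generate_sequence(traj, scene, seed = seq_seeds[k])
    sdir <- file.path(out_dir, id)
    write_sequence(sq, sdir)
    records[[k]] <- list(
      id = id, dir = id, frames_dir = file.path(id, "frames"),
      annotations = file.path(id, "annotations.csv"),
      events = file.path(id, "events.json"),
      split = split[k], seed = seq_seeds[k],
      n_frames = traj$n_frames,
      rom_x_mm = traj$rom_x_mm, rom_y_mm = traj$rom_y_mm)
  }
  manifest <- list(
    root = normalizePath(out_dir),
    calibration = list(mm_per_px = scene$mm_per_px,
                       px_per_mm = 1 / scene$mm_per_px),
    scene = unclass(scene),
    seed = seed,
    sequences = records)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
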