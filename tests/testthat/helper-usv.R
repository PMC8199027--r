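# Shared fixtures, generated in code. Tests run on small half-resolution
# scenes (0.65 mm/px) and a narrow backbone so the whole suite stays fast;
# geometry is identical to the full-scale defaults.

test_scene <- function(..., width = 240L, height = 200L) {
  scene_params(frame_width = width, frame_height = height,
               mm_per_px = 0.65, ...)
}

test_traj <- function(scene, n_frames = 80L, onset = 15L, ne = 12L,
                      na = 12L, nr = 20L, rom_x = 14, rom_y = 14,
                      jitter = 0, seed = NULL) {
  trajectory_params(n_frames = n_frames,
                    rest_point = c(0.55 * (scene$frame_width - 1),
                                   0.42 * (scene$frame_height - 1)),
                    onset_frame = onset, elevation_frames = ne,
                    anterior_frames = na, return_frames = nr,
                    rom_x_mm = rom_x, rom_y_mm = rom_y,
                    jitter_sd = jitter, mm_per_px = scene$mm_per_px,
                    seed = seed)
}

test_backbone <- function(seed = 42L)
  siamfc_backbone(channels = c(4L, 8L, 8L, 8L, 4L), seed = seed)

# reduced patch geometry compatible with the conv arithmetic
# (87 -> 1x1 exemplar cells, 151 -> 9x9 search cells, 9x9 score map)
test_spec <- function(...) patch_spec(exemplar_size = 87L,
                                      search_size = 151L, ...)

# brute-force valid cross-correlation, summed over channels (oracle)
bf_xcorr <- function(ex, se) {
  de <- dim(ex); ds <- dim(se)
  oh <- ds[1] - de[1] + 1L; ow <- ds[2] - de[2] + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    s <- 0
    for (c in seq_len(de[3]))
      s <- s + sum(ex[, , c] *
                   se[i:(i + de[1] - 1L), j:(j + de[2] - 1L), c])
    out[i, j] <- s
  }
  out
}

# brute-force circular cross-correlation of two matrices (oracle):
# out[dy+1, dx+1] = sum_{r,c} a[r, c] * b[r + dy, c + dx] (indices mod n)
bf_circ_corr <- function(a, b) {
  n <- nrow(a); m <- ncol(a)
  out <- matrix(0, n, m)
  for (dy in 0:(n - 1)) for (dx in 0:(m - 1)) {
    s <- 0
    for (r in 0:(n - 1)) for (c in 0:(m - 1))
      s <- s + a[r + 1, c + 1] * b[(r + dy) %% n + 1, (c + dx) %% m + 1]
    out[dy + 1, dx + 1] <- s
  }
  out
}

# integer matrix translation with edge fill (oracle for shift tests)
shift_frame <- function(m, dx, dy, fill = as.integer(round(mean(m)))) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dy; src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c]]
  storage.mode(out) <- "integer"
  out
}
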