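#' Configuration for the correlation-filter (MOSSE-style) baseline
#'
#' A single-channel discriminative correlation filter trained online in
#' the Fourier domain: circulant dense sampling makes correlation with
#' every cyclic shift of the patch an element-wise product of spectra, and
#' the filter is the regularised closed-form ratio of the desired-response
#' and patch spectra.
#'
#' @param learning_rate exponential moving-average rate in `(0, 1]` for the
#'   online numerator/denominator update (0 freezes the filter).
#' @param regularizer small positive ridge term added to the denominator.
#' @param n_aug number of augmented patches used by [init_filter()].
#' @param sigma_factor desired-response Gaussian sigma as a fraction of the
#'   target diagonal (default 1/10).
#' @param patch_factor filter window side as a multiple of the mean target
#'   side.
#' @param aug_scale_range relative scale jitter of the init augmentations.
#' @return object of class `dcf_config`.
#' @export
dcf_config <- function(learning_rate = 0.125, regularizer = 1e-4,
                       n_aug = 8L, sigma_factor = 0.1, patch_factor = 2,
                       aug_scale_range = 0.05) {
  if (learning_rate < 0 || learning_rate > 1)
    stop("learning_rate must lie in [0, 1]")
  if (regularizer <= 0) stop("regularizer must be positive")
  structure(list(learning_rate = learning_rate, regularizer = regularizer,
                 n_aug = as.integer(n_aug), sigma_factor = sigma_factor,
                 patch_factor = patch_factor,
                 aug_scale_range = aug_scale_range),
            class = "dcf_config")
}

# log-intensity + zero-mean/unit-norm + Hann taper, standard MOSSE
# preprocessing; constant patches are left at zero (with a warning
# upstream) rather than dividing by a vanishing norm
dcf_preprocess <- function(patch, window) {
  p <- log1p(patch)
  p <- p - mean(p)
  s <- stats::sd(as.numeric(p))
  if (s > 1e-12) p <- p / s
  p * window
}

# centred 2D Gaussian desired response, peak at the grid centre cell
dcf_gaussian_response <- function(n, sigma) {
  ctr <- floor(n / 2)
  d <- (0:(n - 1)) - ctr
  g <- exp(-d^2 / (2 * sigma^2))
  outer(g, g)
}

#' Initialise the correlation filter from the first frame
#'
#' Solves the regularised single-channel MOSSE filter from `n_aug` scale
#' perturbations of the initial target patch: numerator
#' `sum(G * Conj(F_k))`, denominator `sum(F_k * Conj(F_k))`.
#'
#' @param frame grayscale matrix.
#' @param box list with `center` (`c(x, y)` 0-based px) and `size`
#'   (`c(w, h)` px).
#' @param config a [dcf_config()].
#' @return object of class `dcf_state`.
#' @export
init_filter <- function(frame, box, config = dcf_config()) {
  center <- as.numeric(box$center)
  size <- if (is.null(box$size)) c(30, 30) else as.numeric(box$size)
  h <- nrow(frame); w <- ncol(frame)
  if (center[1] < 0 || center[1] > w - 1 || center[2] < 0 ||
      center[2] > h - 1)
    stop("box centre outside the frame")
  side <- 2L * as.integer(round(config$patch_factor * mean(size) / 2))
  window <- cosine_window(side)
  sigma <- config$sigma_factor * sqrt(sum(size^2))
  G <- stats::fft(dcf_gaussian_response(side, sigma))
  num <- matrix(complex(real = 0), side, side)
  den <- matrix(0, side, side)
  base <- crop_patch(frame, center, side, side)
  if (stats::sd(as.numeric(base)) < 1e-12)
    warning("constant initialisation patch; filter kept stable by the ",
            "regularizer only")
  for (k in seq_len(max(1L, config$n_aug))) {
    f <- if (k == 1L) 1 else
      stats::runif(1, 1 - config$aug_scale_range, 1 + config$aug_scale_range)
    patch <- crop_patch(frame, center, side * f, side)
    Fh <- stats::fft(dcf_preprocess(patch, window))
    num <- num + G * Conj(Fh)
    den <- den + Re(Fh * Conj(Fh))
  }
  structure(list(num = num, den = den, window = window, side = side,
                 target_size = size, center = center,
                 G = G, config = config),
            class = "dcf_state")
}

#' Correlation-filter response and centre update
#'
#' Crops the window at `center`, correlates it with the filter by an
#' element-wise spectral product, and reads the displacement off the
#' response peak with sub-pixel quadratic refinement.
#'
#' @param state a `dcf_state`.
#' @param frame grayscale matrix.
#' @param center current centre `c(x, y)`.
#' @return list with `response` (real matrix), `center` (updated),
#'   `displacement`.
#' @export
respond <- function(state, frame, center = state$center) {
  side <- state$side
  patch <- crop_patch(frame, center, side, side)
  Fh <- stats::fft(dcf_preprocess(patch, state$window))
  Hconj <- state$num / (state$den + state$config$regularizer)
  resp <- Re(stats::fft(Hconj * Fh, inverse = TRUE)) / side^2
  pk <- arrayInd(which.max(resp), dim(resp))
  ctr <- floor(side / 2)
  sub <- function(i, axis) {
    # wrapped neighbours along one axis for the quadratic fit
    get <- function(di) {
      idx <- pk
      idx[axis] <- ((idx[axis] - 1 + di) %% side) + 1
      resp[idx[1], idx[2]]
    }
    den <- get(-1) - 2 * get(0) + get(1)
    if (abs(den) < 1e-12) 0 else
      min(0.5, max(-0.5, 0.5 * (get(-1) - get(1)) / den))
  }
  drow <- ((pk[1] - 1 - ctr + side / 2) %% side) - side / 2 + sub(pk, 1)
  dcol <- ((pk[2] - 1 - ctr + side / 2) %% side) - side / 2 + sub(pk, 2)
  new_center <- c(center[1] + dcol, center[2] + drow)
  list(response = resp, center = new_center,
       displacement = c(dx = dcol, dy = drow))
}

#' Online filter update
#'
#' Exponential moving average of the numerator and denominator spectra at
#' the (new) centre, with rate `learning_rate`: 0 leaves the state
#' untouched, 1 replaces it with the single-frame solution.
#'
#' @param state a `dcf_state`.
#' @param frame grayscale matrix.
#' @param center centre `c(x, y)` at which the target was located.
#' @return updated `dcf_state`.
#' @export
update_filter <- function(state, frame, center) {
  lr <- state$config$learning_rate
  if (lr == 0) return(state)
  patch <- crop_patch(frame, center, state$side, state$side)
  Fh <- stats::fft(dcf_preprocess(patch, state$window))
  state$num <- (1 - lr) * state$num + lr * state$G * Conj(Fh)
  state$den <- (1 - lr) * state$den + lr * Re(Fh * Conj(Fh))
  state$center <- center
  state
}

#' Track one sequence with the correlation-filter baseline
#'
#' Fully online: the filter is initialised on frame 0 and, for each
#' subsequent frame, localises the target before being updated at the new
#' position. Same trace contract as [track_sequence()].
#'
#' @param frames list of grayscale matrices or accessor function with
#'   attribute `n_frames`.
#' @param init_box list with `center` and `size`.
#' @param config a [dcf_config()].
#' @param seed seed for the init augmentations.
#' @return data frame `frame` (0-based), `x`, `y`.
#' @export
dcf_track_sequence <- function(frames, init_box, config = dcf_config(),
                               seed = 1L) {
  if (is.function(frames)) {
    n <- attr(frames, "n_frames")
    get_frame <- frames
  } else {
    n <- length(frames)
    get_frame <- function(i) frames[[i]]
  }
  if (!n) stop("empty frame list")
  set.seed(seed)
  f0 <- get_frame(1)
  h <- nrow(f0); w <- ncol(f0)
  state <- init_filter(f0, init_box, config)
  center <- as.numeric(init_box$center)
  xs <- numeric(n); ys <- numeric(n)
  xs[1] <- center[1]; ys[1] <- center[2]
  if (n > 1L) for (t in 2:n) {
    fr <- get_frame(t)
    r <- respond(state, fr, center)
    center <- r$center
    center[1] <- min(max(center[1], 0), w - 1)
    center[2] <- min(max(center[2], 0), h - 1)
    state <- update_filter(state, fr, center)
    xs[t] <- center[1]; ys[t] <- center[2]
  }
  data.frame(frame = 0:(n - 1), x = xs, y = ys)
}
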