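#' Training configuration for the Siamese tracker
#'
#' Defaults follow the full offline protocol of the emulated study: 5000
#' image pairs per epoch for 50 epochs with SGD, pairs drawn from a single
#' sequence no more than 100 frames apart, centre jitter and stretch
#' augmentation, and an exponentially annealed learning rate. The printed
#' learning-rate endpoints in the source study are taken as decaying
#' magnitudes (see the methods vignette); the defaults here are
#' `1e-2 -> 1e-5`, geometric across epochs.
#'
#' @param pairs_per_epoch image pairs per epoch.
#' @param epochs training epochs.
#' @param eval_checkpoint_epoch epoch whose checkpoint is intended for
#'   evaluation (kept in the history for bookkeeping).
#' @param max_pair_gap_frames maximum frame gap within a pair.
#' @param lr_start,lr_end exponential annealing endpoints
#'   (`lr_start > lr_end > 0`).
#' @param momentum SGD momentum.
#' @param label_radius_px radius (image pixels) of the positive label disc
#'   on the score map; divided by the backbone stride to obtain cells.
#' @param jitter_px amplitude of the uniform search-centre jitter (pixels).
#' @param stretch_range relative crop-side stretch amplitude (uniform in
#'   `[1 - s, 1 + s]`).
#' @param max_grad_norm global gradient-norm clip per step; single-pair
#'   SGD occasionally meets near-degenerate pairs whose raw gradients
#'   would destabilise the momentum buffer (`Inf` disables).
#' @param box_size nominal target box, 30 x 30 pixels.
#' @param val_pairs fixed validation pairs evaluated each epoch.
#' @param seed integer seed covering sampling, augmentation and
#'   initialisation.
#' @return object of class `siamfc_train_config`.
#' @export
train_config <- function(pairs_per_epoch = 5000L, epochs = 50L,
                         eval_checkpoint_epoch = 30L,
                         max_pair_gap_frames = 100L,
                         lr_start = 1e-2, lr_end = 1e-5,
                         momentum = 0.9,
                         label_radius_px = 16,
                         jitter_px = 8, stretch_range = 0.05,
                         max_grad_norm = 5,
                         box_size = c(30, 30),
                         val_pairs = 100L, seed = 1L) {
  if (!(lr_start > lr_end && lr_end > 0))
    stop("need lr_start > lr_end > 0")
  if (max_pair_gap_frames < 0L) stop("max_pair_gap_frames must be >= 0")
  if (jitter_px < 0 || stretch_range < 0)
    stop("augmentation amplitudes must be >= 0")
  structure(list(pairs_per_epoch = as.integer(pairs_per_epoch),
                 epochs = as.integer(epochs),
                 eval_checkpoint_epoch = as.integer(eval_checkpoint_epoch),
                 max_pair_gap_frames = as.integer(max_pair_gap_frames),
                 lr_start = lr_start, lr_end = lr_end, momentum = momentum,
                 label_radius_px = label_radius_px,
                 jitter_px = jitter_px, stretch_range = stretch_range,
                 max_grad_norm = max_grad_norm,
                 box_size = as.numeric(box_size),
                 val_pairs = as.integer(val_pairs),
                 seed = as.integer(seed)),
            class = "siamfc_train_config")
}

#' Sample one training pair
#'
#' Chooses a sequence uniformly, then two frame indices at most
#' `max_gap` frames apart (both uniform given the constraint). Sequences
#' with fewer than 2 frames are skipped with a warning. Consumes the
#' current R RNG stream, so results are deterministic given the RNG state.
#'
#' @param dataset list of sequence records (each with `n_frames`, `gt`,
#'   `get_frame`), e.g. from `pair_dataset_from_manifest()`.
#' @param max_gap maximum |i - j| in frames.
#' @return list with `seq` (index), `i`, `j` (1-based frame indices).
#' @export
sample_pair <- function(dataset, max_gap = 100L) {
  if (!length(dataset)) stop("empty dataset")
  usable <- which(vapply(dataset, function(d) d$n_frames >= 2L, TRUE))
  if (length(usable) < length(dataset))
    warning("skipping ", length(dataset) - length(usable),
            " sequence(s) shorter than 2 frames")
  if (!length(usable)) stop("no usable sequences")
  k <- usable[sample.int(length(usable), 1L)]
  n <- dataset[[k]]$n_frames
  i <- sample.int(n, 1L)
  lo <- max(1L, i - max_gap)
  hi <- min(n, i + max_gap)
  j <- if (max_gap == 0L) i else (lo:hi)[sample.int(hi - lo + 1L, 1L)]
  list(seq = k, i = i, j = j)
}

#' Augment and crop one training pair
#'
#' Crops the exemplar patch centred on the ground-truth point of frame `i`
#' and the search patch around the point of frame `j`, with the search
#' centre jittered uniformly by up to `jitter_px` image pixels and both
#' crop sides stretched by independent uniform factors. The returned label
#' offset is the target's true position relative to the search-patch
#' centre, expressed in search-patch pixels, so the score-map supervision
#' knows exactly where the target ended up.
#'
#' @param exemplar_frame,search_frame grayscale matrices.
#' @param exemplar_point,search_point ground-truth points `c(x, y)`.
#' @param config a [train_config()].
#' @param spec a [patch_spec()].
#' @return list with `exemplar`, `search` (normalised patches) and
#'   `offset_px` (`c(dx, dy)` in search-patch pixels).
#' @export
augment_pair <- function(exemplar_frame, search_frame,
                         exemplar_point, search_point,
                         config, spec = patch_spec()) {
  s_z <- context_crop_side(config$box_size, spec$context_factor)
  s_x <- s_z * spec$search_size / spec$exemplar_size
  stretch <- function() {
    if (config$stretch_range == 0) 1
    else stats::runif(1, 1 - config$stretch_range, 1 + config$stretch_range)
  }
  jit <- if (config$jitter_px == 0) c(0, 0)
         else stats::runif(2, -config$jitter_px, config$jitter_px)
  side_e <- s_z * stretch()
  side_s <- s_x * stretch()
  crop_center <- search_point + jit
  ex <- crop_patch(exemplar_frame, exemplar_point, side_e,
                   spec$exemplar_size) / 255
  se <- crop_patch(search_frame, crop_center, side_s,
                   spec$search_size) / 255
  offset_px <- (search_point - crop_center) * spec$search_size / side_s
  list(exemplar = ex, search = se,
       offset_px = c(dx = unname(offset_px[1]), dy = unname(offset_px[2])),
       side_e = side_e, side_s = side_s)
}

#' Build the score-map label and balancing weights
#'
#' Cells within `label_radius_px / total_stride` cells of the target cell
#' (Euclidean, measured in image pixels) are labelled `+1`, all others
#' `-1`. Weights are uniform within each class and scaled so the positive
#' and negative classes carry equal total weight (each 1/2).
#'
#' @param grid_size score-map side (cells).
#' @param label_radius_px positive radius in image pixels.
#' @param total_stride backbone stride.
#' @param center_offset_cells target offset from the grid centre in cells
#'   (`c(dcol, drow)`, sub-cell allowed).
#' @return list with `label` (+-1 matrix) and `weights` (sums to 1).
#' @export
make_label <- function(grid_size, label_radius_px, total_stride,
                       center_offset_cells = c(0, 0)) {
  if (grid_size < 1L) stop("grid_size must be >= 1")
  ctr <- (grid_size + 1) / 2
  r0 <- ctr + center_offset_cells[2]
  c0 <- ctr + center_offset_cells[1]
  rows <- matrix(seq_len(grid_size), grid_size, grid_size)
  cols <- t(rows)
  dist_px <- total_stride * sqrt((rows - r0)^2 + (cols - c0)^2)
  label <- ifelse(dist_px <= label_radius_px, 1, -1)
  n_pos <- sum(label > 0)
  n_neg <- sum(label < 0)
  weights <- matrix(0, grid_size, grid_size)
  if (n_pos > 0L && n_neg > 0L) {
    weights[label > 0] <- 0.5 / n_pos
    weights[label < 0] <- 0.5 / n_neg
  } else {
    weights[] <- 1 / length(label)
  }
  list(label = label, weights = weights)
}

#' Weighted binary cross-entropy score-map loss
#'
#' `sum(w * log(1 + exp(-label * score))) / sum(w)`: the weighted mean of
#' the logistic loss over score-map cells.
#'
#' @param score,label,weights equally sized matrices (`label` in -1/+1).
#' @return scalar loss.
#' @export
weighted_bce_loss <- function(score, label, weights) {
  if (!all(dim(score) == dim(label)) || !all(dim(score) == dim(weights)))
    stop("score, label and weight grids must share dimensions")
  z <- -label * score
  # numerically stable log(1 + exp(z))
  l <- pmax(z, 0) + log1p(exp(-abs(z)))
  sum(weights * l) / sum(weights)
}

# gradient of the weighted BCE wrt the score grid
weighted_bce_grad <- function(score, label, weights) {
  sw <- sum(weights)
  (weights / sw) * (-label) * stats::plogis(-label * score)
}

# one SGD step on a single pair; backbone gradients from the exemplar and
# search branches are summed (shared weights)
siamfc_pair_grads <- function(backbone, pair, lab) {
  fe <- backbone_forward(backbone, pair$exemplar, keep_cache = TRUE)
  fs <- backbone_forward(backbone, pair$search, keep_cache = TRUE)
  de <- dim(fe$out)
  raw <- cpp_conv_forward(fs$out, matrix(as.numeric(fe$out), ncol = 1), 0,
                          de[1], de[2], 1L)
  xc <- raw[, , 1]
  score <- xc * backbone$score_scale + backbone$score_bias
  loss <- weighted_bce_loss(score, lab$label, lab$weights)
  gs <- weighted_bce_grad(score, lab$label, lab$weights)
  g_scale <- sum(gs * xc)
  g_bias <- sum(gs)
  gxc <- gs * backbone$score_scale
  bw <- cpp_conv_backward(fs$out, matrix(as.numeric(fe$out), ncol = 1),
                          array(gxc, c(dim(gxc), 1L)), de[1], de[2], 1L,
                          TRUE)
  g_ex_feat <- array(as.numeric(bw$gW), de)
  g_se_feat <- bw$gx
  ge <- backbone_backward(backbone, fe$cache, g_ex_feat)
  gse <- backbone_backward(backbone, fs$cache, g_se_feat)
  list(loss = loss, grads_e = ge, grads_s = gse,
       g_scale = g_scale, g_bias = g_bias)
}

siamfc_pair_loss <- function(backbone, pair, lab) {
  fe <- embed(pair$exemplar, backbone)
  fs <- embed(pair$search, backbone)
  score <- cross_correlate(fe, fs) * backbone$score_scale +
    backbone$score_bias
  weighted_bce_loss(score, lab$label, lab$weights)
}

# draw a pair from the dataset and prepare patches + label
prepare_pair <- function(dataset, config, spec, score_side, total_stride,
                         augment = TRUE) {
  p <- sample_pair(dataset, config$max_pair_gap_frames)
  d <- dataset[[p$seq]]
  cfg <- config
  if (!augment) {
    cfg$jitter_px <- 0
    cfg$stretch_range <- 0
  }
  ap <- augment_pair(d$get_frame(p$i), d$get_frame(p$j),
                     d$gt[p$i, ], d$gt[p$j, ], cfg, spec)
  lab <- make_label(score_side, config$label_radius_px, total_stride,
                    center_offset_cells = ap$offset_px / total_stride)
  list(pair = ap, lab = lab)
}

#' Train the Siamese tracker
#'
#' Offline training by SGD with momentum on augmented exemplar/search
#' pairs, minimising the weighted binary cross-entropy between the score
#' map and the displacement-aware label. The learning rate is annealed
#' geometrically from `lr_start` to `lr_end` across epochs. Per-epoch
#' training and validation losses are recorded; non-finite loss aborts
#' with a diagnostic. Fully reproducible given `config$seed`.
#'
#' @param train_dataset,val_dataset pair datasets (see
#'   `pair_dataset_from_manifest()`); `val_dataset` may be `NULL`.
#' @param config a [train_config()].
#' @param spec a [patch_spec()].
#' @param backbone optional starting [siamfc_backbone()]; a fresh one is
#'   initialised from `config$seed` when omitted.
#' @param checkpoint_dir optional directory receiving one serialised
#'   checkpoint per epoch (`epoch_###.rds`).
#' @param verbose print per-epoch progress.
#' @return list with `backbone` (trained), `history` (data frame epoch,
#'   train_loss, val_loss, lr), and `config`.
#' @export
siamfc_train <- function(train_dataset, val_dataset = NULL,
                         config = train_config(), spec = patch_spec(),
                         backbone = NULL, checkpoint_dir = NULL,
                         verbose = FALSE) {
  set.seed(config$seed)
  if (is.null(backbone))
    backbone <- siamfc_backbone(seed = config$seed)
  score_side <- backbone_out_size(backbone, spec$search_size) -
    backbone_out_size(backbone, spec$exemplar_size) + 1L
  stride <- backbone$total_stride

  # fixed validation pairs (drawn once, reused every epoch)
  val_set <- NULL
  if (!is.null(val_dataset) && config$val_pairs > 0L) {
    val_set <- lapply(seq_len(config$val_pairs), function(i)
      prepare_pair(val_dataset, config, spec, score_side, stride,
                   augment = FALSE))
  }

  conv_idx <- backbone_param_layers(backbone)
  vel <- lapply(backbone$layers[conv_idx], function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b))))
  v_scale <- 0; v_bias <- 0

  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  if (config$epochs == 0L)
    return(list(backbone = backbone, history = history, config = config))

  lrs <- if (config$epochs == 1L) config$lr_start else
    config$lr_start * (config$lr_end / config$lr_start)^
      ((seq_len(config$epochs) - 1) / (config$epochs - 1))

  for (ep in seq_len(config$epochs)) {
    lr <- lrs[ep]
    ep_loss <- 0
    for (it in seq_len(config$pairs_per_epoch)) {
      pp <- prepare_pair(train_dataset, config, spec, score_side, stride)
      st <- siamfc_pair_grads(backbone, pp$pair, pp$lab)
      if (!is.finite(st$loss))
        stop("training diverged: non-finite loss at epoch ", ep,
             ", iteration ", it)
      ep_loss <- ep_loss + st$loss
      gWs <- lapply(conv_idx, function(li)
        st$grads_e[[li]]$gW + st$grads_s[[li]]$gW)
      gbs <- lapply(conv_idx, function(li)
        st$grads_e[[li]]$gb + st$grads_s[[li]]$gb)
      gnorm <- sqrt(sum(vapply(gWs, function(g) sum(g^2), 0)) +
                    sum(vapply(gbs, function(g) sum(g^2), 0)) +
                    st$g_scale^2 + st$g_bias^2)
      clip <- if (is.finite(config$max_grad_norm) &&
                  gnorm > config$max_grad_norm)
        config$max_grad_norm / gnorm else 1
      for (k in seq_along(conv_idx)) {
        li <- conv_idx[k]
        vel[[k]]$W <- config$momentum * vel[[k]]$W - lr * clip * gWs[[k]]
        vel[[k]]$b <- config$momentum * vel[[k]]$b - lr * clip * gbs[[k]]
        backbone$layers[[li]]$W <- backbone$layers[[li]]$W + vel[[k]]$W
        backbone$layers[[li]]$b <- backbone$layers[[li]]$b + vel[[k]]$b
      }
      v_scale <- config$momentum * v_scale - lr * clip * st$g_scale
      v_bias <- config$momentum * v_bias - lr * clip * st$g_bias
      backbone$score_scale <- backbone$score_scale + v_scale
      backbone$score_bias <- backbone$score_bias + v_bias
    }
    train_loss <- ep_loss / config$pairs_per_epoch
    val_loss <- NA_real_
    if (!is.null(val_set))
      val_loss <- mean(vapply(val_set, function(v)
        siamfc_pair_loss(backbone, v$pair, v$lab), 0))
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = train_loss,
                                         val_loss = val_loss, lr = lr))
    if (!is.null(checkpoint_dir)) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(list(backbone = backbone, epoch = ep, config = config),
              file.path(checkpoint_dir, sprintf("epoch_%03d.rds", ep)))
    }
    if (verbose)
      message(sprintf("epoch %d/%d  lr %.2e  train %.4f  val %s",
                      ep, config$epochs, lr, train_loss,
                      ifelse(is.na(val_loss), "-",
                             sprintf("%.4f", val_loss))))
  }
  list(backbone = backbone, history = history, config = config)
}

#' Save / load tracker weights
#'
#' Single-file serialised checkpoint: backbone weights plus a config echo.
#'
#' @param fit result of [siamfc_train()] (or a list with `backbone`).
#' @param path file path (`.rds`).
#' @return `save_weights`: `path` invisibly; `load_weights`: the list.
#' @export
save_weights <- function(fit, path) {
  saveRDS(list(backbone = fit$backbone, config = fit$config,
               history = fit$history), path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path)
  readRDS(path)
}
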