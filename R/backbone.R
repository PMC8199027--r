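#' Padding-free AlexNet-style feature extraction backbone
#'
#' Builds the five-convolution, two-maxpool backbone used by the Siamese
#' tracker. No layer uses spatial padding, so the network is exactly
#' fully convolutional: translating the input by `total_stride` pixels
#' translates the feature grid by exactly one cell. With the classic
#' geometry (kernels 11/5/3/3/3, conv1 stride 2, two 3x3/2 maxpools) the
#' total stride is 8, a 127x127 exemplar embeds to 6x6 cells and a 255x255
#' search patch to 22x22, giving a 17x17 raw score map.
#'
#' Weights are He-initialised; the raw cross-correlation output is passed
#' through a learnable affine adjustment (`score_scale`, `score_bias`,
#' initialised 1e-3 and 0) that brings the score magnitudes into a range
#' where the logistic loss is well conditioned, standing in for the batch
#' normalisation of larger implementations.
#'
#' @param channels integer vector of the five conv output widths.
#' @param in_channels input channels (1: grayscale patches).
#' @param seed optional seed for the weight initialisation.
#' @return object of class `siamfc_backbone`.
#' @export
siamfc_backbone <- function(channels = c(8L, 16L, 16L, 16L, 8L),
                            in_channels = 1L, seed = NULL) {
  stopifnot(length(channels) == 5L)
  if (!is.null(seed)) set.seed(seed)
  kk <- c(11L, 5L, 3L, 3L, 3L)
  st <- c(2L, 1L, 1L, 1L, 1L)
  cin <- c(in_channels, channels[-5])
  layers <- list()
  for (l in 1:5) {
    fanin <- kk[l] * kk[l] * cin[l]
    W <- matrix(stats::rnorm(fanin * channels[l], 0, sqrt(2 / fanin)),
                fanin, channels[l])
    layers[[length(layers) + 1L]] <-
      list(type = "conv", k = kk[l], stride = st[l], cin = cin[l],
           cout = channels[l], W = W, b = rep(0, channels[l]))
    if (l < 5L) layers[[length(layers) + 1L]] <- list(type = "relu")
    if (l %in% 1:2) layers[[length(layers) + 1L]] <-
        list(type = "pool", size = 3L, stride = 2L)
  }
  structure(list(layers = layers, total_stride = 8L,
                 in_channels = as.integer(in_channels),
                 score_scale = 1e-3, score_bias = 0),
            class = "siamfc_backbone")
}

#' @export
print.siamfc_backbone <- function(x, ...) {
  convs <- Filter(function(l) l$type == "conv", x$layers)
  cat("Padding-free Siamese backbone: 5 conv layers, total stride",
      x$total_stride, "\n  channels:",
      paste(vapply(convs, function(l) l$cout, 0L), collapse = "-"), "\n")
  invisible(x)
}

# spatial output side for a given square input side (NA if too small)
backbone_out_size <- function(backbone, in_size) {
  s <- in_size
  for (l in backbone$layers) {
    if (l$type == "conv") s <- (s - l$k) %/% l$stride + 1L
    if (l$type == "pool") s <- (s - l$size) %/% l$stride + 1L
    if (s < 1L) return(NA_integer_)
  }
  as.integer(s)
}

as_input_cube <- function(patch, in_channels) {
  if (is.matrix(patch)) {
    x <- array(0, c(nrow(patch), ncol(patch), in_channels))
    for (c in seq_len(in_channels)) x[, , c] <- patch
    x
  } else {
    stopifnot(length(dim(patch)) == 3L, dim(patch)[3] == in_channels)
    patch
  }
}

# forward pass; with keep_cache the per-layer inputs needed by the backward
# pass are retained
backbone_forward <- function(backbone, patch, keep_cache = FALSE) {
  x <- as_input_cube(patch, backbone$in_channels)
  cache <- if (keep_cache) vector("list", length(backbone$layers)) else NULL
  for (i in seq_along(backbone$layers)) {
    l <- backbone$layers[[i]]
    if (l$type == "conv") {
      if (keep_cache) cache[[i]] <- list(x = x)
      x <- cpp_conv_forward(x, l$W, l$b, l$k, l$k, l$stride)
    } else if (l$type == "relu") {
      mask <- x > 0
      x <- x * mask
      if (keep_cache) cache[[i]] <- list(mask = mask)
    } else {
      p <- cpp_maxpool_forward(x, l$size, l$stride)
      if (keep_cache) cache[[i]] <- list(idx = p$idx,
                                         h = dim(x)[1], w = dim(x)[2])
      x <- p$out
    }
  }
  list(out = x, cache = cache)
}

# backward pass; returns gradient lists aligned with backbone$layers
# (conv entries carry gW/gb) and optionally the input gradient
backbone_backward <- function(backbone, cache, gout) {
  grads <- vector("list", length(backbone$layers))
  g <- gout
  for (i in rev(seq_along(backbone$layers))) {
    l <- backbone$layers[[i]]
    if (l$type == "conv") {
      need_gx <- i > 1L
      bw <- cpp_conv_backward(cache[[i]]$x, l$W, g, l$k, l$k, l$stride,
                              need_gx)
      grads[[i]] <- list(gW = bw$gW, gb = as.numeric(bw$gb))
      g <- bw$gx
    } else if (l$type == "relu") {
      g <- g * cache[[i]]$mask
    } else {
      g <- cpp_maxpool_backward(g, cache[[i]]$idx,
                                cache[[i]]$h, cache[[i]]$w)
    }
  }
  grads
}

#' Embed a patch with the backbone
#'
#' Runs the deterministic forward pass. Accepts any patch large enough for
#' the receptive field; the tracker itself always feeds the spec sizes
#' (127 exemplar / 255 search).
#'
#' @param patch numeric matrix (grayscale, any intensity scale; callers
#'   normalise to `[0, 1]`).
#' @param backbone a [siamfc_backbone()].
#' @return feature array (rows x cols x channels).
#' @export
embed <- function(patch, backbone) {
  stopifnot(inherits(backbone, "siamfc_backbone"))
  n <- if (is.matrix(patch)) nrow(patch) else dim(patch)[1]
  if (is.na(backbone_out_size(backbone, n)))
    stop("patch of side ", n, " is smaller than the backbone receptive field")
  backbone_forward(backbone, patch)$out
}

#' Cross-correlate exemplar and search embeddings
#'
#' Valid-mode cross-correlation of the two feature grids, summed over
#' channels: the exemplar embedding slides over the search embedding and
#' each placement contributes the inner product of the overlapping
#' features. Output side = search side - exemplar side + 1.
#'
#' @param exemplar_feat,search_feat feature arrays from [embed()], same
#'   channel count; the exemplar grid must not exceed the search grid.
#' @return numeric matrix (the raw score map).
#' @export
cross_correlate <- function(exemplar_feat, search_feat) {
  de <- dim(exemplar_feat); ds <- dim(search_feat)
  if (length(de) != 3L || length(ds) != 3L || de[3] != ds[3])
    stop("feature grids must be 3-d arrays with equal channel counts")
  if (de[1] > ds[1] || de[2] > ds[2])
    stop("exemplar grid larger than search grid")
  out <- cpp_conv_forward(search_feat,
                          matrix(as.numeric(exemplar_feat), ncol = 1), 0,
                          de[1], de[2], 1L)
  matrix(out, dim(out)[1], dim(out)[2])
}

# collect flat parameter list (for the optimiser)
backbone_param_layers <- function(backbone)
  which(vapply(backbone$layers, function(l) l$type == "conv", TRUE))
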