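# Frozen convolutional feature extraction and sequence assembly.
#
# Transfer learning in the fixed-feature-extractor setting: a convolutional
# base maps each slice image to a global-average-pooled feature vector, and
# only the classifier heads are ever trained. The four ImageNet backbones are
# described by name with their published penultimate feature dimensions;
# their pretrained weights are not bundled, so they can be instantiated with
# deterministic random weights (weights = "random"), which preserves every
# structural contract (feature dimension, frozenness, determinism). TinyTest
# is a small randomly initialised backbone intended for routine use on CPU.

BACKBONES <- list(
  EfficientNetB0 = list(feature_dim = 1280L, input_size = 224L, preprocess = "unit"),
  MobileNet      = list(feature_dim = 1024L, input_size = 224L, preprocess = "pm1"),
  NASNetMobile   = list(feature_dim = 1056L, input_size = 224L, preprocess = "pm1"),
  ResNet50V2     = list(feature_dim = 2048L, input_size = 224L, preprocess = "pm1"),
  TinyTest       = list(feature_dim = 64L,   input_size = 64L,  preprocess = "unit")
)

#' Describe a frozen feature-extractor backbone
#'
#' The four named ImageNet backbones carry their published penultimate
#' (global-average-pooled) feature dimensions: EfficientNetB0 1280, MobileNet
#' 1024, NASNetMobile 1056, ResNet50V2 2048. `TinyTest` is a compact
#' randomly initialised convolutional network (feature dimension 64, input 64
#' px) that makes the full cascade trainable on one CPU in minutes. With
#' `weights = "random"` the convolution kernels are drawn once,
#' deterministically from `(name, seed)`, and are frozen thereafter; with
#' `weights = "pretrained"` feature extraction fails with an explicit message,
#' since no pretrained weights ship with the package.
#'
#' @param name backbone name.
#' @param weights `"random"` or `"pretrained"`.
#' @param seed integer seed for the deterministic random weights.
#' @return Object of class `backbone_spec` with fields `name`, `feature_dim`,
#'   `input_size`, `preprocess_mode`, `weights`, `seed` and (for random
#'   weights) the frozen kernel list.
#' @export
backbone_spec <- function(name = c("TinyTest", "EfficientNetB0", "MobileNet",
                                   "NASNetMobile", "ResNet50V2"),
                          weights = c("random", "pretrained"),
                          seed = 1234L) {
  name <- match.arg(name)
  weights <- match.arg(weights)
  info <- BACKBONES[[name]]
  spec <- list(name = name, feature_dim = info$feature_dim,
               input_size = info$input_size, preprocess_mode = info$preprocess,
               weights = weights, seed = as.integer(seed))
  if (weights == "random")
    spec$kernels <- make_backbone_weights(name, info, as.integer(seed))
  structure(spec, class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf("Backbone %s (%s weights): input %dx%d, features %d, preprocessing '%s'\n",
              x$name, x$weights, x$input_size, x$input_size, x$feature_dim,
              x$preprocess_mode))
  invisible(x)
}

# Architecture of the random backbones: a short strided conv stack ending in a
# 1x1 convolution with feature_dim channels, followed by global average
# pooling. Layers are (kernel, stride, out_channels).
backbone_arch <- function(name, info) {
  if (name == "TinyTest")
    list(c(5L, 2L, 16L), c(3L, 2L, 32L), c(1L, 1L, info$feature_dim))
  else
    list(c(7L, 4L, 32L), c(3L, 2L, 64L), c(3L, 2L, 128L), c(1L, 1L, info$feature_dim))
}

make_backbone_weights <- function(name, info, seed) {
  arch <- backbone_arch(name, info)
  withr::with_seed(derive_seed(seed, sum(utf8ToInt(name))), {
    cin <- 3L
    lapply(arch, function(l) {
      k <- l[1]; cout <- l[3]
      fan_in <- k * k * cin
      W <- matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
      b <- stats::rnorm(cout, 0, 0.01)
      cin <<- cout
      list(W = W, b = b, kernel = k, stride = l[2])
    })
  })
}

#' Preprocess a slice image for a backbone
#'
#' Resizes the grayscale image to the backbone's input size (bilinear),
#' replicates it to three channels, and applies the backbone's declared input
#' scaling: mode `"unit"` maps `[0, 255]` to `[0, 1]`, mode `"pm1"` maps it to
#' `[-1, 1]`. Deterministic.
#'
#' @param image numeric matrix with intensities in `[0, 255]`.
#' @param spec a [backbone_spec()].
#' @return Numeric array `input_size x input_size x 3`.
#' @export
preprocess_image <- function(image, spec) {
  stopifnot(inherits(spec, "backbone_spec"), is.matrix(image))
  if (min(image) < 0 || max(image) > 255) stopf("image intensities must lie in [0, 255]")
  S <- spec$input_size
  m <- image
  if (nrow(m) != S || ncol(m) != S)
    m <- EBImage::resize(m, w = S, h = S)
  m <- switch(spec$preprocess_mode,
              unit = m / 255,
              pm1 = m / 127.5 - 1,
              stopf("unsupported preprocess mode: %s", spec$preprocess_mode))
  array(rep(as.numeric(m), 3L), dim = c(S, S, 3L))
}

# valid-padding strided convolution via im2col; x is H x W x C
conv2d <- function(x, layer) {
  k <- layer$kernel; s <- layer$stride
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  Ho <- (H - k) %/% s + 1L; Wo <- (W - k) %/% s + 1L
  cols <- matrix(0, Ho * Wo, k * k * C)
  col <- 1L
  for (c in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    cols[, col] <- as.numeric(x[seq(dy, by = s, length.out = Ho),
                                seq(dx, by = s, length.out = Wo), c])
    col <- col + 1L
  }
  out <- cols %*% layer$W
  out <- sweep(out, 2L, layer$b, "+")
  array(out, dim = c(Ho, Wo, ncol(layer$W)))
}

backbone_forward <- function(x, kernels) {
  for (l in kernels) {
    x <- conv2d(x, l)
    x <- pmax(x, 0)
  }
  apply(x, 3L, mean)  # global average pooling
}

#' Extract frozen-backbone features from slice images
#'
#' Runs each image through the backbone's convolutional base and global
#' average pooling, producing one feature vector of length
#' `spec$feature_dim` per image. The backbone is frozen: no downstream
#' training ever modifies it, so repeated calls give bit-identical features.
#'
#' @param images a list of numeric matrices, a character vector of PNG paths,
#'   or a single matrix.
#' @param spec a [backbone_spec()]. Must have been built with
#'   `weights = "random"`; pretrained weights are not distributed with the
#'   package and requesting them is an explicit error.
#' @param cache_dir optional directory: features are cached per
#'   (backbone, weights, seed, image set) and reloaded when unchanged.
#' @return Numeric matrix `n_images x feature_dim`.
#' @export
extract_features <- function(images, spec, cache_dir = NULL) {
  stopifnot(inherits(spec, "backbone_spec"))
  if (spec$weights == "pretrained")
    stopf(paste0("pretrained weights for %s are not available in this installation; ",
                 "build the spec with weights = \"random\""), spec$name)
  if (is.matrix(images)) images <- list(images)
  paths <- NULL
  if (is.character(images)) {
    paths <- images
    images <- lapply(paths, function(p) {
      px <- png::readPNG(p)
      if (length(dim(px)) == 3L) px <- px[, , 1L]
      px * 255
    })
  }
  key <- NULL
  if (!is.null(cache_dir)) {
    key <- fnv1a(c(spec$name, spec$weights, spec$seed,
                   paths %||% as.character(length(images)),
                   as.character(vapply(images, function(m) sum(m), 0))))
    cache_file <- file.path(cache_dir, sprintf("features-%s-%s.rds", spec$name, key))
    if (file.exists(cache_file)) return(readRDS(cache_file))
  }
  feats <- t(vapply(images, function(m)
    backbone_forward(preprocess_image(m, spec), spec$kernels),
    numeric(spec$feature_dim)))
  if (!is.null(key)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(feats, cache_file)
  }
  feats
}

#' Assemble a padded, masked feature sequence for one stack
#'
#' Packs per-slice feature vectors, ordered apex to base, into a fixed
#' `time_steps x feature_dim` matrix (default 25 time steps, the maximum
#' number of short-axis slices the models support). Valid steps come first
#' (post-padding); padded rows are all-zero with mask `FALSE` and a label
#' sentinel `NA`.
#'
#' @param features `n x feature_dim` matrix, slices in apex-to-base order.
#' @param ordinals integer class ordinals (0..4) for the `n` slices.
#' @param slice_index optional slice indices; when given and not already
#'   ascending, rows are sorted by it if `sort = TRUE`, otherwise an error is
#'   raised.
#' @param time_steps sequence length (default 25); `n` must not exceed it.
#' @param sort whether to sort rows by `slice_index`.
#' @return Object of class `feature_sequence`: list with `x`
#'   (`time_steps x feature_dim`), `mask` (logical), `y` (integer ordinals
#'   with `NA` at padded steps), `n`, `feature_dim`.
#' @export
build_sequences <- function(features, ordinals, slice_index = NULL,
                            time_steps = 25L, sort = TRUE) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  n <- nrow(features)
  if (n > time_steps)
    stopf("stack has %d slices but the sequence length is %d", n, time_steps)
  if (length(ordinals) != n) stopf("one label ordinal per slice is required")
  if (any(ordinals < 0L | ordinals > 4L)) stopf("ordinals must lie in 0..4")
  if (!is.null(slice_index)) {
    if (anyDuplicated(slice_index)) stopf("duplicate slice indices")
    if (is.unsorted(slice_index)) {
      if (!sort) stopf("slices are not in ascending slice_index order")
      o <- order(slice_index)
      features <- features[o, , drop = FALSE]
      ordinals <- ordinals[o]
      slice_index <- slice_index[o]
    }
  }
  D <- ncol(features)
  x <- matrix(0, time_steps, D)
  x[seq_len(n), ] <- features
  structure(list(x = x,
                 mask = seq_len(time_steps) <= n,
                 y = c(as.integer(ordinals), rep(NA_integer_, time_steps - n)),
                 n = n, feature_dim = D),
            class = "feature_sequence")
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("Feature sequence: %d valid of %d steps, %d features/step\n",
              x$n, length(x$mask), x$feature_dim))
  invisible(x)
}

# Stack a list of feature_sequence objects into batch arrays.
sequence_batch <- function(seqs) {
  stopifnot(length(seqs) > 0L, all(vapply(seqs, inherits, TRUE, "feature_sequence")))
  T_ <- length(seqs[[1]]$mask); D <- seqs[[1]]$feature_dim
  B <- length(seqs)
  x <- array(0, dim = c(B, T_, D))
  mask <- matrix(FALSE, B, T_)
  y <- matrix(NA_integer_, B, T_)
  for (i in seq_len(B)) {
    if (length(seqs[[i]]$mask) != T_ || seqs[[i]]$feature_dim != D)
      stopf("sequence %d has mismatched dimensions", i)
    x[i, , ] <- seqs[[i]]$x
    mask[i, ] <- seqs[[i]]$mask
    y[i, ] <- seqs[[i]]$y
  }
  list(x = x, mask = mask, y = y)
}
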