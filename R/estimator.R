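#' Model configuration
#'
#' Assembles the knobs of the pose estimator: backbone, input and heatmap
#' resolution, keypoint count, and whether the bidirectional temporal fusion
#' head is attached. The `"tiny"` backbone (three strided conv blocks, x8
#' downsampling, ~50k parameters) is first-class and trains in minutes on one
#' CPU; `"resnet50"` builds the full-scale bottleneck stack (x32
#' downsampling, 8x8 feature grid at 256 input) without batch normalization
#' or pretrained weights.
#'
#' @param backbone `"tiny"` or `"resnet50"`.
#' @param image_size input side in px (default 64 for tiny, 384 for resnet50;
#'   must be divisible by the backbone stride).
#' @param heatmap_size output heatmap side (default `image_size/2` for tiny,
#'   `image_size/4` for resnet50; must not exceed `image_size`).
#' @param K number of keypoints (default 21).
#' @param channels input channels (default 1 for tiny, 3 for resnet50).
#' @param use_temporal attach the five-frame Bi-ConvRNN head?
#' @param rnn_hidden hidden channels of each recurrent branch (default 8).
#' @param rnn_kernel recurrent kernel side (odd, default 3).
#' @param temperature spatial-softmax temperature used at decode time.
#' @param pretrained_backbone path to an RDS file of backbone parameters to
#'   load, or FALSE (default) for random initialization.
#' @return object of class `stc_model_config`.
#' @export
model_config <- function(backbone = c("tiny", "resnet50"),
                         image_size = NULL, heatmap_size = NULL, K = 21L,
                         channels = NULL, use_temporal = FALSE,
                         rnn_hidden = 8L, rnn_kernel = 3L, temperature = 1,
                         pretrained_backbone = FALSE) {
  backbone <- match.arg(backbone)
  ds <- switch(backbone, tiny = 8L, resnet50 = 32L)
  if (is.null(image_size)) image_size <- switch(backbone, tiny = 64L, resnet50 = 384L)
  if (is.null(channels)) channels <- switch(backbone, tiny = 1L, resnet50 = 3L)
  if (is.null(heatmap_size))
    heatmap_size <- switch(backbone, tiny = image_size %/% 2L, resnet50 = image_size %/% 4L)
  image_size <- as.integer(image_size); heatmap_size <- as.integer(heatmap_size)
  if (image_size %% ds != 0L)
    stop(sprintf("image_size must be divisible by the backbone stride (%d)", ds))
  if (heatmap_size > image_size) stop("heatmap_size must not exceed image_size")
  feat <- image_size %/% ds
  f <- heatmap_size / feat
  if (f < 1 || abs(log2(f) - round(log2(f))) > 1e-9)
    stop("heatmap_size must be the feature grid size times a power of two")
  if (K < 1L) stop("K must be at least 1")
  structure(list(backbone = backbone, image_size = image_size,
                 heatmap_size = heatmap_size, K = as.integer(K),
                 channels = as.integer(channels),
                 use_temporal = isTRUE(use_temporal),
                 rnn_hidden = as.integer(rnn_hidden),
                 rnn_kernel = as.integer(rnn_kernel),
                 temperature = temperature,
                 pretrained_backbone = pretrained_backbone),
            class = "stc_model_config")
}

tiny_backbone <- function(channels) {
  list(layer_conv(channels, 8L, 3L, stride = 2L, act = "tanh"),
       layer_conv(8L, 16L, 3L, stride = 2L, act = "tanh"),
       layer_conv(16L, 32L, 3L, stride = 2L, act = "tanh"))
}

bottleneck <- function(cin, mid, stride) {
  cout <- 4L * mid
  body <- list(layer_conv(cin, mid, 1L, stride = 1L, pad = 0L, act = "relu"),
               layer_conv(mid, mid, 3L, stride = stride, act = "relu"),
               layer_conv(mid, cout, 1L, stride = 1L, pad = 0L, act = "linear"))
  proj <- if (stride != 1L || cin != cout)
    list(layer_conv(cin, cout, 1L, stride = stride, pad = 0L, act = "linear"))
  layer_residual(body, proj)
}

resnet50_backbone <- function(channels) {
  stage <- function(cin, mid, n, stride) {
    out <- list(bottleneck(cin, mid, stride))
    for (i in seq_len(n - 1L)) out <- c(out, list(bottleneck(4L * mid, mid, 1L)))
    out
  }
  c(list(layer_conv(channels, 64L, 7L, stride = 2L, pad = 3L, act = "relu"),
         layer_maxpool(3L, 2L, 1L)),
    stage(64L, 64L, 3L, 1L),
    stage(256L, 128L, 4L, 2L),
    stage(512L, 256L, 6L, 2L),
    stage(1024L, 512L, 3L, 2L))
}

# Upsampling head: sub-pixel rearrangement first, then transposed-convolution
# stages doubling the side, the last one emitting K channels.
build_head <- function(cfeat, factor, K) {
  n <- as.integer(round(log2(factor)))
  if (n == 0L) return(list(layer_conv(cfeat, K, 3L, act = "linear")))
  layers <- list()
  c_now <- cfeat
  n_left <- n
  if (n >= 2L && cfeat %% 4L == 0L) {
    layers <- c(layers, list(layer_ps(2L)))
    c_now <- cfeat %/% 4L
    n_left <- n - 1L
  }
  while (n_left > 1L) {
    c_next <- max(c_now %/% 4L, 8L)
    layers <- c(layers, list(layer_convT(c_now, c_next, 4L, 2L, 1L, act = "tanh")))
    c_now <- c_next
    n_left <- n_left - 1L
  }
  c(layers, list(layer_convT(c_now, K, 4L, 2L, 1L, act = "linear")))
}

#' Build a pose estimation model
#'
#' Constructs backbone + upsampling head (+ optional temporal head) with
#' Glorot-initialized weights drawn from the current RNG stream, so
#' `set.seed()` before building gives reproducible models.
#'
#' @param cfg a [model_config()].
#' @param scheme a [keypoint_scheme()] with `K` matching `cfg$K`.
#' @return object of class `stc_model`.
#' @export
build_model <- function(cfg, scheme = carp_scheme()) {
  stopifnot(inherits(cfg, "stc_model_config"))
  if (scheme$K != cfg$K) stop("cfg$K must match the keypoint scheme")
  backbone <- switch(cfg$backbone,
                     tiny = tiny_backbone(cfg$channels),
                     resnet50 = resnet50_backbone(cfg$channels))
  cfeat <- switch(cfg$backbone, tiny = 32L, resnet50 = 2048L)
  feat <- cfg$image_size %/% switch(cfg$backbone, tiny = 8L, resnet50 = 32L)
  head <- build_head(cfeat, cfg$heatmap_size / feat, cfg$K)
  if (!isFALSE(cfg$pretrained_backbone)) {
    init <- readRDS(cfg$pretrained_backbone)
    backbone <- layers_set_params(backbone, init)
  }
  temporal <- if (cfg$use_temporal)
    temporal_head_new(cin = 1L, hidden = cfg$rnn_hidden, k = cfg$rnn_kernel)
  structure(list(cfg = cfg, scheme = scheme, backbone = backbone, head = head,
                 temporal = temporal,
                 norm = list(mean = 0.5, sd = 0.25),
                 subspace = NULL, eps_t = NULL),
            class = "stc_model")
}

#' @export
print.stc_model <- function(x, ...) {
  cat(sprintf("<stc_model> %s backbone, %dpx -> %dpx heatmaps, K = %d%s\n",
              x$cfg$backbone, x$cfg$image_size, x$cfg$heatmap_size, x$cfg$K,
              if (x$cfg$use_temporal) ", temporal head" else ""))
  invisible(x)
}

check_image <- function(model, image) {
  img <- as_cube(image)
  d <- dim(img)
  if (d[1L] != model$cfg$image_size || d[2L] != model$cfg$image_size ||
      d[3L] != model$cfg$channels)
    stop(sprintf("image must be %d x %d x %d", model$cfg$image_size,
                 model$cfg$image_size, model$cfg$channels))
  img
}

# raw K-channel heatmaps for one frame, with caches for backprop
frame_fwd <- function(model, image) {
  x <- (check_image(model, image) - model$norm$mean) / model$norm$sd
  fb <- net_forward(model$backbone, x)
  fh <- net_forward(model$head, fb$y)
  list(raw = fh$y, cache_backbone = fb$caches, cache_head = fh$caches)
}

frame_bwd <- function(model, fw, graw) {
  rh <- net_backward(model$head, fw$cache_head, graw)
  rb <- net_backward(model$backbone, fw$cache_backbone, rh$gx)
  list(backbone = rb$grads, head = rh$grads)
}

# ---- differentiable decoding ----------------------------------------------
# raw (H, W, K) -> per-keypoint soft-argmax coordinates on the heatmap grid.

decode_coords <- function(raw, temperature = 1) {
  K <- dim(raw)[3L]
  H <- dim(raw)[1L]; W <- dim(raw)[2L]
  probs <- array(0, dim(raw))
  xy <- matrix(0, K, 2L)
  conf <- numeric(K)
  for (k in seq_len(K)) {
    p <- spatial_softmax(raw[, , k], temperature)
    probs[, , k] <- p
    xy[k, ] <- c(sum(colSums(p) * (seq_len(W) - 1)),
                 sum(rowSums(p) * (seq_len(H) - 1)))
    conf[k] <- max(p)
  }
  list(xy = xy, probs = probs, conf = conf)
}

decode_coords_bwd <- function(dec, gxy, temperature = 1) {
  d <- dim(dec$probs)
  H <- d[1L]; W <- d[2L]; K <- d[3L]
  Xg <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  Yg <- matrix(seq_len(H) - 1, H, W)
  graw <- array(0, d)
  for (k in seq_len(K)) {
    p <- dec$probs[, , k]
    s <- (Xg - dec$xy[k, 1L]) * gxy[k, 1L] + (Yg - dec$xy[k, 2L]) * gxy[k, 2L]
    graw[, , k] <- p * s / temperature
  }
  graw
}

#' Predict a pose for a single frame
#'
#' Runs backbone and head, applies spatial softmax and soft-argmax per
#' keypoint, and rescales coordinates from the heatmap grid to image pixels
#' (factor `image_size / heatmap_size`). Deterministic: identical weights and
#' image give bit-identical poses.
#'
#' @param model a built [build_model()] (or loaded checkpoint).
#' @param image `image_size x image_size` matrix (grayscale) or array with
#'   `channels` slices, values in `[0, 1]`.
#' @return a [pose()] with per-keypoint confidences.
#' @export
predict_frame <- function(model, image) {
  stopifnot(inherits(model, "stc_model"))
  fw <- frame_fwd(model, image)
  dec <- decode_coords(fw$raw, model$cfg$temperature)
  scale <- model$cfg$image_size / model$cfg$heatmap_size
  pose(dec$xy * scale, model$scheme, confidence = dec$conf)
}

# temporal decode for the window centered at `center` given precomputed raw
# heatmap list; returns pose in image coordinates.
temporal_predict_center <- function(model, raws, center) {
  K <- model$cfg$K
  H <- dim(raws[[1L]])[1L]; W <- dim(raws[[1L]])[2L]
  frames <- lapply((center - 2L):(center + 2L), function(t) raws[[t]])
  r <- bi_fuse_fwd(frames, model$temporal, K)
  dec <- decode_coords(r$fused, model$cfg$temperature)
  scale <- model$cfg$image_size / model$cfg$heatmap_size
  pose(dec$xy * scale, model$scheme, confidence = dec$conf)
}

#' Predict a trajectory over a clip
#'
#' A base (single-frame) model maps every frame independently. A temporal
#' model slides its five-frame window along the clip and predicts the center
#' frame of each window, yielding poses for frames `3 .. T-2` (1-based); the
#' two edge frames at each end get no temporal prediction unless
#' `edge_fallback = TRUE`, in which case the base head fills them in.
#'
#' @param model an `stc_model`.
#' @param frames list of images (see [predict_frame()]).
#' @param edge_fallback fill edge frames with single-frame predictions?
#' @return a [trajectory()] with 0-based frame indices into `frames`.
#' @export
predict_clip <- function(model, frames, edge_fallback = FALSE) {
  stopifnot(inherits(model, "stc_model"))
  Tn <- length(frames)
  if (!model$cfg$use_temporal || is.null(model$temporal)) {
    if (Tn < 1L) stop("need at least one frame")
    poses <- lapply(frames, function(f) predict_frame(model, f))
    return(trajectory(poses, seq_len(Tn) - 1L))
  }
  if (Tn < 5L) stop("temporal prediction needs at least five frames")
  raws <- lapply(frames, function(f) frame_fwd(model, f)$raw)
  centers <- 3L:(Tn - 2L)
  poses <- lapply(centers, function(t) temporal_predict_center(model, raws, t))
  idx <- centers - 1L
  if (edge_fallback) {
    edge <- c(1L, 2L, Tn - 1L, Tn)
    poses <- c(lapply(edge[1:2], function(t) predict_frame(model, frames[[t]])),
               poses,
               lapply(edge[3:4], function(t) predict_frame(model, frames[[t]])))
    idx <- c(edge[1:2] - 1L, idx, edge[3:4] - 1L)
    o <- order(idx)
    poses <- poses[o]; idx <- idx[o]
  }
  trajectory(poses, idx)
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding weights, configuration, keypoint scheme,
#' normalization statistics and (when fitted) the pose subspace and temporal
#' thresholds.
#'
#' @param model an `stc_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the model; `save_checkpoint` the path,
#'   invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "stc_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "stc_model")) stop("not an stc_model checkpoint")
  model
}

# parameter tree of the whole model (backbone / head / temporal)
model_get_params <- function(model) {
  p <- list(backbone = layers_get_params(model$backbone),
            head = layers_get_params(model$head))
  if (!is.null(model$temporal))
    p$temporal <- list(fwd = model$temporal$fwd[c("wx", "wh", "b")],
                       bwd = model$temporal$bwd[c("wx", "wh", "b")],
                       proj = model$temporal$proj)
  p
}

model_set_params <- function(model, p) {
  model$backbone <- layers_set_params(model$backbone, p$backbone)
  model$head <- layers_set_params(model$head, p$head)
  if (!is.null(model$temporal)) {
    model$temporal$fwd[c("wx", "wh", "b")] <- p$temporal$fwd
    model$temporal$bwd[c("wx", "wh", "b")] <- p$temporal$bwd
    model$temporal$proj <- p$temporal$proj
  }
  model
}
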