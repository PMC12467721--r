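# Bidirectional convolutional-recurrent fusion head. Five consecutive
# per-keypoint heatmaps are combined into a refined center-frame heatmap: a
# forward branch runs frames 1->3, a backward branch 5->3, their hidden states
# at the center frame are averaged pixel-wise and projected to one channel by
# a shared 1x1 convolution. Parameters are shared across keypoints (the
# keypoint dimension is treated as a batch); the two branches carry
# independent parameters. Steps beyond the center frame cannot influence the
# center state, so each branch is unrolled only up to frame 3.

#' Preliminary sub-pixel upsampling
#'
#' Pixel rearrangement (sub-pixel convolution without the convolution): a
#' `(H, W, C*scale^2)` feature stack becomes `(H*scale, W*scale, C)`. Pure
#' value rearrangement -- the multiset of values (and their sum) is conserved
#' exactly; `scale = 1` is the identity.
#'
#' @param x 3D array `(H, W, C)` (a 2D matrix is treated as one channel).
#' @param scale integer upsampling factor; `C` must be divisible by `scale^2`.
#' @return 3D array `(H*scale, W*scale, C/scale^2)`.
#' @export
upsample_prelim <- function(x, scale) {
  x <- as_cube(x)
  scale <- as.integer(scale)
  if (scale < 1L) stop("scale must be a positive integer")
  if (scale == 1L) return(x)
  C <- dim(x)[3L]
  if (C %% (scale^2) != 0L)
    stop(sprintf("channel count %d not divisible by scale^2 = %d", C, scale^2))
  nn_pixel_shuffle(x, scale, C)
}

#' Convolutional recurrent cell parameters
#'
#' One branch of the bidirectional head: `h' = act(ConvX(x) + ConvH(h) + b)`
#' with square odd-sided kernels and spatial shape preserved by padding.
#' Weights are Glorot-initialized from the current RNG stream.
#'
#' @param cin input channels per keypoint (1 for raw heatmaps).
#' @param hidden hidden channels (default 8).
#' @param k kernel side (odd, default 3).
#' @param activation `"tanh"` (default) or `"linear"`.
#' @return object of class `convrnn_params`.
#' @export
convrnn_params <- function(cin = 1L, hidden = 8L, k = 3L, activation = "tanh") {
  if (k %% 2L != 1L) stop("kernel side must be odd")
  structure(list(
    cin = cin, hidden = hidden, k = k, act = activation,
    wx = glorot_mat(hidden, cin * k * k, cin * k * k, hidden * k * k),
    wh = glorot_mat(hidden, hidden * k * k, hidden * k * k, hidden * k * k),
    b = numeric(hidden)), class = "convrnn_params")
}

#' Degenerate pass-through cell
#'
#' A 1-channel linear cell with identity input convolution and zero hidden
#' convolution: each step simply emits its input frame, so the fused center
#' map equals the raw center-frame heatmap and temporal decoding reduces to
#' single-frame decoding.
#'
#' @return a `convrnn_params` in the identity configuration.
#' @export
convrnn_identity_params <- function() {
  p <- convrnn_params(cin = 1L, hidden = 1L, k = 1L, activation = "linear")
  p$wx <- matrix(1, 1L, 1L)
  p$wh <- matrix(0, 1L, 1L)
  p$b <- 0
  p
}

#' One recurrent step
#'
#' @param hidden previous hidden state `(H, W, hidden)`, or `NULL` for the
#'   initial frame (zero state).
#' @param x current frame input `(H, W, cin)`.
#' @param params a [convrnn_params()].
#' @return new hidden state `(H, W, hidden)`.
#' @export
convrnn_step <- function(hidden, x, params) {
  stopifnot(inherits(params, "convrnn_params"))
  x <- as_cube(x)
  if (dim(x)[3L] != params$cin) stop("frame input channel mismatch")
  pad <- (params$k - 1L) %/% 2L
  pre <- nn_conv_fwd(x, params$wx, params$b, params$cin, params$k, 1L, pad)
  if (!is.null(hidden)) {
    hidden <- as_cube(hidden)
    if (!all(dim(hidden) == c(dim(x)[1:2], params$hidden)))
      stop("hidden state shape mismatch")
    pre <- pre + nn_conv_fwd(hidden, params$wh, numeric(params$hidden),
                             params$hidden, params$k, 1L, pad)
  }
  act_apply(pre, params$act)
}

#' Construct a bidirectional temporal head
#'
#' Independent forward and backward [convrnn_params()] plus the shared 1x1
#' projection that maps the averaged center hidden state to one channel.
#'
#' @inheritParams convrnn_params
#' @param identity if TRUE build the degenerate pass-through configuration
#'   (see [convrnn_identity_params()]), with unit projection.
#' @return object of class `stc_temporal_head`.
#' @export
temporal_head_new <- function(cin = 1L, hidden = 8L, k = 3L, identity = FALSE) {
  if (identity) {
    head <- list(fwd = convrnn_identity_params(), bwd = convrnn_identity_params(),
                 proj = list(W = matrix(1, 1L, 1L), b = 0))
  } else {
    head <- list(fwd = convrnn_params(cin, hidden, k),
                 bwd = convrnn_params(cin, hidden, k),
                 proj = list(W = glorot_mat(1L, hidden, hidden, 1L), b = 0))
  }
  structure(head, class = "stc_temporal_head")
}

# ---- batched forward/backward over keypoints ------------------------------
# frames: list of 5 cubes (H, W, K*cin); returns fused (H, W, K) plus caches.

branch_fwd <- function(frames_in_order, params, K) {
  pad <- (params$k - 1L) %/% 2L
  h <- NULL
  steps <- vector("list", length(frames_in_order))
  for (s in seq_along(frames_in_order)) {
    x <- frames_in_order[[s]]
    pre <- nn_conv_fwd(x, params$wx, params$b, params$cin, params$k, 1L, pad)
    if (!is.null(h))
      pre <- pre + nn_conv_fwd(h, params$wh, numeric(params$hidden),
                               params$hidden, params$k, 1L, pad)
    hn <- act_apply(pre, params$act)
    steps[[s]] <- list(x = x, hprev = h, h = hn)
    h <- hn
  }
  list(h = h, steps = steps)
}

branch_bwd <- function(steps, params, gh) {
  pad <- (params$k - 1L) %/% 2L
  gwx <- params$wx * 0; gwh <- params$wh * 0; gb <- params$b * 0
  gx <- vector("list", length(steps))
  for (s in rev(seq_along(steps))) {
    st <- steps[[s]]
    gpre <- gh * act_grad_from_y(st$h, params$act)
    rx <- nn_conv_bwd(st$x, params$wx, gpre, params$cin, params$k, 1L, pad)
    gx[[s]] <- rx$gx
    gwx <- gwx + rx$gW
    gb <- gb + as.numeric(rx$gb)
    if (!is.null(st$hprev)) {
      rh <- nn_conv_bwd(st$hprev, params$wh, gpre, params$hidden, params$k, 1L, pad)
      gwh <- gwh + rh$gW
      gh <- rh$gx
    }
  }
  list(gx = gx, grads = list(wx = gwx, wh = gwh, b = gb))
}

bi_fuse_fwd <- function(frames, head, K) {
  hid <- head$fwd$hidden
  f <- branch_fwd(frames[1:3], head$fwd, K)
  b <- branch_fwd(frames[5:3], head$bwd, K)
  center <- (f$h + b$h) / 2
  fused <- nn_conv_fwd(center, head$proj$W, head$proj$b, hid, 1L, 1L, 0L)
  list(fused = fused, cache = list(f = f, b = b, center = center))
}

bi_fuse_bwd <- function(cache, head, gfused) {
  hid <- head$fwd$hidden
  rp <- nn_conv_bwd(cache$center, head$proj$W, as_cube(gfused), hid, 1L, 1L, 0L)
  gcenter <- rp$gx / 2
  rf <- branch_bwd(cache$f$steps, head$fwd, gcenter)
  rb <- branch_bwd(cache$b$steps, head$bwd, gcenter)
  gframes <- vector("list", 5L)
  for (s in 1:3) gframes[[s]] <- rf$gx[[s]]
  for (s in 1:3) {                       # backward branch walked frames 5,4,3
    fr <- 6L - s
    g <- rb$gx[[s]]
    gframes[[fr]] <- if (is.null(gframes[[fr]])) g else gframes[[fr]] + g
  }
  list(gframes = gframes,
       grads = list(fwd = rf$grads, bwd = rb$grads,
                    proj = list(W = rp$gW, b = as.numeric(rp$gb))))
}

#' Fuse a five-frame heatmap stack at the center frame
#'
#' Runs the forward branch over frames 1..5 and the backward branch over
#' frames 5..1, takes each branch's hidden state at the center (3rd) frame,
#' averages them pixel-wise and projects to a single-channel map. Reversing
#' the temporal order of the stack while swapping the two branch parameter
#' sets leaves the output unchanged.
#'
#' @param stack five per-keypoint heatmaps: an `(H, W, 5)` array or a list of
#'   five `H x W` matrices, in strictly increasing temporal order.
#' @param head a [temporal_head_new()] (or a list with elements `fwd`, `bwd`,
#'   `proj`).
#' @return the fused center `H x W` map.
#' @export
bi_fuse <- function(stack, head) {
  if (is.list(stack) && !is.array(stack))
    stack <- array(unlist(stack), c(dim(stack[[1L]]), length(stack)))
  if (dim(stack)[3L] != 5L) stop("bi_fuse needs exactly five frames")
  frames <- lapply(1:5, function(t) as_cube(stack[, , t]))
  r <- bi_fuse_fwd(frames, head, K = 1L)
  r$fused[, , 1L]
}

#' Decode a center-frame pose from per-keypoint five-frame stacks
#'
#' Applies [bi_fuse()] per keypoint (parameters shared across keypoints),
#' then spatial softmax and soft-argmax on each fused map. Coordinates are in
#' the heatmap pixel grid; confidences are the peak probabilities.
#'
#' @param stacks `(H, W, 5, K)` array, or list of K `(H, W, 5)` stacks.
#' @param head a [temporal_head_new()].
#' @param scheme the [keypoint_scheme()] naming the K stacks.
#' @param temperature softmax temperature (default 1).
#' @return a [pose()] for the center frame.
#' @export
temporal_decode <- function(stacks, head, scheme, temperature = 1) {
  if (is.list(stacks) && !is.array(stacks))
    stacks <- array(unlist(stacks), c(dim(stacks[[1L]])[1:2], 5L, length(stacks)))
  K <- dim(stacks)[4L]
  if (K != scheme$K) stop("number of stacks must match the scheme")
  H <- dim(stacks)[1L]; W <- dim(stacks)[2L]
  frames <- lapply(1:5, function(t)
    array(stacks[, , t, ], c(H, W, K)))      # keypoints as batch, cin = 1
  fused <- bi_fuse_fwd(frames, head, K)$fused
  decode_maps_to_pose(fused, scheme, temperature)
}

# shared decoding: raw K-channel maps -> pose (heatmap grid coordinates)
decode_maps_to_pose <- function(raw, scheme, temperature = 1) {
  K <- dim(raw)[3L]
  xy <- matrix(0, K, 2L)
  conf <- numeric(K)
  for (k in seq_len(K)) {
    p <- spatial_softmax(raw[, , k], temperature)
    xy[k, ] <- soft_argmax(p)
    conf[k] <- max(p)
  }
  pose(xy, scheme, confidence = conf)
}
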