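#' Render a Gaussian target map
#'
#' Isotropic Gaussian evaluated at pixel centres and renormalized to sum 1,
#' so targets are probability maps and the soft-argmax of a target recovers
#' its centre (away from borders). Border-truncated kernels are renormalized,
#' keeping the unit-sum invariant near edges.
#'
#' @param center numeric `(x, y)` in pixels (x = column, y = row, 0-based).
#' @param shape integer `(H, W)`.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return H x W matrix summing to 1.
#' @export
render_gaussian <- function(center, shape, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("sigma must be a positive scalar")
  H <- as.integer(shape[1L]); W <- as.integer(shape[2L])
  dx2 <- ((seq_len(W) - 1) - center[1L])^2
  dy2 <- ((seq_len(H) - 1) - center[2L])^2
  m <- exp(-(outer(dy2, dx2, "+")) / (2 * sigma^2))
  m / sum(m)
}

#' Spatial softmax
#'
#' Normalizes a raw score map into a probability distribution over all H*W
#' cells. Invariant to adding a constant to every cell; lowering the
#' temperature sharpens the map toward its hard argmax.
#'
#' @param m H x W matrix of finite scores.
#' @param temperature positive scalar, default 1.
#' @return H x W matrix of non-negative values summing to 1.
#' @export
spatial_softmax <- function(m, temperature = 1) {
  if (!is.finite(temperature) || temperature <= 0) stop("temperature must be positive")
  mx <- max(m)
  if (!is.finite(mx)) stop("spatial_softmax: degenerate input (no finite maximum)")
  e <- exp((m - mx) / temperature)
  e / sum(e)
}

is_normalized_map <- function(m, tol = 1e-5) {
  all(m >= -tol) && abs(sum(m) - 1) <= tol
}

#' Soft argmax of a normalized map
#'
#' Probability-weighted expectation of pixel-centre coordinates,
#' `(sum p*x, sum p*y)`, giving a differentiable sub-pixel location.
#'
#' @param m normalized H x W probability map (see [spatial_softmax()]).
#' @return numeric `(x, y)` in 0-based pixel coordinates.
#' @export
soft_argmax <- function(m) {
  if (!is_normalized_map(m))
    stop("soft_argmax expects a normalized probability map (non-negative, sum 1)")
  H <- nrow(m); W <- ncol(m)
  c(x = sum(colSums(m) * (seq_len(W) - 1)),
    y = sum(rowSums(m) * (seq_len(H) - 1)))
}

#' Peak confidence of a normalized map
#'
#' The maximum cell probability, used as the per-keypoint confidence score of
#' a prediction (a sharply localized map has peak near 1, a diffuse one near
#' 1/(H*W)).
#'
#' @param m normalized probability map.
#' @return scalar in `[0, 1]`.
#' @export
peak_confidence <- function(m) {
  if (!is_normalized_map(m))
    stop("peak_confidence expects a normalized probability map")
  max(m)
}

#' Stack per-keypoint heatmaps
#'
#' @param maps H x W x K array (or list of K matrices).
#' @param normalized logical; TRUE when each map is a probability distribution.
#' @return H x W x K array with attribute `normalized`.
#' @export
heatmap_stack <- function(maps, normalized = FALSE) {
  if (is.list(maps)) maps <- array(unlist(maps), dim = c(dim(maps[[1L]]), length(maps)))
  if (normalized) {
    ok <- vapply(seq_len(dim(maps)[3L]), function(k) is_normalized_map(maps[, , k]), TRUE)
    if (!all(ok)) stop("maps flagged normalized must each be non-negative and sum to 1")
  }
  structure(maps, normalized = normalized)
}
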