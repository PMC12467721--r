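#' Fit the plausible-pose subspace
#'
#' Principal component analysis of flattened training poses. Poses move in a
#' 2K-dimensional coordinate space but real body configurations occupy a much
#' lower-dimensional manifold; the span of the leading components is used as
#' the "plausible" subspace and predictions are penalized by their distance to
#' it ([pose_loss()]). Invalid vectors (any keypoint invisible) are dropped
#' before fitting; the number of remaining training vectors must be at least
#' 2K, otherwise the covariance cannot be modeled.
#'
#' The eigendecomposition is the deterministic full decomposition of the
#' centred covariance (no randomized solver), with the sign of each component
#' fixed by forcing its largest-magnitude entry positive, so the retained
#' rank R and component matrix P are reproducible. R is the smallest count
#' whose cumulative explained variance reaches `variance_target`;
#' zero-variance degenerate data yields R = 0 and reconstruction collapses
#' to the mean pose.
#'
#' @param vectors list of `pose_vector`s, or an N x 2K numeric matrix.
#' @param variance_target fraction of variance to retain (default 0.99).
#' @param scheme optional [keypoint_scheme()] stored for serialization.
#' @return object of class `pose_subspace`: `mu` (length 2K), `components`
#'   (2K x R, orthonormal columns), `explained_ratio` (all 2K ratios),
#'   `R`, `variance_target`, `eps_pose` (NA until calibrated), `K`.
#' @export
fit_subspace <- function(vectors, variance_target = 0.99, scheme = NULL) {
  X <- as_pose_matrix(vectors)
  if (!is.finite(variance_target) || variance_target <= 0 || variance_target > 1)
    stop("variance_target must be in (0, 1]")
  if (any(!is.finite(X))) stop("pose vectors contain non-finite values")
  n <- nrow(X); d <- ncol(X); K <- d %/% 2L
  if (n < d)
    stop(sprintf("need at least 2K = %d valid training poses, got %d", d, n))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  S <- crossprod(Xc) / (n - 1L)
  eg <- eigen(S, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total <- sum(ev)
  if (total <= d * 1e-12) {          # degenerate: no variance at all
    ratio <- rep(0, d); R <- 0L
  } else {
    ratio <- ev / total
    R <- which(cumsum(ratio) >= variance_target - 1e-12)[1L]
    R <- min(R, n - 1L, d)
  }
  P <- eg$vectors[, seq_len(R), drop = FALSE]
  for (j in seq_len(R)) {            # deterministic sign convention
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) P[, j] <- -P[, j]
  }
  structure(list(mu = mu, components = P, explained_ratio = ratio,
                 R = R, variance_target = variance_target,
                 eps_pose = NA_real_, K = K,
                 scheme_names = if (!is.null(scheme)) scheme$names else NULL),
            class = "pose_subspace")
}

as_pose_matrix <- function(vectors) {
  if (is.matrix(vectors)) return(vectors)
  if (inherits(vectors, "pose_vector")) vectors <- list(vectors)
  keep <- vapply(vectors, function(v) isTRUE(v$valid), TRUE)
  vectors <- vectors[keep]
  if (!length(vectors)) stop("no valid pose vectors to fit on")
  do.call(rbind, lapply(vectors, `[[`, "values"))
}

#' @export
print.pose_subspace <- function(x, ...) {
  cat(sprintf("<pose_subspace> 2K = %d, R = %d (%.1f%% variance), eps = %s\n",
              2L * x$K, x$R, 100 * x$variance_target,
              if (is.na(x$eps_pose)) "uncalibrated" else sprintf("%.3f px", x$eps_pose)))
  invisible(x)
}

subspace_values <- function(y_hat, K) {
  v <- if (inherits(y_hat, "pose_vector")) y_hat$values
       else if (inherits(y_hat, "pose")) flatten_pose(y_hat)$values
       else as.numeric(y_hat)
  if (length(v) != 2L * K)
    stop(sprintf("pose vector has length %d, expected %d", length(v), 2L * K))
  v
}

#' Project a pose onto the subspace and back
#'
#' Computes the reconstruction `(y_hat - mu) P P' + mu`: the pose is centred,
#' projected onto the retained components and restored to coordinate space.
#' Idempotent; a pose already in the subspace is a fixed point.
#'
#' @param model a fitted `pose_subspace`.
#' @param y_hat pose vector (`pose_vector`, `pose`, or bare length-2K numeric).
#' @return numeric length-2K reconstructed vector.
#' @export
reconstruct <- function(model, y_hat) {
  stopifnot(inherits(model, "pose_subspace"))
  v <- subspace_values(y_hat, model$K)
  ctr <- v - model$mu
  if (model$R == 0L) return(model$mu)
  drop(model$components %*% crossprod(model$components, ctr)) + model$mu
}

# Per-keypoint 2D reconstruction errors of one vector: length-K vector of
# Euclidean norms over consecutive (x, y) pairs.
reconstruction_errors <- function(model, y_hat) {
  v <- subspace_values(y_hat, model$K)
  e <- v - reconstruct(model, v)
  sqrt(e[c(TRUE, FALSE)]^2 + e[c(FALSE, TRUE)]^2)
}

#' Calibrate the pose-plausibility threshold
#'
#' Reconstructs every training pose through the fitted subspace, measures the
#' per-keypoint 2D pixel error, and takes the maximum over all frames and
#' keypoints. Training poses thus never incur pose loss; only reconstructions
#' worse than anything seen in training are penalized.
#'
#' @param model a fitted `pose_subspace`.
#' @param training_vectors list of valid `pose_vector`s or N x 2K matrix.
#' @param per_keypoint if TRUE return the length-K vector of per-keypoint
#'   maxima instead of the global scalar.
#' @return scalar epsilon in pixels (or length-K vector).
#' @export
calibrate_eps_pose <- function(model, training_vectors, per_keypoint = FALSE) {
  stopifnot(inherits(model, "pose_subspace"))
  X <- as_pose_matrix(training_vectors)
  if (!nrow(X)) stop("no training vectors to calibrate on")
  E <- t(apply(X, 1L, function(v) reconstruction_errors(model, v)))
  if (per_keypoint) apply(E, 2L, max) else max(E)
}

#' Save / load a pose subspace model
#'
#' Single-file archive holding mean, components, explained ratios, calibrated
#' epsilon and keypoint names.
#'
#' @param model a `pose_subspace`.
#' @param path file path.
#' @return `load_subspace` returns the model; `save_subspace` the path,
#'   invisibly.
#' @export
save_subspace <- function(model, path) {
  stopifnot(inherits(model, "pose_subspace"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_subspace
#' @export
load_subspace <- function(path) {
  structure(readRDS(path), class = "pose_subspace")
}
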