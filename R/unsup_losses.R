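# Loss system: supervised coordinate RMSE on labeled frames, plus two
# unsupervised hinge losses evaluated on soft-argmax coordinates of unlabeled
# video -- temporal continuity (inter-frame displacement) and pose
# plausibility (distance to the PCA pose subspace). In the gradient path
# every Euclidean norm is smoothed with a tiny floor (1e-12) inside the
# square root so gradients stay finite at zero displacement; reported loss
# values use the exact norm.

NORM_FLOOR <- 1e-12

smooth_norm <- function(d2) sqrt(d2 + NORM_FLOOR)

#' Loss weights
#'
#' Weights of the two unsupervised terms in the total loss
#' `L_total = L_RMSE + alpha * L_T + beta * L_P`; both default to 1.
#' Setting both to zero reduces training to the purely supervised model.
#'
#' @param alpha weight of the temporal continuity loss (>= 0).
#' @param beta weight of the pose plausibility loss (>= 0).
#' @return object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1, beta = 1) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha < 0 || beta < 0)
    stop("loss weights must be non-negative finite scalars")
  structure(list(alpha = alpha, beta = beta), class = "loss_weights")
}

#' Supervised coordinate RMSE
#'
#' Root of the mean (over visible truth keypoints) squared Euclidean distance
#' between predicted and true keypoint positions, in pixels. Keypoints marked
#' invisible in the truth are excluded.
#'
#' @param pred,truth [pose()] objects on the same scheme.
#' @return scalar RMSE in pixels.
#' @export
supervised_rmse <- function(pred, truth) {
  stopifnot(inherits(pred, "pose"), inherits(truth, "pose"))
  if (pred$scheme$K != truth$scheme$K || !all(pred$scheme$names == truth$scheme$names))
    stop("pred and truth must share one keypoint scheme")
  vis <- truth$visible & pred$visible
  if (!any(vis)) stop("supervised RMSE undefined: no visible keypoints")
  d2 <- rowSums((pred$coords[vis, , drop = FALSE] - truth$coords[vis, , drop = FALSE])^2)
  sqrt(mean(d2))
}

# value + gradient wrt pred coords (K x 2); internal, used by the trainer and
# by finite-difference tests.
supervised_rmse_grad <- function(pred_xy, truth_xy, visible) {
  d <- pred_xy - truth_xy
  d[!visible, ] <- 0
  n <- sum(visible)
  r <- smooth_norm(sum(d^2) / n)
  list(value = r, grad = d / (n * r))
}

#' Temporal continuity loss
#'
#' Hinge penalty on inter-frame keypoint displacement: for every keypoint k
#' and consecutive frame pair, `max(0, ||y_k^t - y_k^(t-1)|| - eps_t[k])`,
#' averaged over all evaluated (pair, keypoint) terms. Displacements within
#' the per-keypoint threshold (ordinary motion) incur no loss; only abrupt
#' jumps are penalized. Invariant under a global translation of every pose.
#'
#' @param traj a [trajectory()] of predicted poses with consecutive frame
#'   indices (T >= 2).
#' @param eps_t per-keypoint thresholds in pixels (length K, or a scalar
#'   recycled to all keypoints); see [calibrate_eps_temporal()].
#' @return scalar mean hinge loss in pixels.
#' @export
temporal_loss <- function(traj, eps_t) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj) < 2L) stop("temporal loss needs at least two frames")
  if (any(diff(traj$frame_index) != 1L)) stop("temporal loss requires consecutive frames")
  K <- traj$scheme$K
  eps_t <- check_eps_t(eps_t, K)
  terms <- numeric(0L)
  for (t in 2L:length(traj)) {
    a <- traj$poses[[t - 1L]]; b <- traj$poses[[t]]
    vis <- a$visible & b$visible
    if (!any(vis)) next
    d <- sqrt(rowSums((b$coords - a$coords)^2))
    terms <- c(terms, pmax(0, d[vis] - eps_t[vis]))
  }
  if (!length(terms)) stop("temporal loss undefined: no co-visible keypoint pairs")
  mean(terms)
}

check_eps_t <- function(eps_t, K) {
  if (length(eps_t) == 1L) eps_t <- rep(as.numeric(eps_t), K)
  if (length(eps_t) != K) stop("eps_t must be a scalar or length-K vector")
  if (any(!is.finite(eps_t) | eps_t < 0)) stop("eps_t thresholds must be non-negative")
  eps_t
}

# value + per-frame gradients for a list of K x 2 coordinate matrices
# (all keypoints assumed visible, as for network predictions).
temporal_loss_grad <- function(coords_list, eps_t) {
  Tn <- length(coords_list)
  K <- nrow(coords_list[[1L]])
  eps_t <- check_eps_t(eps_t, K)
  grads <- lapply(coords_list, function(x) matrix(0, K, 2L))
  n <- (Tn - 1L) * K
  total <- 0
  for (t in 2L:Tn) {
    delta <- coords_list[[t]] - coords_list[[t - 1L]]
    d <- smooth_norm(rowSums(delta^2))
    act <- d > eps_t
    total <- total + sum(pmax(0, d - eps_t))
    if (any(act)) {
      g <- delta[act, , drop = FALSE] / d[act] / n
      grads[[t]][act, ] <- grads[[t]][act, ] + g
      grads[[t - 1L]][act, ] <- grads[[t - 1L]][act, ] - g
    }
  }
  list(value = total / n, grads = grads)
}

#' Pose plausibility loss
#'
#' Hinge penalty on the distance between a predicted pose and its
#' reconstruction through the plausible-pose subspace: per keypoint,
#' `max(0, ||y_k - y_tilde_k|| - eps)`, averaged over the K keypoints, with
#' `eps` the calibrated reconstruction threshold ([calibrate_eps_pose()]).
#' Poses inside the subspace reconstruct exactly and incur zero loss; unlike
#' the temporal loss this term is not translation-invariant (a translated
#' pose leaves the subspace).
#'
#' @param pred a fully visible [pose()], `pose_vector`, or length-2K numeric.
#' @param model fitted `pose_subspace`.
#' @param eps threshold override in pixels; defaults to `model$eps_pose`.
#' @return scalar mean hinge loss in pixels.
#' @export
pose_loss <- function(pred, model, eps = model$eps_pose) {
  stopifnot(inherits(model, "pose_subspace"))
  if (inherits(pred, "pose") && !all(pred$visible))
    stop("pose loss needs a fully specified pose")
  if (is.na(eps)) stop("pose threshold not calibrated; run calibrate_eps_pose()")
  r <- reconstruction_errors(model, pred)
  mean(pmax(0, r - eps))
}

# value + gradient wrt the K x 2 coordinates of one pose.
pose_loss_grad <- function(xy, model, eps = model$eps_pose) {
  K <- model$K
  v <- as.numeric(t(xy))
  ctr <- v - model$mu
  e <- if (model$R == 0L) ctr else ctr - drop(model$components %*% crossprod(model$components, ctr))
  r <- smooth_norm(e[c(TRUE, FALSE)]^2 + e[c(FALSE, TRUE)]^2)
  act <- r > eps
  value <- mean(pmax(0, r - eps))
  g <- numeric(2L * K)
  if (any(act)) {
    w <- ifelse(act, 1 / (K * r), 0)
    g <- e * rep(w, each = 2L)
    if (model$R > 0L)                       # chain through M = I - P P'
      g <- g - drop(model$components %*% crossprod(model$components, g))
  }
  list(value = value, grad = matrix(g, K, 2L, byrow = TRUE))
}

#' Combine loss components
#'
#' Weighted sum `L_total = L_RMSE + alpha * L_T + beta * L_P`.
#'
#' @param l_rmse,l_temporal,l_pose finite scalar loss components (pixels).
#' @param weights a [loss_weights()].
#' @return object of class `loss_report` with the three components and
#'   `l_total`.
#' @export
total_loss <- function(l_rmse, l_temporal, l_pose, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  comp <- c(l_rmse, l_temporal, l_pose)
  if (any(!is.finite(comp))) stop("loss components must be finite")
  structure(list(l_rmse = l_rmse, l_temporal = l_temporal, l_pose = l_pose,
                 l_total = l_rmse + weights$alpha * l_temporal + weights$beta * l_pose,
                 alpha = weights$alpha, beta = weights$beta),
            class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf("<loss> total %.4f = rmse %.4f + %g*temporal %.4f + %g*pose %.4f\n",
              x$l_total, x$l_rmse, x$alpha, x$l_temporal, x$beta, x$l_pose))
  invisible(x)
}
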