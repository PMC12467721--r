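#' Keypoint scheme
#'
#' An ordered set of K keypoint names. The ordering is the single source of
#' truth for vectorization: index `k` of every pose, heatmap stack, threshold
#' vector and pose-vector slot always refers to the same anatomical landmark.
#'
#' Coordinates throughout the package are `(x, y)` with `x` = column and
#' `y` = row, 0-based, origin at the centre of the top-left pixel; sub-pixel
#' outputs use the same frame.
#'
#' @param names character vector of unique keypoint labels (K >= 1).
#' @return object of class `kp_scheme` with fields `names` and `K`.
#' @seealso [carp_scheme()] for the default 21-keypoint fish layout.
#' @export
keypoint_scheme <- function(names) {
  names <- as.character(names)
  if (length(names) < 1L) stop("a keypoint scheme needs at least one keypoint")
  if (anyDuplicated(names)) stop("keypoint names must be unique")
  structure(list(names = names, K = length(names)), class = "kp_scheme")
}

#' Default 21-keypoint fish scheme
#'
#' 15 midline points from snout to caudal peduncle plus 6 fin markers
#' (two pectoral pairs, dorsal fin, tail tip), matching the synthetic
#' fish generator in [fish_params()].
#'
#' @return a `kp_scheme` with K = 21.
#' @export
carp_scheme <- function() {
  keypoint_scheme(c(sprintf("midline_%02d", 1:15),
                    "pectoral_l1", "pectoral_r1", "pectoral_l2", "pectoral_r2",
                    "dorsal_fin", "tail_tip"))
}

#' Construct a pose
#'
#' @param coords K x 2 numeric matrix of `(x, y)` pixel coordinates.
#' @param scheme a [keypoint_scheme()].
#' @param visible logical vector of length K; invisible keypoints are carried
#'   as masked, never zero-filled.
#' @param confidence optional numeric vector in `[0, 1]`.
#' @return object of class `pose`.
#' @export
pose <- function(coords, scheme, visible = rep(TRUE, scheme$K), confidence = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 2L)
  if (nrow(coords) != scheme$K) stop("coords must have one row per keypoint")
  dimnames(coords) <- list(scheme$names, c("x", "y"))
  visible <- as.logical(visible)
  if (length(visible) != scheme$K) stop("visible must have length K")
  if (any(!is.finite(coords[visible, , drop = FALSE])))
    stop("visible keypoints must have finite coordinates")
  if (!is.null(confidence)) {
    confidence <- as.numeric(confidence)
    if (length(confidence) != scheme$K) stop("confidence must have length K")
    if (any(confidence < -1e-12 | confidence > 1 + 1e-12, na.rm = TRUE))
      stop("confidences must lie in [0, 1]")
  }
  structure(list(coords = coords, visible = visible, confidence = confidence,
                 scheme = scheme), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat("<pose> K =", x$scheme$K, "|", sum(x$visible), "visible\n")
  invisible(x)
}

#' Flatten a pose to a 2K vector
#'
#' Layout is interleaved `(x_1, y_1, ..., x_K, y_K)`. The vector is marked
#' invalid when any keypoint is invisible; such vectors are dropped before
#' fitting the pose subspace.
#'
#' @param p a [pose()].
#' @return object of class `pose_vector` with fields `values` (length 2K)
#'   and `valid`.
#' @export
flatten_pose <- function(p) {
  stopifnot(inherits(p, "pose"))
  structure(list(values = as.numeric(t(p$coords)),
                 valid = all(p$visible),
                 K = p$scheme$K),
            class = "pose_vector")
}

#' Rebuild a pose from a 2K vector
#'
#' Inverse of [flatten_pose()] on fully visible poses.
#'
#' @param v a `pose_vector` or a bare numeric vector of length 2K.
#' @param scheme the target [keypoint_scheme()].
#' @return a [pose()] (fully visible).
#' @export
unflatten_pose <- function(v, scheme) {
  values <- if (inherits(v, "pose_vector")) v$values else as.numeric(v)
  if (length(values) != 2L * scheme$K)
    stop(sprintf("pose vector has length %d, expected 2K = %d",
                 length(values), 2L * scheme$K))
  pose(matrix(values, ncol = 2L, byrow = TRUE), scheme)
}

#' An ordered sequence of poses
#'
#' @param poses list of [pose()] objects sharing one scheme.
#' @param frame_index strictly increasing integer frame indices (0-based by
#'   convention of the clip readers, but any strictly increasing integers are
#'   accepted).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(poses, frame_index = seq_along(poses) - 1L) {
  if (!length(poses)) stop("a trajectory needs at least one pose")
  if (!all(vapply(poses, inherits, TRUE, "pose"))) stop("poses must be pose objects")
  K <- poses[[1L]]$scheme$K
  nm <- poses[[1L]]$scheme$names
  ok <- vapply(poses, function(p) p$scheme$K == K && all(p$scheme$names == nm), TRUE)
  if (!all(ok)) stop("all poses in a trajectory must share one keypoint scheme")
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != length(poses)) stop("one frame index per pose")
  if (any(diff(frame_index) <= 0L)) stop("frame indices must be strictly increasing")
  structure(list(poses = poses, frame_index = frame_index,
                 scheme = poses[[1L]]$scheme), class = "trajectory")
}

#' @export
length.trajectory <- function(x) length(x$poses)

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$poses), "frames, K =", x$scheme$K, "\n")
  invisible(x)
}

# K x 2 coordinate matrix of a trajectory entry t (internal convenience)
traj_coords <- function(traj, t) traj$poses[[t]]$coords
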