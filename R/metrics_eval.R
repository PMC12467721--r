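#' Trajectory RMSE report
#'
#' Root of the pooled mean (over all visible `(frame, keypoint)` entries) of
#' squared Euclidean distances between predicted and true keypoints -- not
#' the mean of per-keypoint RMSEs. The per-keypoint variant pools over frames
#' only. Frames are aligned on their indices; entries invisible in the truth
#' are excluded.
#'
#' @param pred,truth [trajectory()] objects on the same scheme.
#' @return object of class `eval_report`: `rmse_overall`,
#'   `rmse_per_keypoint` (length K), `n_frames`, plus outlier counters
#'   (NA until the corresponding filter is run).
#' @export
rmse_eval <- function(pred, truth) {
  stopifnot(inherits(pred, "trajectory"), inherits(truth, "trajectory"))
  if (!all(pred$scheme$names == truth$scheme$names))
    stop("prediction and truth must share one keypoint scheme")
  common <- intersect(pred$frame_index, truth$frame_index)
  if (!length(common)) stop("no overlapping frames to evaluate")
  K <- pred$scheme$K
  sq <- matrix(NA_real_, length(common), K)
  for (i in seq_along(common)) {
    p <- pred$poses[[match(common[i], pred$frame_index)]]
    g <- truth$poses[[match(common[i], truth$frame_index)]]
    vis <- g$visible & p$visible
    d2 <- rowSums((p$coords - g$coords)^2)
    sq[i, vis] <- d2[vis]
  }
  per_k <- sqrt(colMeans(sq, na.rm = TRUE))
  structure(list(rmse_overall = sqrt(mean(sq, na.rm = TRUE)),
                 rmse_per_keypoint = stats::setNames(per_k, pred$scheme$names),
                 n_frames = length(common),
                 n_outliers_conf = NA_integer_,
                 n_outliers_jump = NA_integer_),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval> RMSE %.3f px over %d frames", x$rmse_overall, x$n_frames))
  if (!is.na(x$n_outliers_conf)) cat(sprintf(", %d low-confidence", x$n_outliers_conf))
  if (!is.na(x$n_outliers_jump)) cat(sprintf(", %d jump outliers", x$n_outliers_jump))
  cat("\n")
  invisible(x)
}

#' Confidence-based outlier filtering
#'
#' Masks keypoints whose confidence falls strictly below the threshold
#' (default 0.9) and returns the flagged `(frame, keypoint)` pairs. This
#' catches the low-confidence outlier class; high-confidence mispredictions
#' pass through and need [jump_outliers()].
#'
#' @param traj a [trajectory()] whose poses carry confidences.
#' @param threshold confidence threshold (strict `<`).
#' @return list with `trajectory` (flagged keypoints masked invisible) and
#'   `flagged` (data.frame with `frame`, `keypoint`, `confidence`).
#' @export
confidence_filter <- function(traj, threshold = 0.9) {
  stopifnot(inherits(traj, "trajectory"))
  if (any(vapply(traj$poses, function(p) is.null(p$confidence), TRUE)))
    stop("confidence_filter needs per-keypoint confidences")
  flagged <- list()
  poses <- traj$poses
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    low <- p$confidence < threshold
    if (any(low)) {
      flagged[[length(flagged) + 1L]] <-
        data.frame(frame = traj$frame_index[i],
                   keypoint = p$scheme$names[low],
                   confidence = p$confidence[low])
      poses[[i]] <- pose(p$coords, p$scheme, visible = p$visible & !low,
                         confidence = p$confidence)
    }
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged)
             else data.frame(frame = integer(), keypoint = character(),
                             confidence = numeric())
  list(trajectory = trajectory(poses, traj$frame_index), flagged = flagged)
}

#' Trajectory jump outliers
#'
#' Flags every `(frame, keypoint)` whose displacement from the previous frame
#' exceeds the per-keypoint temporal threshold -- the same statistic the
#' temporal continuity loss penalizes. This catches high-confidence
#' mispredictions that confidence filtering misses: abrupt, biologically
#' implausible jumps in an otherwise smooth track. Displacement-based, hence
#' invariant to a global translation of all poses.
#'
#' @param traj a [trajectory()] (T >= 2).
#' @param eps_t per-keypoint thresholds in px (scalar recycled), typically
#'   from [calibrate_eps_temporal()].
#' @return data.frame with `frame`, `keypoint`, `displacement`.
#' @export
jump_outliers <- function(traj, eps_t) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj) < 2L) stop("need at least two frames")
  K <- traj$scheme$K
  eps_t <- check_eps_t(eps_t, K)
  out <- list()
  for (i in 2L:length(traj)) {
    if (traj$frame_index[i] - traj$frame_index[i - 1L] != 1L) next
    a <- traj$poses[[i - 1L]]; b <- traj$poses[[i]]
    vis <- a$visible & b$visible
    d <- sqrt(rowSums((b$coords - a$coords)^2))
    hit <- vis & d > eps_t
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(frame = traj$frame_index[i],
                                            keypoint = traj$scheme$names[hit],
                                            displacement = d[hit])
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(frame = integer(), keypoint = character(),
                  displacement = numeric())
}

#' Write an evaluation report
#'
#' Flat key/value text rendering of an `eval_report` (machine-readable,
#' one `key<TAB>value` line each).
#'
#' @param report an `eval_report`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  lines <- c(sprintf("rmse_overall\t%.6f", report$rmse_overall),
             sprintf("n_frames\t%d", report$n_frames),
             sprintf("n_outliers_conf\t%s", report$n_outliers_conf),
             sprintf("n_outliers_jump\t%s", report$n_outliers_jump),
             sprintf("rmse_%s\t%.6f", names(report$rmse_per_keypoint),
                     report$rmse_per_keypoint))
  writeLines(lines, path)
  invisible(path)
}
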