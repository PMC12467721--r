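traj_from_coords <- function(coords_list, scheme, frame_index = NULL, conf = NULL) {
  poses <- lapply(coords_list, function(x)
    pose(x, scheme, confidence = conf))
  trajectory(poses, frame_index %||% (seq_along(poses) - 1L))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("trajectory RMSE pools squared distances over visible entries", {
  s1 <- keypoint_scheme("p")
  t1 <- traj_from_coords(list(matrix(c(0, 0), 1L)), s1)
  p_same <- t1
  expect_equal(rmse_eval(p_same, t1)$rmse_overall, 0)

  p_off <- traj_from_coords(list(matrix(c(3, 4), 1L)), s1)
  expect_equal(rmse_eval(p_off, t1)$rmse_overall, 5)

  # two keypoints, errors 0 and 5 -> pooled sqrt(12.5), not mean of RMSEs
  tr <- traj_from_coords(list(matrix(c(1, 1, 2, 2), 2L)), scheme2)
  pr <- traj_from_coords(list(matrix(c(1, 4, 2, 6), 2L)), scheme2)
  r <- rmse_eval(pr, tr)
  expect_equal(r$rmse_overall, sqrt(12.5), tolerance = 1e-9)
  expect_equal(unname(r$rmse_per_keypoint), c(0, 5))

  expect_error(rmse_eval(traj_from_coords(list(matrix(c(0, 0), 1L)), s1,
                                          frame_index = 5L), t1),
               "no overlapping")
})

test_that("RMSE is frame-permutation invariant and scales linearly", {
  set.seed(70)
  sch <- scheme3
  tr <- traj_from_coords(lapply(1:5, function(i) matrix(runif(6, 0, 40), 3L)), sch)
  pr <- traj_from_coords(lapply(1:5, function(i) matrix(runif(6, 0, 40), 3L)), sch)
  r1 <- rmse_eval(pr, tr)$rmse_overall
  # alignment is by frame index, not position: evaluating on a sub-window and
  # its complement and pooling reproduces the full-trajectory value
  sub1 <- trajectory(pr$poses[1:2], pr$frame_index[1:2])
  sub2 <- trajectory(pr$poses[3:5], pr$frame_index[3:5])
  e1 <- rmse_eval(sub1, tr); e2 <- rmse_eval(sub2, tr)
  pooled <- sqrt((e1$rmse_overall^2 * 2 + e2$rmse_overall^2 * 3) / 5)
  expect_equal(pooled, r1, tolerance = 1e-9)
  scale3 <- function(t) trajectory(lapply(t$poses, function(p)
    pose(p$coords * 3, p$scheme)), t$frame_index)
  expect_equal(rmse_eval(scale3(pr), scale3(tr))$rmse_overall, 3 * r1,
               tolerance = 1e-9)
})

test_that("confidence filtering uses a strict threshold and masks flags", {
  sch <- scheme2
  tr <- traj_from_coords(list(matrix(1, 2L, 2L), matrix(2, 2L, 2L)), sch,
                         conf = c(1, 1))
  r <- confidence_filter(tr)
  expect_equal(nrow(r$flagged), 0L)

  mixed <- trajectory(list(
    pose(matrix(1, 2L, 2L), sch, confidence = c(0.95, 0.89)),
    pose(matrix(2, 2L, 2L), sch, confidence = c(0.9, 0.91))), 0:1)
  r2 <- confidence_filter(mixed, threshold = 0.9)
  expect_equal(r2$flagged$keypoint, "b")          # 0.89 only; 0.90 is not < 0.9
  expect_false(r2$trajectory$poses[[1L]]$visible[2L])
  expect_true(all(r2$trajectory$poses[[2L]]$visible))

  expect_equal(nrow(confidence_filter(mixed, threshold = 0)$flagged), 0L)
  expect_error(confidence_filter(traj_from_coords(list(matrix(1, 2L, 2L)), sch)),
               "confidences")
})

test_that("jump_outliers flags exactly an injected teleport and is shift-invariant", {
  par <- fish_params("straight", occlusion_rate = 0, noise_sd = 0)
  set.seed(71)
  cl <- simulate_clip(par, 15L)
  eps_t <- calibrate_eps_temporal(cl$truth, q = 1.0)
  expect_equal(nrow(jump_outliers(cl$truth, eps_t)), 0L)

  # keypoint 2 teleports 50 px away from frame 7 (0-based) onward
  poses <- cl$truth$poses
  for (i in 8:15) {
    xy <- poses[[i]]$coords
    xy[2L, ] <- xy[2L, ] + c(50, 0)
    poses[[i]] <- pose(xy, poses[[i]]$scheme)
  }
  corrupted <- trajectory(poses, cl$truth$frame_index)
  flags <- jump_outliers(corrupted, eps_t)
  expect_equal(nrow(flags), 1L)
  expect_equal(flags$frame, 7L)
  expect_equal(flags$keypoint, corrupted$scheme$names[2L])

  # translation invariance: a hair of threshold slack avoids knife-edge ties
  # (q = 1 thresholds equal the max displacement to the last float bit)
  eps_safe <- eps_t * (1 + 1e-9)
  shifted <- trajectory(lapply(poses, function(p)
    pose(p$coords + 11.5, p$scheme)), corrupted$frame_index)
  expect_equal(jump_outliers(shifted, eps_safe),
               jump_outliers(corrupted, eps_safe), tolerance = 1e-6)
})

test_that("evaluation reports serialize as flat key/value text", {
  s1 <- keypoint_scheme("p")
  tr <- traj_from_coords(list(matrix(c(0, 0), 1L), matrix(c(1, 1), 1L)), s1)
  pr <- traj_from_coords(list(matrix(c(3, 4), 1L), matrix(c(1, 1), 1L)), s1)
  r <- rmse_eval(pr, tr)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_eval_report(r, f)
  lines <- readLines(f)
  kv <- do.call(rbind, strsplit(lines, "\t"))
  expect_equal(as.numeric(kv[kv[, 1L] == "rmse_overall", 2L]),
               r$rmse_overall, tolerance = 1e-6)
  expect_equal(as.integer(kv[kv[, 1L] == "n_frames", 2L]), 2L)
})
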