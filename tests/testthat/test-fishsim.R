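test_that("the midline follows the traveling-wave model", {
  # no undulation: collinear points along the heading
  p0 <- fish_params("straight", a_head = 0, a_tail = 0, heading = 0.7)
  mid <- midline_at(1.3, p0)
  d <- sweep(mid[-1, ], 2L, mid[1, ])
  angles <- atan2(d[, 2L], d[, 1L])
  expect_equal(angles, rep(0.7, nrow(d)), tolerance = 1e-9)

  # periodicity over one tail-beat (straight gait: rigid frame is static)
  p1 <- fish_params("straight", freq = 2)
  expect_equal(midline_at(0.37 + 1 / p1$freq, p1), midline_at(0.37, p1),
               tolerance = 1e-9)

  # backward gait equals the closed-form phase-reversed wave
  pb <- fish_params("backward")
  t <- 0.21
  s <- seq(0, 1, length.out = pb$M)
  A <- pb$a_head + (pb$a_tail - pb$a_head) * s^2
  h <- A * sin(2 * pi * (s / pb$wavelength + pb$freq * t))
  expected <- cbind(pb$center[1] + (s - 0.5) * pb$body_length,
                    pb$center[2] + h)               # heading 0: n = (0, 1)
  expect_equal(midline_at(t, pb), expected, tolerance = 1e-9)
})

test_that("poses carry 21 keypoints with mirror-symmetric pectorals at rest", {
  par <- fish_params("straight")
  p <- pose_at(0.4, par)
  expect_equal(p$scheme$K, 21L)

  par0 <- fish_params("straight", a_head = 0, a_tail = 0, heading = 0)
  p0 <- pose_at(1.1, par0)
  cy <- par0$center[2]
  l1 <- p0$coords["pectoral_l1", ]; r1 <- p0$coords["pectoral_r1", ]
  expect_equal(l1[["x"]], r1[["x"]], tolerance = 1e-9)
  expect_equal(l1[["y"]] - cy, -(r1[["y"]] - cy), tolerance = 1e-9)
})

test_that("consecutive-frame displacements respect the smoothness bound", {
  par <- fish_params("straight")
  ts <- seq(0, 1 / par$freq, by = 1 / par$frame_rate)
  bound <- par$body_length * par$freq / par$frame_rate
  for (i in seq_len(length(ts) - 1L)) {
    d <- sqrt(rowSums((pose_at(ts[i + 1L], par)$coords -
                       pose_at(ts[i], par)$coords)^2))
    expect_lte(max(d), bound)
  }
})

test_that("rendering is deterministic, supported on the body, occlusion-aware", {
  par <- fish_params("straight", noise_sd = 0.02)
  p <- pose_at(0.3, par)
  set.seed(60); f1 <- render_frame(p, par)
  set.seed(60); f2 <- render_frame(p, par)
  expect_identical(f1$image, f2$image)

  # brightest pixel lies within 2 px of some body keypoint
  peak <- which(f1$image == max(f1$image), arr.ind = TRUE)[1, ]
  px <- peak[2L] - 1; py <- peak[1L] - 1
  dmin <- min(sqrt((p$coords[, 1L] - px)^2 + (p$coords[, 2L] - py)^2))
  expect_lte(dmin, 2)

  # occluder zeroes coverage and flips visibility of covered keypoints
  occ <- c(p$coords[8, 1L] - 3, p$coords[8, 1L] + 3,
           p$coords[8, 2L] - 3, p$coords[8, 2L] + 3)
  set.seed(61)
  fo <- render_frame(p, par, occluder = occ)
  expect_false(fo$truth$visible[8])
  expect_true(any(fo$truth$visible))
})

test_that("generate_dataset writes the annotated layout deterministically", {
  cfg <- sim_config(n_labeled = 12L, n_clips = 2L, clip_seconds = 1,
                    frame_rate = 6, image_size = 32L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds <- generate_dataset(cfg, seed = 3L, out_dir = d1)
  generate_dataset(cfg, seed = 3L, out_dir = d2)

  ann_path <- file.path(d1, "labeled", "annotations.csv")
  lines <- readLines(ann_path)
  expect_length(lines, 3L + 12L)
  expect_length(list.dirs(file.path(d1, "clips"), recursive = FALSE), 2L)
  expect_identical(readLines(ann_path),
                   readLines(file.path(d2, "labeled", "annotations.csv")))

  # annotations reproduce the simulator truth for visible keypoints
  tab <- read_annotations(ann_path, ds$scheme)
  poses <- stcpose:::annotation_poses(tab)
  for (i in seq_along(poses)) {
    vis <- ds$labeled$truth[[i]]$visible
    expect_identical(poses[[i]]$visible, vis)
    expect_equal(poses[[i]]$coords[vis, ], ds$labeled$truth[[i]]$coords[vis, ],
                 tolerance = 1e-6)
  }

  # clip truth round-trips through its CSV
  tr <- read_truth_csv(file.path(d1, "truth", "clip_01_truth.csv"), ds$scheme)
  expect_equal(length(tr), length(ds$clip_truth[[1L]]))
  expect_equal(tr$poses[[3L]]$coords, ds$clip_truth[[1L]]$poses[[3L]]$coords,
               tolerance = 1e-6)

  expect_error(generate_dataset(cfg, seed = 3L, out_dir = d1), "collision")
})

test_that("the default generation yields 400 labeled frames and 20 clips", {
  ds <- generate_dataset(sim_config(), seed = 9L)
  expect_length(ds$labeled$images, 400L)
  expect_length(ds$clips, 20L)
  expect_true(all(lengths(ds$clips) == sim_config()$clip_seconds *
                                       sim_config()$frame_rate))
  expect_setequal(unique(ds$labeled$gaits), c("straight", "backward", "turning"))
})

test_that("straight-swimming poses span a genuinely low-dimensional subspace", {
  par <- fish_params("straight")
  ts <- seq(0, 6, length.out = 60)                 # > 2K = 42 poses
  X <- do.call(rbind, lapply(ts, function(t) flatten_pose(pose_at(t, par))$values))
  m <- fit_subspace(X)
  expect_lte(m$R, 8L)
  expect_gte(sum(m$explained_ratio[seq_len(m$R)]), 0.99 - 1e-9)
})

test_that("ground-truth motion never violates its own max-displacement threshold", {
  par <- fish_params("turning", occlusion_rate = 0)
  set.seed(62)
  cl <- simulate_clip(par, 30L)
  eps_t <- calibrate_eps_temporal(cl$truth, q = 1.0)
  expect_equal(temporal_loss(cl$truth, eps_t), 0)
  expect_equal(nrow(jump_outliers(cl$truth, eps_t)), 0L)
})
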