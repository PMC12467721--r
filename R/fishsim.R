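# Synthetic articulated-fish video generator. The body is a carangiform
# traveling wave: midline points at arc positions s in [0,1] get a lateral
# offset h(s,t) = A(s) * sin(2*pi*(s/lambda - sigma*f*t)) with a tailward-
# growing amplitude envelope A(s) = a_head + (a_tail - a_head)*s^2; sigma=+1
# sends the wave tailward (forward swimming), sigma=-1 headward (backward
# swimming), and a nonzero heading rate produces turning. Frames are the fish
# rendered as Gaussian blobs of tapering radius on a noisy background, in a
# fish-centred crop (the camera follows the animal, as pose pipelines crop
# around a detection). Ground truth is frame-synchronous by construction.

#' Fish kinematics and rendering parameters
#'
#' Defaults emulate the study conditions this package targets: a single fish,
#' 21 keypoints (15 midline + 2 pectoral pairs + dorsal fin + tail tip),
#' three gaits, occlusion events on a tenth of the frames.
#'
#' @param gait `"straight"`, `"backward"` or `"turning"`.
#' @param image_size frame side in px.
#' @param body_length fish length in px (default 60% of the frame side).
#' @param M number of midline points (default 15; with the 6 fin points this
#'   gives the 21-keypoint scheme).
#' @param a_head,a_tail wave amplitude envelope at head and tail, px.
#' @param wavelength body-wave length as a fraction of body length.
#' @param freq tail-beat frequency, Hz.
#' @param frame_rate frames per second.
#' @param heading initial heading, radians.
#' @param heading_rate turning rate, rad/s (nonzero for the turning gait).
#' @param center fish centre `(x, y)` px; default frame centre.
#' @param occlusion_rate fraction of frames hit by a rectangular occluder.
#' @param noise_sd additive Gaussian background noise (intensity units).
#' @return object of class `fish_params`.
#' @export
fish_params <- function(gait = c("straight", "backward", "turning"),
                        image_size = 64L,
                        body_length = 0.6 * image_size,
                        M = 15L,
                        a_head = 0.02 * body_length,
                        a_tail = 0.12 * body_length,
                        wavelength = 0.95,
                        freq = 2,
                        frame_rate = 10,
                        heading = 0,
                        heading_rate = if (match.arg(gait) == "turning") pi / 6 else 0,
                        center = c(image_size, image_size) / 2,
                        occlusion_rate = 0.1,
                        noise_sd = 0.02) {
  gait <- match.arg(gait)
  stopifnot(a_head >= 0, a_tail >= 0, frame_rate > 0, freq > 0, M >= 2L)
  structure(list(gait = gait, image_size = as.integer(image_size),
                 body_length = body_length, M = as.integer(M),
                 a_head = a_head, a_tail = a_tail, wavelength = wavelength,
                 freq = freq, frame_rate = frame_rate,
                 heading = heading, heading_rate = heading_rate,
                 sigma = if (gait == "backward") -1 else 1,
                 center = center, occlusion_rate = occlusion_rate,
                 noise_sd = noise_sd),
            class = "fish_params")
}

# body point (and lateral unit normal) at arc position s and time t
body_point <- function(s, t, params) {
  th <- params$heading + params$heading_rate * t
  u <- c(cos(th), sin(th))        # along-body direction, head at s = 0
  n <- c(-sin(th), cos(th))
  A <- params$a_head + (params$a_tail - params$a_head) * s^2
  h <- A * sin(2 * pi * (s / params$wavelength - params$sigma * params$freq * t))
  base <- params$center + (s - 0.5) * params$body_length * u
  base + h * n
}

#' Midline points at time t
#'
#' @param t time in seconds (>= 0).
#' @param params a [fish_params()].
#' @return M x 2 matrix of `(x, y)` px, head first.
#' @export
midline_at <- function(t, params) {
  stopifnot(inherits(params, "fish_params"))
  s <- seq(0, 1, length.out = params$M)
  t(vapply(s, body_point, numeric(2L), t = t, params = params))
}

# fin anchor positions (arc position, perpendicular offset in body lengths,
# tangential offset): two pectoral pairs, dorsal fin, tail tip marker
fin_spec <- function() {
  data.frame(name = c("pectoral_l1", "pectoral_r1", "pectoral_l2", "pectoral_r2",
                      "dorsal_fin", "tail_tip"),
             s = c(0.20, 0.20, 0.38, 0.38, 0.52, 1.00),
             perp = c(0.09, -0.09, 0.07, -0.07, 0.035, 0),
             tang = c(0, 0, 0, 0, 0, 0.05))
}

#' Full 21-keypoint pose at time t
#'
#' 15 midline samples plus 6 fin points offset perpendicular to the local
#' midline tangent (tail tip extends along it). With zero undulation the
#' left/right pectoral points are mirror-symmetric about the body axis.
#'
#' @inheritParams midline_at
#' @param scheme keypoint scheme (default [carp_scheme()]).
#' @return a fully visible [pose()].
#' @export
pose_at <- function(t, params, scheme = carp_scheme()) {
  mid <- midline_at(t, params)
  fins <- fin_spec()
  ds <- 1e-4
  fin_xy <- t(vapply(seq_len(nrow(fins)), function(i) {
    s <- fins$s[i]
    p0 <- body_point(s, t, params)
    tau <- body_point(min(s + ds, 1), t, params) - body_point(max(s - ds, 0), t, params)
    tau <- tau / sqrt(sum(tau^2))
    nrm <- c(-tau[2L], tau[1L])
    p0 + params$body_length * (fins$perp[i] * nrm + fins$tang[i] * tau)
  }, numeric(2L)))
  pose(rbind(mid, fin_xy), scheme)
}

#' Render one frame
#'
#' Body drawn as Gaussian blobs of tapering radius along the midline plus fin
#' blobs, additive Gaussian background noise (from the current RNG stream),
#' and an optional rectangular occluder that zeroes its coverage and flips
#' the visibility of covered keypoints. Keypoints outside the frame are also
#' marked invisible.
#'
#' @param p a [pose()] from [pose_at()].
#' @param params a [fish_params()].
#' @param occluder optional `c(x0, x1, y0, y1)` rectangle in px.
#' @param time time stamp stored in the frame, seconds.
#' @return list with `image` (H x W matrix in `[0, 1]`), `truth` (pose with
#'   occlusion-aware visibility) and `time`.
#' @export
render_frame <- function(p, params, occluder = NULL, time = NA_real_) {
  n <- params$image_size
  xs <- seq_len(n) - 1
  img <- matrix(0, n, n)
  mid <- p$coords[seq_len(params$M), , drop = FALSE]
  s <- seq(0, 1, length.out = params$M)
  radius <- params$body_length * (0.060 * (1 - 0.65 * s) + 0.012)
  blob <- function(cx, cy, r, amp) {
    outer(exp(-(xs - cy)^2 / (2 * r^2)), exp(-(xs - cx)^2 / (2 * r^2))) * amp
  }
  for (i in seq_len(params$M))
    img <- img + blob(mid[i, 1L], mid[i, 2L], radius[i], 0.55)
  fin_rows <- (params$M + 1L):nrow(p$coords)
  for (i in fin_rows)
    img <- img + blob(p$coords[i, 1L], p$coords[i, 2L], 0.04 * params$body_length, 0.35)
  img <- pmin(img, 1)
  visible <- p$coords[, 1L] >= 0 & p$coords[, 1L] <= n - 1 &
             p$coords[, 2L] >= 0 & p$coords[, 2L] <= n - 1
  if (!is.null(occluder)) {
    ix <- xs >= occluder[1L] & xs <= occluder[2L]
    iy <- xs >= occluder[3L] & xs <= occluder[4L]
    img[iy, ix] <- 0
    covered <- p$coords[, 1L] >= occluder[1L] & p$coords[, 1L] <= occluder[2L] &
               p$coords[, 2L] >= occluder[3L] & p$coords[, 2L] <= occluder[4L]
    visible <- visible & !covered
  }
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
  img <- pmin(pmax(img, 0), 1)
  list(image = img,
       truth = pose(p$coords, p$scheme, visible = visible),
       time = time)
}

random_occluder <- function(params) {
  n <- params$image_size
  w <- stats::runif(1L, 0.15, 0.30) * n
  h <- stats::runif(1L, 0.15, 0.30) * n
  x0 <- stats::runif(1L, 0, n - 1 - w)
  y0 <- stats::runif(1L, 0, n - 1 - h)
  c(x0, x0 + w, y0, y0 + h)
}

# simulate a clip: consecutive frames with occlusion events
simulate_clip <- function(params, n_frames, t0 = 0) {
  frames <- vector("list", n_frames)
  poses <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    t <- t0 + (i - 1L) / params$frame_rate
    occ <- if (stats::runif(1L) < params$occlusion_rate) random_occluder(params)
    fr <- render_frame(pose_at(t, params), params, occluder = occ, time = t)
    frames[[i]] <- fr$image
    poses[[i]] <- fr$truth
  }
  list(frames = frames, truth = trajectory(poses, seq_len(n_frames) - 1L))
}

#' Dataset generation configuration
#'
#' Defaults mirror the study composition this package emulates: 400 labeled
#' static frames sampled across the three gaits plus 20 unlabeled ten-second
#' clips; everything scales down for test-sized runs.
#'
#' @param n_labeled number of labeled static frames.
#' @param n_clips number of unlabeled clips.
#' @param clip_seconds clip duration, s.
#' @param frame_rate clip frame rate, fps.
#' @param image_size frame side, px.
#' @param occlusion_rate fraction of frames with an occluder.
#' @param noise_sd background noise level.
#' @param gaits gaits to cycle through.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_labeled = 400L, n_clips = 20L, clip_seconds = 10,
                       frame_rate = 10, image_size = 64L,
                       occlusion_rate = 0.1, noise_sd = 0.02,
                       gaits = c("straight", "backward", "turning")) {
  structure(list(n_labeled = as.integer(n_labeled), n_clips = as.integer(n_clips),
                 clip_seconds = clip_seconds, frame_rate = frame_rate,
                 image_size = as.integer(image_size),
                 occlusion_rate = occlusion_rate, noise_sd = noise_sd,
                 gaits = gaits), class = "sim_config")
}

labeled_fish_params <- function(cfg, gait) {
  n <- cfg$image_size
  fish_params(gait, image_size = n,
              heading = stats::runif(1L, 0, 2 * pi),
              center = n / 2 + stats::runif(2L, -0.08, 0.08) * n,
              frame_rate = cfg$frame_rate,
              occlusion_rate = cfg$occlusion_rate,
              noise_sd = cfg$noise_sd)
}

#' Generate a synthetic dataset
#'
#' Labeled static frames (annotations carry only visible keypoints; the full
#' hidden ground truth is kept separately for evaluation) plus unlabeled
#' clips with frame-synchronous ground-truth trajectories. Fully
#' deterministic given `seed`: two runs write byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @param out_dir optional output directory; when given, frames are written
#'   as PNG files, annotations as a DeepLabCut-dialect CSV
#'   (`labeled/annotations.csv`), and ground truth as plain CSV tables under
#'   `truth/`. The directory must not already contain a dataset.
#' @return (invisibly when writing) the in-memory dataset: `scheme`,
#'   `labeled` (`images`, `truth` poses, `gaits`), `clips` (lists of images),
#'   `clip_truth` (trajectories), `cfg`.
#' @export
generate_dataset <- function(cfg = sim_config(), seed = 1L, out_dir = NULL) {
  set.seed(seed)
  scheme <- carp_scheme()
  gaits <- rep(cfg$gaits, length.out = cfg$n_labeled)
  images <- vector("list", cfg$n_labeled)
  truth <- vector("list", cfg$n_labeled)
  for (i in seq_len(cfg$n_labeled)) {
    par <- labeled_fish_params(cfg, gaits[i])
    t <- stats::runif(1L, 0, 10)
    occ <- if (stats::runif(1L) < cfg$occlusion_rate) random_occluder(par)
    fr <- render_frame(pose_at(t, par), par, occluder = occ, time = t)
    images[[i]] <- fr$image
    truth[[i]] <- fr$truth
  }
  clip_gaits <- rep(cfg$gaits, length.out = cfg$n_clips)
  n_frames <- round(cfg$clip_seconds * cfg$frame_rate)
  clips <- vector("list", cfg$n_clips)
  clip_truth <- vector("list", cfg$n_clips)
  for (j in seq_len(cfg$n_clips)) {
    par <- labeled_fish_params(cfg, clip_gaits[j])
    cl <- simulate_clip(par, n_frames, t0 = stats::runif(1L, 0, 2))
    clips[[j]] <- cl$frames
    clip_truth[[j]] <- cl$truth
  }
  ds <- list(scheme = scheme,
             labeled = list(images = images, truth = truth, gaits = gaits),
             clips = clips, clip_truth = clip_truth, cfg = cfg)
  if (!is.null(out_dir)) {
    write_dataset(ds, out_dir)
    return(invisible(ds))
  }
  ds
}

write_dataset <- function(ds, out_dir) {
  lab_dir <- file.path(out_dir, "labeled")
  if (dir.exists(lab_dir)) stop("output path collision: ", lab_dir, " exists")
  dir.create(lab_dir, recursive = TRUE)
  dir.create(file.path(out_dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  n <- length(ds$labeled$images)
  rel <- sprintf("frame_%04d.png", seq_len(n))
  for (i in seq_len(n))
    png::writePNG(ds$labeled$images[[i]], file.path(lab_dir, rel[i]))
  # annotations: visible keypoints only
  vis_truth <- lapply(ds$labeled$truth, function(p) p)
  tab <- annotation_table(rel, vis_truth, ds$scheme)
  write_annotations(tab, file.path(lab_dir, "annotations.csv"))
  write_truth_csv(ds$labeled$truth, seq_len(n) - 1L,
                  file.path(out_dir, "truth", "labeled_truth.csv"))
  for (j in seq_along(ds$clips)) {
    cdir <- file.path(out_dir, "clips", sprintf("clip_%02d", j))
    dir.create(cdir, recursive = TRUE)
    for (i in seq_along(ds$clips[[j]]))
      png::writePNG(ds$clips[[j]][[i]], file.path(cdir, sprintf("frame_%04d.png", i)))
    write_truth_csv(ds$clip_truth[[j]]$poses, ds$clip_truth[[j]]$frame_index,
                    file.path(out_dir, "truth", sprintf("clip_%02d_truth.csv", j)))
  }
  invisible(out_dir)
}

write_truth_csv <- function(poses, frame_index, path) {
  rows <- do.call(rbind, lapply(seq_along(poses), function(i) {
    p <- poses[[i]]
    data.frame(frame = frame_index[i], keypoint = p$scheme$names,
               x = sprintf("%.6f", p$coords[, 1L]),
               y = sprintf("%.6f", p$coords[, 2L]),
               visible = as.integer(p$visible))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth trajectory table
#'
#' Reads the plain CSV written by [generate_dataset()] (`frame, keypoint, x,
#' y, visible`) back into a [trajectory()].
#'
#' @param path CSV path.
#' @param scheme keypoint scheme the table must match.
#' @return a `trajectory`.
#' @export
read_truth_csv <- function(path, scheme = carp_scheme()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  frames <- sort(unique(d$frame))
  poses <- lapply(frames, function(f) {
    di <- d[d$frame == f, ]
    di <- di[match(scheme$names, di$keypoint), ]
    pose(cbind(di$x, di$y), scheme, visible = di$visible == 1L)
  })
  trajectory(poses, frames)
}
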