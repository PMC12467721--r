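#' Training configuration
#'
#' Defaults follow the study protocol this package implements: Adam with
#' initial learning rate 0.001 halved at epochs 150/200/250, backbone frozen
#' for the first 20 epochs, batch size 6, 300 epochs, unsupervised loss
#' weights alpha = beta = 1.
#'
#' @param lr0 initial learning rate.
#' @param milestones ascending epochs at which the rate is multiplied by
#'   `lr_factor`.
#' @param lr_factor multiplicative decay at each milestone.
#' @param freeze_epochs number of initial epochs with the backbone frozen.
#' @param batch_size labeled samples per optimizer step.
#' @param epochs total training epochs.
#' @param weights a [loss_weights()]; both zero gives purely supervised
#'   training.
#' @param unlabeled_window frames per sampled unlabeled clip segment (>= 6,
#'   so a five-frame temporal window yields at least two interior
#'   predictions).
#' @param seed RNG seed governing the split, initialization consumers and
#'   batch shuffling.
#' @param val_fraction fraction of labeled frames held out for validation.
#' @param eps_quantile quantile used by [calibrate_eps_temporal()].
#' @param eps_t optional explicit temporal thresholds (scalar or length K),
#'   overriding calibration.
#' @return object of class `stc_train_config`.
#' @export
train_config <- function(lr0 = 0.001, milestones = c(150L, 200L, 250L),
                         lr_factor = 0.5, freeze_epochs = 20L, batch_size = 6L,
                         epochs = 300L, weights = loss_weights(),
                         unlabeled_window = 6L, seed = 1L,
                         val_fraction = 0.2, eps_quantile = 0.95, eps_t = NULL) {
  if (is.unsorted(milestones, strictly = TRUE)) stop("milestones must be ascending")
  if (batch_size < 1L || epochs < 1L) stop("counts must be positive")
  if (unlabeled_window < 6L) stop("unlabeled_window must be at least 6")
  if (freeze_epochs < 0L) stop("freeze_epochs must be non-negative")
  stopifnot(inherits(weights, "loss_weights"))
  structure(list(lr0 = lr0, milestones = as.integer(milestones),
                 lr_factor = lr_factor, freeze_epochs = as.integer(freeze_epochs),
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 weights = weights, unlabeled_window = as.integer(unlabeled_window),
                 seed = as.integer(seed), val_fraction = val_fraction,
                 eps_quantile = eps_quantile, eps_t = eps_t),
            class = "stc_train_config")
}

#' Learning rate at a given epoch
#'
#' Step schedule: `lr0 * lr_factor^m` where `m` counts milestones at or
#' before `epoch` (0-based).
#'
#' @param epoch 0-based epoch index.
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
lr_at <- function(epoch, cfg) {
  if (epoch < 0) stop("epoch must be non-negative")
  cfg$lr0 * cfg$lr_factor^sum(cfg$milestones <= epoch)
}

#' Calibrate per-keypoint temporal thresholds
#'
#' Different keypoints move by different amounts between frames (a tail tip
#' travels farther than a snout), so each gets its own dead-zone threshold:
#' the `q`-quantile of its observed inter-frame displacements over reference
#' trajectories (annotated sequences or simulator ground truth). At `q = 1`
#' no genuine motion in the reference ever exceeds its threshold.
#'
#' @param trajs a [trajectory()] or list of trajectories.
#' @param q quantile in `[0, 1]` (default 0.95).
#' @return named numeric vector of length K, pixels.
#' @export
calibrate_eps_temporal <- function(trajs, q = 0.95) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  K <- trajs[[1L]]$scheme$K
  disp <- vector("list", K)
  for (tr in trajs) {
    if (length(tr) < 2L) next
    for (i in 2L:length(tr)) {
      if (tr$frame_index[i] - tr$frame_index[i - 1L] != 1L) next
      a <- tr$poses[[i - 1L]]; b <- tr$poses[[i]]
      vis <- a$visible & b$visible
      d <- sqrt(rowSums((b$coords - a$coords)^2))
      for (k in which(vis)) disp[[k]] <- c(disp[[k]], d[k])
    }
  }
  if (any(vapply(disp, length, 1L) == 0L))
    stop("calibration needs at least one consecutive visible pair per keypoint")
  stats::setNames(vapply(disp, stats::quantile, numeric(1L), probs = q,
                         names = FALSE, type = 7),
                  trajs[[1L]]$scheme$names)
}

#' Build one epoch of mixed batches
#'
#' Shuffles the labeled pool into batches of `batch_size`; each step
#' additionally carries one unlabeled clip window of `unlabeled_window`
#' frames when clips are available and at least one unsupervised weight is
#' nonzero (otherwise steps are purely supervised and no unlabeled RNG is
#' consumed, so a run with `alpha = beta = 0` matches a supervised-only run
#' step for step). Uses the current RNG stream.
#'
#' @param labeled integer vector of labeled sample indices (or a count).
#' @param clips list of clips (each a list of frames); may be empty.
#' @param cfg a [train_config()].
#' @return list of steps, each `list(labeled =, clip =, start =)`.
#' @export
make_mixed_batches <- function(labeled, clips, cfg) {
  if (length(labeled) == 1L && is.numeric(labeled) && labeled >= 1L)
    labeled <- seq_len(labeled)
  if (!length(labeled)) stop("labeled pool is empty")
  ord <- sample(labeled)
  steps <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
  use_unlab <- length(clips) > 0L &&
    (cfg$weights$alpha > 0 || cfg$weights$beta > 0)
  lapply(steps, function(idx) {
    if (!use_unlab) return(list(labeled = idx, clip = NA_integer_, start = NA_integer_))
    lens <- vapply(clips, length, 1L)
    ok <- which(lens >= cfg$unlabeled_window)
    if (!length(ok)) stop("no clip is long enough for the unlabeled window")
    j <- ok[sample.int(length(ok), 1L)]
    s <- sample.int(lens[j] - cfg$unlabeled_window + 1L, 1L)
    list(labeled = idx, clip = j, start = s)
  })
}

# labeled-frame prediction consistent with the training path: the temporal
# model sees a static five-frame window (the labeled frame replicated).
predict_labeled_fwd <- function(model, img) {
  fw <- frame_fwd(model, img)
  if (is.null(model$temporal)) {
    dec <- decode_coords(fw$raw, model$cfg$temperature)
    list(fw = fw, dec = dec, fuse_cache = NULL)
  } else {
    r <- bi_fuse_fwd(rep(list(fw$raw), 5L), model$temporal, model$cfg$K)
    list(fw = fw, dec = decode_coords(r$fused, model$cfg$temperature),
         fuse_cache = r$cache)
  }
}

#' Semi-supervised training
#'
#' Each optimizer step combines a supervised part (coordinate RMSE on a
#' batch of labeled frames; the temporal model sees each labeled frame as a
#' static five-frame window) with an unsupervised part: a sampled unlabeled
#' clip window whose interior-frame predictions feed the temporal continuity
#' loss on consecutive pairs and the pose plausibility loss on each pose.
#' The three terms are combined as
#' `L_total = L_RMSE + alpha * L_T + beta * L_P` and minimized with Adam;
#' the backbone is frozen (gradients zeroed, weights bit-identical) for the
#' first `freeze_epochs` epochs.
#'
#' The pose subspace is fitted once, before epoch 0, on the fully visible
#' labeled training poses and then frozen; if fewer than 2K valid poses are
#' available the covariance cannot be modeled (PCA precondition), the pose
#' term is disabled and this is recorded in the returned object. Temporal
#' thresholds come from `cfg$eps_t`, or are calibrated from
#' `data$clip_truth` reference trajectories.
#'
#' @param model a freshly built or resumed [build_model()].
#' @param data list with `labeled` (`images`, `truth`), `clips`, optional
#'   `clip_truth` -- the shape returned by [generate_dataset()].
#' @param cfg a [train_config()].
#' @return object of class `stc_fit`: `model` (final), `best_model` (lowest
#'   validation RMSE), `history` (one row per epoch: lr and the four loss
#'   components plus `val_rmse`), `val_idx`, `pose_loss_active`.
#' @export
train <- function(model, data, cfg = train_config()) {
  stopifnot(inherits(model, "stc_model"), inherits(cfg, "stc_train_config"))
  images <- data$labeled$images
  truth <- data$labeled$truth
  if (!length(images)) stop("labeled pool is empty")
  clips <- data$clips %||% list()
  set.seed(cfg$seed)
  n <- length(images)
  n_val <- max(1L, round(cfg$val_fraction * n))
  perm <- sample(n)
  val_idx <- sort(perm[seq_len(n_val)])
  train_idx <- sort(perm[-seq_len(n_val)])
  if (!length(train_idx)) stop("no labeled frames left for training")

  px <- unlist(lapply(images[train_idx], as.numeric))
  model$norm <- list(mean = mean(px), sd = max(stats::sd(px), 1e-6))

  w <- cfg$weights
  vecs <- lapply(truth[train_idx], flatten_pose)
  n_valid <- sum(vapply(vecs, function(v) v$valid, TRUE))
  pose_active <- w$beta > 0 && n_valid >= 2L * model$cfg$K
  if (pose_active) {
    model$subspace <- fit_subspace(vecs, scheme = model$scheme)
    model$subspace$eps_pose <- calibrate_eps_pose(model$subspace, vecs)
  } else if (w$beta > 0 && length(clips)) {
    message(sprintf(paste0("pose plausibility loss disabled: %d valid labeled poses ",
                           "< 2K = %d required for the PCA subspace"),
                    n_valid, 2L * model$cfg$K))
  }

  temporal_active <- w$alpha > 0 && length(clips) > 0L
  eps_t <- NULL
  if (temporal_active || length(clips)) {
    eps_t <- if (!is.null(cfg$eps_t)) check_eps_t(cfg$eps_t, model$cfg$K)
             else if (!is.null(data$clip_truth))
               calibrate_eps_temporal(data$clip_truth, cfg$eps_quantile)
    if (temporal_active && is.null(eps_t))
      stop("temporal loss needs eps_t: supply cfg$eps_t or data$clip_truth")
  }
  model$eps_t <- eps_t

  params <- model_get_params(model)
  opt <- adam_init(params)
  scale <- model$cfg$image_size / model$cfg$heatmap_size
  tau <- model$cfg$temperature
  K <- model$cfg$K
  use_temporal <- !is.null(model$temporal)

  hist <- vector("list", cfg$epochs)
  best_val <- Inf
  best_params <- params

  for (e in seq_len(cfg$epochs)) {
    lr <- lr_at(e - 1L, cfg)
    frozen <- e <= cfg$freeze_epochs
    steps <- make_mixed_batches(train_idx, clips, cfg)
    el <- c(rmse = 0, temporal = 0, pose = 0)
    for (st in steps) {
      grads <- tree_zeros(params)
      nb <- length(st$labeled)
      # supervised part
      for (i in st$labeled) {
        pf <- predict_labeled_fwd(model, images[[i]])
        sg <- supervised_rmse_grad(pf$dec$xy * scale, truth[[i]]$coords,
                                   truth[[i]]$visible)
        el["rmse"] <- el["rmse"] + sg$value / nb
        graw <- decode_coords_bwd(pf$dec, sg$grad * scale / nb, tau)
        if (use_temporal) {
          rb <- bi_fuse_bwd(pf$fuse_cache, model$temporal, graw)
          graw <- Reduce(`+`, rb$gframes)
          grads$temporal <- tree_add(grads$temporal, rb$grads)
        }
        fg <- frame_bwd(model, pf$fw, graw)
        grads$backbone <- tree_add(grads$backbone, fg$backbone)
        grads$head <- tree_add(grads$head, fg$head)
      }
      # unsupervised part
      if (!is.na(st$clip) && (temporal_active || pose_active)) {
        frames <- clips[[st$clip]][st$start:(st$start + cfg$unlabeled_window - 1L)]
        fws <- lapply(frames, function(f) frame_fwd(model, f))
        raws <- lapply(fws, `[[`, "raw")
        Tn <- length(frames)
        if (use_temporal) {
          centers <- 3L:(Tn - 2L)
          fuse <- lapply(centers, function(t)
            bi_fuse_fwd(raws[(t - 2L):(t + 2L)], model$temporal, K))
          decs <- lapply(fuse, function(r) decode_coords(r$fused, tau))
        } else {
          centers <- seq_len(Tn)
          decs <- lapply(raws, function(r) decode_coords(r, tau))
        }
        coords <- lapply(decs, function(d) d$xy * scale)
        np <- length(coords)
        gxy <- lapply(coords, function(x) x * 0)
        if (temporal_active && np >= 2L) {
          tl <- temporal_loss_grad(coords, eps_t)
          el["temporal"] <- el["temporal"] + tl$value
          gxy <- Map(function(g, a) g + w$alpha * a, gxy, tl$grads)
        }
        if (pose_active) {
          lp <- 0
          for (i in seq_len(np)) {
            pl <- pose_loss_grad(coords[[i]], model$subspace)
            lp <- lp + pl$value / np
            gxy[[i]] <- gxy[[i]] + w$beta * pl$grad / np
          }
          el["pose"] <- el["pose"] + lp
        }
        graw_frames <- lapply(raws, function(r) r * 0)
        for (i in seq_len(np)) {
          graw <- decode_coords_bwd(decs[[i]], gxy[[i]] * scale, tau)
          if (use_temporal) {
            rb <- bi_fuse_bwd(fuse[[i]]$cache, model$temporal, graw)
            grads$temporal <- tree_add(grads$temporal, rb$grads)
            idx <- (centers[i] - 2L):(centers[i] + 2L)
            for (s in 1:5)
              graw_frames[[idx[s]]] <- graw_frames[[idx[s]]] + rb$gframes[[s]]
          } else {
            graw_frames[[i]] <- graw_frames[[i]] + graw
          }
        }
        for (t in seq_len(Tn)) {
          if (all(graw_frames[[t]] == 0)) next
          fg <- frame_bwd(model, fws[[t]], graw_frames[[t]])
          grads$backbone <- tree_add(grads$backbone, fg$backbone)
          grads$head <- tree_add(grads$head, fg$head)
        }
      }
      if (frozen) grads$backbone <- tree_zeros(grads$backbone)
      r <- adam_step(params, grads, opt, lr)
      params <- r$params
      opt <- r$state
      model <- model_set_params(model, params)
    }
    ns <- length(steps)
    rep_ <- total_loss(el[["rmse"]] / ns, el[["temporal"]] / ns, el[["pose"]] / ns, w)
    if (!is.finite(rep_$l_total))
      stop(sprintf("training diverged at epoch %d (total loss %g)", e, rep_$l_total))
    val_rmse <- mean(vapply(val_idx, function(i) {
      pf <- predict_labeled_fwd(model, images[[i]])
      supervised_rmse(pose(pf$dec$xy * scale, model$scheme), truth[[i]])
    }, numeric(1L)))
    hist[[e]] <- data.frame(epoch = e, lr = lr, l_rmse = rep_$l_rmse,
                            l_temporal = rep_$l_temporal, l_pose = rep_$l_pose,
                            l_total = rep_$l_total, val_rmse = val_rmse)
    if (val_rmse < best_val) {
      best_val <- val_rmse
      best_params <- params
    }
  }
  structure(list(model = model,
                 best_model = model_set_params(model, best_params),
                 history = do.call(rbind, hist),
                 val_idx = val_idx,
                 pose_loss_active = pose_active,
                 cfg = cfg),
            class = "stc_fit")
}

#' @export
print.stc_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<stc_fit> %d epochs, final total loss %.4f, best val RMSE %.3f px\n",
              nrow(x$history), last$l_total, min(x$history$val_rmse)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
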