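test_that("the learning-rate schedule halves at each milestone", {
  cfg <- train_config()
  expect_equal(lr_at(0, cfg), 0.001)
  expect_equal(lr_at(149, cfg), 0.001)
  expect_equal(lr_at(150, cfg), 0.0005)
  expect_equal(lr_at(160, cfg), 0.0005)
  expect_equal(lr_at(260, cfg), 0.000125)
  expect_error(lr_at(-1, cfg), "non-negative")
  expect_error(train_config(milestones = c(200L, 150L)), "ascending")
  expect_error(train_config(unlabeled_window = 4L), "at least 6")
})

test_that("temporal thresholds are per-keypoint displacement quantiles", {
  static <- displacement_traj(c(0, 0, 0, 0))
  expect_equal(unname(calibrate_eps_temporal(static, q = 0.95)), 0)

  tr <- displacement_traj(c(1, 2, 3, 4, 100))
  expect_equal(unname(calibrate_eps_temporal(tr, q = 0.5)), 3)  # order-statistic oracle

  # per-keypoint equivariance under keypoint permutation
  set.seed(40)
  sch <- scheme3
  mk <- function(order) {
    poses <- lapply(0:5, function(t)
      pose(cbind(c(1, 3, 10)[order] * t, 0 * order), sch))
    trajectory(poses)
  }
  e1 <- calibrate_eps_temporal(mk(1:3))
  e2 <- calibrate_eps_temporal(mk(c(3, 1, 2)))
  expect_equal(unname(e2), unname(e1[c(3, 1, 2)]))

  expect_error(calibrate_eps_temporal(displacement_traj(numeric(0))),
               "consecutive")
})

test_that("mixed batches cover the labeled pool and are seed-deterministic", {
  cfg <- train_config(batch_size = 6L)
  clips <- list(as.list(1:10), as.list(1:8))
  set.seed(1)
  steps <- make_mixed_batches(12L, clips, cfg)
  expect_length(steps, 2L)
  expect_setequal(unlist(lapply(steps, `[[`, "labeled")), 1:12)
  expect_true(all(!is.na(vapply(steps, `[[`, 1L, "clip"))))

  set.seed(1)
  steps2 <- make_mixed_batches(12L, clips, cfg)
  expect_identical(steps, steps2)

  # alpha = beta = 0: no unlabeled sampling at all
  cfg0 <- train_config(batch_size = 6L, weights = loss_weights(0, 0))
  set.seed(1)
  steps0 <- make_mixed_batches(12L, clips, cfg0)
  expect_true(all(is.na(vapply(steps0, `[[`, 1L, "clip"))))
  expect_identical(lapply(steps0, `[[`, "labeled"), lapply(steps, `[[`, "labeled"))

  expect_error(make_mixed_batches(integer(), clips, cfg), "empty")
})

make_train_data <- function(n_labeled = 10L, n_clips = 1L, seed = 5) {
  generate_dataset(sim_config(n_labeled = n_labeled, n_clips = n_clips,
                              clip_seconds = 1, frame_rate = 8,
                              image_size = 32L),
                   seed = seed)
}

test_that("the backbone stays bit-identical while frozen", {
  ds <- make_train_data()
  set.seed(50)
  m <- build_model(model_config("tiny", image_size = 32L), ds$scheme)
  before <- stcpose:::layers_get_params(m$backbone)
  fit <- train(m, ds, train_config(epochs = 1L, freeze_epochs = 20L,
                                   batch_size = 5L, seed = 2L))
  after <- stcpose:::layers_get_params(fit$model$backbone)
  expect_identical(after, before)
  head_after <- stcpose:::layers_get_params(fit$model$head)
  expect_gt(stcpose:::tree_sq_norm(stcpose:::tree_map2(`-`, head_after,
            stcpose:::layers_get_params(m$head))), 0)
})

test_that("alpha = beta = 0 reduces to the purely supervised run, step for step", {
  ds <- make_train_data()
  build <- function() {
    set.seed(51)
    build_model(model_config("tiny", image_size = 32L), ds$scheme)
  }
  cfg0 <- train_config(epochs = 2L, freeze_epochs = 0L, batch_size = 5L,
                       weights = loss_weights(0, 0), seed = 3L)
  fit_mixed <- train(build(), ds, cfg0)
  ds_sup <- ds; ds_sup$clips <- list(); ds_sup$clip_truth <- NULL
  fit_sup <- train(build(), ds_sup, cfg0)
  expect_equal(fit_mixed$history, fit_sup$history, tolerance = 1e-12)
  expect_identical(stcpose:::model_get_params(fit_mixed$model),
                   stcpose:::model_get_params(fit_sup$model))
  expect_equal(fit_mixed$history$l_temporal, c(0, 0))
  expect_equal(fit_mixed$history$l_pose, c(0, 0))
})

test_that("training history satisfies the total-loss bookkeeping identity", {
  ds <- make_train_data(n_labeled = 8L)
  set.seed(52)
  m <- build_model(model_config("tiny", image_size = 32L, use_temporal = TRUE,
                                rnn_hidden = 2L), ds$scheme)
  fit <- train(m, ds, train_config(epochs = 2L, freeze_epochs = 0L,
                                   batch_size = 4L, seed = 4L))
  h <- fit$history
  expect_equal(h$l_total, h$l_rmse + 1 * h$l_temporal + 1 * h$l_pose,
               tolerance = 1e-9)
  expect_true(all(is.finite(h$val_rmse)))
  # reproducibility: same seed and config, same histories
  set.seed(52)
  m2 <- build_model(model_config("tiny", image_size = 32L, use_temporal = TRUE,
                                 rnn_hidden = 2L), ds$scheme)
  fit2 <- train(m2, ds, train_config(epochs = 2L, freeze_epochs = 0L,
                                     batch_size = 4L, seed = 4L))
  expect_identical(fit$history, fit2$history)
})

test_that("the pose term is disabled below the PCA sample-size precondition", {
  ds <- make_train_data(n_labeled = 10L)   # 8 training poses < 2K = 42
  set.seed(53)
  m <- build_model(model_config("tiny", image_size = 32L), ds$scheme)
  expect_message(
    fit <- train(m, ds, train_config(epochs = 1L, batch_size = 5L, seed = 5L)),
    "disabled")
  expect_false(fit$pose_loss_active)
  expect_equal(fit$history$l_pose, 0)
})
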