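fd_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("supervised RMSE matches hand-computed distances and masks truth", {
  p <- pose(matrix(c(3, 4), 1L, 2L), keypoint_scheme("p"))
  t0 <- pose(matrix(c(0, 0), 1L, 2L), keypoint_scheme("p"))
  expect_equal(supervised_rmse(p, p), 0, tolerance = 1e-6)
  expect_equal(supervised_rmse(p, t0), 5, tolerance = 1e-6)

  pr <- pose(matrix(c(3, 10, 4, 20), 2L, 2L), scheme2)     # offsets (3,4), (0,0)
  tr <- pose(matrix(c(0, 10, 0, 20), 2L, 2L), scheme2)
  expect_equal(supervised_rmse(pr, tr), sqrt(25 / 2), tolerance = 1e-6)

  # invisible truth keypoints drop out entirely
  tr2 <- pose(matrix(c(0, 99, 0, 99), 2L, 2L), scheme2, visible = c(TRUE, FALSE))
  expect_equal(supervised_rmse(pr, tr2), 5, tolerance = 1e-6)
  tr3 <- pose(matrix(c(0, 0, 0, 0), 2L, 2L), scheme2, visible = c(FALSE, FALSE))
  expect_error(supervised_rmse(pr, tr3), "no visible")
})

test_that("temporal loss implements the per-keypoint displacement hinge", {
  static <- displacement_traj(c(0, 0, 0))
  expect_equal(temporal_loss(static, 3), 0)
  one_step <- displacement_traj(5)
  expect_equal(temporal_loss(one_step, 3), 2, tolerance = 1e-6)
  inside <- displacement_traj(c(1, 2.5, 0.5))
  expect_equal(temporal_loss(inside, 3), 0)
  expect_error(temporal_loss(displacement_traj(numeric(0)), 3), "two frames")
})

test_that("pose loss vanishes in-subspace and passes displacement through at eps 0", {
  d <- rank2_data()
  m <- fit_subspace(d$X)
  m$eps_pose <- 0
  y_in <- m$mu + drop(m$components %*% c(1.5, -2))
  expect_equal(pose_loss(y_in, m), 0, tolerance = 1e-6)

  # K = 1 degenerate model: identical poses, R = 0, reconstruction = mu
  X1 <- matrix(rep(c(5, 5), 4), 4, 2, byrow = TRUE)
  m1 <- fit_subspace(X1)
  m1$eps_pose <- 0
  expect_equal(pose_loss(c(5 + 3, 5 + 4), m1), 5, tolerance = 1e-6)

  # hinge inputs equal per-keypoint reconstruction errors from the SVD oracle
  set.seed(12)
  y <- rnorm(8, sd = 6) + d$mu0
  mu <- colMeans(d$X); Xc <- sweep(d$X, 2, mu); V <- svd(Xc)$v[, 1:2]
  rec <- drop((y - mu) %*% V %*% t(V)) + mu
  err_k <- sqrt(colSums(matrix((y - rec)^2, 2L)))
  expect_equal(pose_loss(y, m), mean(err_k), tolerance = 1e-6)
})

test_that("total loss is the weighted sum with ablatable terms", {
  r <- total_loss(2, 3, 4, loss_weights(1, 1))
  expect_equal(r$l_total, 9)
  expect_equal(total_loss(2, 3, 4, loss_weights(1, 0))$l_total, 5)
  r2 <- total_loss(2, 3, 4, loss_weights(2, 1))
  expect_equal(r2$l_total - r$l_total, 3)          # doubling alpha adds one l_t
  expect_equal(r$l_total, r$l_rmse + r$alpha * r$l_temporal + r$beta * r$l_pose,
               tolerance = 1e-9)
  expect_error(loss_weights(-1, 1), "non-negative")
})

test_that("hinges are non-negative, flat in the dead zone, 1-Lipschitz beyond", {
  eps <- 2
  d <- seq(0, 6, by = 0.25)
  vals <- vapply(d, function(x) temporal_loss(displacement_traj(x), eps), numeric(1))
  expect_true(all(vals >= 0))
  expect_true(all(vals[d <= eps - 1e-6] == 0))
  slopes <- diff(vals) / diff(d)
  expect_true(all(slopes <= 1 + 1e-9))
  expect_equal(vals[d == 6], 4, tolerance = 1e-6)
})

test_that("analytic gradients match finite differences, vanishing in dead zones", {
  set.seed(13)
  # supervised
  pr <- matrix(runif(8, 0, 20), 4L, 2L)
  tr <- matrix(runif(8, 0, 20), 4L, 2L)
  vis <- c(TRUE, TRUE, FALSE, TRUE)
  g <- stcpose:::supervised_rmse_grad(pr, tr, vis)
  gn <- fd_grad(function(x) stcpose:::supervised_rmse_grad(x, tr, vis)$value, pr)
  expect_equal(g$grad, gn, tolerance = 1e-5)

  # temporal: active and dead-zone terms
  coords <- lapply(1:3, function(i) matrix(runif(4, 0, 30), 2L, 2L))
  tg <- stcpose:::temporal_loss_grad(coords, 1)
  for (t in 1:3) {
    gn <- fd_grad(function(x) {
      cc <- coords; cc[[t]] <- x
      stcpose:::temporal_loss_grad(cc, 1)$value
    }, coords[[t]])
    expect_equal(tg$grads[[t]], gn, tolerance = 1e-5)
  }
  tg0 <- stcpose:::temporal_loss_grad(coords, 1e5)     # everything in dead zone
  expect_true(all(vapply(tg0$grads, function(g) all(g == 0), TRUE)))

  # pose
  d <- rank2_data()
  m <- fit_subspace(d$X)
  m$eps_pose <- 0.5
  xy <- matrix(runif(8, 0, 50), 4L, 2L, byrow = TRUE)
  pg <- stcpose:::pose_loss_grad(xy, m)
  gn <- fd_grad(function(x) stcpose:::pose_loss_grad(x, m)$value, xy)
  expect_equal(pg$grad, gn, tolerance = 1e-5)
  y_in <- matrix(m$mu + drop(m$components %*% c(1, 1)), 4L, 2L, byrow = TRUE)
  expect_true(all(stcpose:::pose_loss_grad(y_in, m)$grad == 0))
})

test_that("temporal loss is translation-invariant; pose loss is not", {
  set.seed(14)
  sch <- scheme3
  poses <- lapply(1:4, function(i) random_pose(sch, 30))
  tr <- trajectory(poses)
  shifted <- trajectory(lapply(poses, function(p)
    pose(p$coords + matrix(c(7, -4), sch$K, 2L, byrow = TRUE), sch)))
  expect_equal(temporal_loss(tr, 2), temporal_loss(shifted, 2), tolerance = 1e-9)

  d <- rank2_data()                        # K = 4
  m <- fit_subspace(d$X)
  m$eps_pose <- 0
  y <- d$X[3, ]
  y_shift <- y + rep(c(7, -4), 4)
  expect_equal(pose_loss(y, m), 0, tolerance = 1e-6)
  expect_gt(pose_loss(y_shift, m), 0.1)
})
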