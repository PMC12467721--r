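# Shared fixtures, all built in code.

scheme2 <- keypoint_scheme(c("a", "b"))
scheme3 <- keypoint_scheme(c("a", "b", "c"))
scheme4 <- keypoint_scheme(c("a", "b", "c", "d"))

random_pose <- function(scheme, range = 50) {
  pose(matrix(runif(2 * scheme$K, 0, range), scheme$K, 2L), scheme)
}

# trajectory of a single keypoint moving along x by the given displacements
displacement_traj <- function(disp) {
  s1 <- keypoint_scheme("p")
  xs <- cumsum(c(10, disp))
  trajectory(lapply(xs, function(x) pose(matrix(c(x, 20), 1L, 2L), s1)))
}

# small deterministic model for estimator tests
tiny_model <- function(seed = 42, K = 3L, use_temporal = FALSE, image = 32L) {
  set.seed(seed)
  sch <- keypoint_scheme(letters[seq_len(K)])
  build_model(model_config("tiny", image_size = image, K = K,
                           use_temporal = use_temporal, rnn_hidden = 4L),
              scheme = sch)
}

# exactly rank-2 pose data plus a pose displaced off-subspace at one keypoint
rank2_data <- function(K = 4L, n = 30L, seed = 7) {
  set.seed(seed)
  d <- 2L * K
  mu0 <- runif(d, 20, 40)
  v1 <- c(1, rep(0, d - 1L))
  v2 <- c(0, 1, rep(0, d - 2L))
  t1 <- rnorm(n, sd = 4); t2 <- rnorm(n, sd = 3)
  X <- t(vapply(seq_len(n), function(i) mu0 + t1[i] * v1 + t2[i] * v2,
                numeric(d)))
  list(X = X, mu0 = mu0, v1 = v1, v2 = v2)
}
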