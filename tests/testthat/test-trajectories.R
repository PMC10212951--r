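# build a rate_tensor directly from an array (bypassing spike data)
toy_tensor <- function(values, centers, trials) {
  structure(list(values = values, bin_centers_ms = centers,
                 window_ms = 100, step_ms = 100, trials = trials),
            class = "rate_tensor")
}

toy_trials <- function(stimulus, category = "a") {
  data.frame(trial_id = seq_along(stimulus), stimulus_id = stimulus,
             category = category, ramp_ms = 0, intensity = 1,
             plateau_ms = 500)
}

test_that("PCA recovers a single-axis structure and an orthonormal basis", {
  set.seed(1)
  x <- matrix(0, 5, 100)
  x[2, ] <- rnorm(100, sd = 3)   # variance only along channel 2
  p <- suppressWarnings(pca_fit(x))
  expect_equal(abs(p$basis[2, 1]), 1, tolerance = 1e-9)
  expect_equal(p$eigenvalues[2], 0, tolerance = 1e-9)
  y <- matrix(rnorm(20 * 500), 20)
  p2 <- pca_fit(y)
  expect_lt(max(abs(crossprod(p2$basis) - diag(3))), 1e-10)
  # variance captured by the projection equals the top-3 eigenvalue sum
  proj <- t(y - rowMeans(y)) %*% p2$basis
  expect_equal(sum(apply(proj, 2, stats::var)), sum(p2$eigenvalues[1:3]),
               tolerance = 1e-8)
  expect_warning(pca_fit(matrix(rnorm(8), 4, 2)), "rank")
})

test_that("mean trajectory equals the projection of the mean (linearity)", {
  set.seed(2)
  vals <- array(rnorm(6 * 5 * 40, 10), c(6, 5, 40))
  rt <- toy_tensor(vals, seq(-150, 240, by = 10), toy_trials(rep(1:2, 3)))
  flat <- matrix(aperm(vals, c(2, 1, 3)), 5)
  basis <- pca_fit(flat)
  ts <- build_trajectories(rt, basis, baseline_window_ms = c(-150, 0),
                           endpoint_ms = 100)
  for (cond in ts$conditions) {
    idx <- NULL
    expect_equal(dim(cond$trajectory), c(40L, 3L))
  }
  m1 <- apply(vals[c(1, 3, 5), , , drop = FALSE], c(2, 3), mean)
  expect_equal(ts$conditions[[1]]$trajectory, t(m1) %*% basis$basis,
               tolerance = 1e-10)
  # identical trials: zero covariance
  vals2 <- vals
  for (tr in 2:6) vals2[tr, , ] <- vals2[1, , ]
  rt2 <- toy_tensor(vals2, seq(-150, 240, by = 10), toy_trials(rep(1, 6)))
  ts2 <- build_trajectories(rt2, basis, baseline_window_ms = c(-150, 0),
                            endpoint_ms = 100)
  expect_equal(max(abs(ts2$conditions[[1]]$baseline_cov)), 0, tolerance = 1e-12)
})

test_that("covariance ellipsoids have the right semi-axes", {
  mesh <- covariance_ellipsoid(diag(3), scale = 0.5)
  expect_equal(range(sqrt(rowSums(mesh^2))), c(0.5, 0.5), tolerance = 1e-9)
  # odd tessellation so the equator (the x/y extremes) lies on the grid
  mesh2 <- covariance_ellipsoid(diag(c(4, 1, 1)), scale = 0.5, n = 21)
  expect_equal(max(abs(mesh2[, 1])), 1, tolerance = 1e-9)
  expect_equal(max(abs(mesh2[, 2])), 0.5, tolerance = 1e-9)
  mesh3 <- covariance_ellipsoid(matrix(0, 3, 3), center = c(1, 2, 3))
  expect_equal(max(abs(sweep(mesh3, 2, c(1, 2, 3)))), 0)
  bad <- diag(c(1, 1, -1))
  expect_error(covariance_ellipsoid(bad), "semi-definite")
  expect_error(covariance_ellipsoid(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("native-space distances reproduce a 3-4-5 construction", {
  # two channels, two stimuli; at the probe bin the stimulus means differ
  # by the vector (3, 4)
  vals <- array(0, c(4, 2, 3))
  vals[, , 1] <- 0                      # pre-stimulus baseline bin
  vals[1:2, 1, 3] <- 0; vals[1:2, 2, 3] <- 0
  vals[3:4, 1, 3] <- 3; vals[3:4, 2, 3] <- 4
  rt <- toy_tensor(vals, c(-50, 50, 150), toy_trials(c(1, 1, 2, 2)))
  ds <- distance_series(rt, baseline_window_ms = c(-100, 0))
  expect_equal(ds$separation[ds$time_ms == 150], 5)
  expect_equal(ds$separation[ds$time_ms == -50], 0)
  expect_equal(ds$dist_to_baseline[ds$time_ms == -50], 0)
  # identical stimuli -> zero separation everywhere
  rt_same <- toy_tensor(vals[c(1, 2, 1, 2), , ], c(-50, 50, 150),
                        toy_trials(c(1, 1, 2, 2)))
  ds2 <- distance_series(rt_same, baseline_window_ms = c(-100, 0))
  expect_true(all(ds2$separation == 0))
})

test_that("discriminability index approaches the theoretical ratio", {
  set.seed(3)
  n <- 4000
  vals <- array(rnorm(2 * n, rep(c(0, 10), each = n)), c(2 * n, 1, 1))
  rt <- toy_tensor(vals, 100, toy_trials(rep(1:2, each = n)))
  di <- discriminability_index(rt)
  expect_equal(di$index, 10, tolerance = 0.05)
  expect_equal(di$separation, 10, tolerance = 0.1)
})

test_that("the index is scale- and permutation-invariant and zero for equal means", {
  set.seed(4)
  vals <- array(rnorm(8 * 6 * 10, 20, 2), c(8, 6, 10))
  rt <- toy_tensor(vals, seq(50, 950, 100), toy_trials(rep(1:2, each = 4)))
  di <- discriminability_index(rt)
  rt_scaled <- rt; rt_scaled$values <- rt$values * 7.3
  expect_equal(discriminability_index(rt_scaled)$index, di$index,
               tolerance = 1e-12)
  perm <- sample(6)
  rt_perm <- rt; rt_perm$values <- rt$values[, perm, ]
  expect_equal(discriminability_index(rt_perm)$index, di$index,
               tolerance = 1e-12)
  # equal stimulus means in expectation: index near 0 at large n
  valsz <- array(rep(c(5, 9), each = 2 * 400 * 3), c(800, 2, 3)) * 0 + 5
  rtz <- toy_tensor(valsz, c(100, 200, 300), toy_trials(rep(1:2, each = 400)))
  diz <- discriminability_index(rtz)
  expect_true(all(is.na(diz$index)))  # zero variability -> undefined, recorded
  expect_true(all(diz$separation == 0))
})

test_that("pooled and per-stimulus variability conventions are both available", {
  set.seed(5)
  vals <- array(rnorm(20 * 4 * 5, 15, c(1, 3)), c(20, 4, 5))
  rt <- toy_tensor(vals, seq(100, 500, 100), toy_trials(rep(1:2, each = 10)))
  a <- discriminability_index(rt, variability = "per_stimulus")
  b <- discriminability_index(rt, variability = "pooled")
  expect_equal(a$separation, b$separation)
  expect_false(isTRUE(all.equal(a$index, b$index)))
  expect_error(discriminability_index(toy_tensor(vals, seq(100, 500, 100),
                                                 toy_trials(rep(1, 20)))),
               "single stimulus")
})

test_that("distances in the data's own span survive projection (isometry)", {
  set.seed(6)
  # data confined to a 3-D subspace of 10 channels
  basis3 <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
  coords <- array(rnorm(12 * 3 * 8, 5), c(12, 3, 8))
  vals <- array(0, c(12, 10, 8))
  for (tr in 1:12) vals[tr, , ] <- basis3 %*% coords[tr, , ]
  rt <- toy_tensor(vals, seq(50, 750, 100), toy_trials(rep(1:2, each = 6)))
  flat <- matrix(aperm(vals, c(2, 1, 3)), 10)
  p <- pca_fit(flat)
  ds <- distance_series(rt, baseline_window_ms = c(-100, 50))
  # projected separation equals native separation
  m1 <- apply(vals[1:6, , ], c(2, 3), mean)
  m2 <- apply(vals[7:12, , ], c(2, 3), mean)
  native <- sqrt(colSums((m1 - m2)^2))
  proj <- sqrt(colSums((t(p$basis) %*% (m1 - m2))^2))
  expect_equal(proj, native, tolerance = 1e-8)
})
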