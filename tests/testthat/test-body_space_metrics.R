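test_that("trial covariance matches the double-loop textbook oracle", {
  set.seed(20)
  w <- matrix(rnorm(40 * 4), 40, 4)
  cv <- trial_covariance(w)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    oracle[i, j] <- sum((w[, i] - mean(w[, i])) *
                        (w[, j] - mean(w[, j]))) / (nrow(w) - 1)
  }
  expect_equal(cv, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  two <- cbind(a = w[, 1], b = w[, 1])
  cv2 <- trial_covariance(two)
  expect_true(all(abs(cv2 - cv2[1, 1]) < 1e-12))

  # adding a constant to a channel leaves covariance unchanged
  w2 <- w; w2[, 2] <- w2[, 2] + 100
  expect_equal(trial_covariance(w2), cv, tolerance = 1e-12)

  expect_error(trial_covariance(w[1, , drop = FALSE]), "2 samples")
})

test_that("generalized variance equals the eigen/determinant oracles", {
  expect_equal(generalized_variance(diag(6)), 1)

  set.seed(21)
  for (d in c(3, 6, 12)) {
    A <- matrix(rnorm(d * d), d)
    spd <- crossprod(A) + diag(d) * 0.1
    gv <- generalized_variance(spd)
    expect_equal(gv, prod(eigen(spd, symmetric = TRUE)$values),
                 tolerance = 1e-9)
    expect_equal(gv, det(spd), tolerance = 1e-9)  # LU route as oracle
  }

  # scaling data by c multiplies GV by c^(2d)
  w <- matrix(rnorm(50 * 3), 50, 3)
  g1 <- generalized_variance(trial_covariance(w))
  g2 <- generalized_variance(trial_covariance(2 * w))
  expect_equal(g2 / g1, 2^(2 * 3), tolerance = 1e-9)

  asym <- matrix(c(1, 2, 0, 1), 2, 2)
  expect_error(generalized_variance(asym), "not symmetric")
})

test_that("PC spectrum is a sorted unit-sum fraction vector", {
  # rank-1 data -> (1, 0, ...)
  u <- rnorm(30)
  w1 <- outer(u, c(1, 2, -1))
  s1 <- pc_spectrum(w1)
  expect_equal(s1[1], 1, tolerance = 1e-9)
  expect_equal(sum(s1), 1, tolerance = 1e-9)

  # constructed covariance with eigenvalues 4, 1 -> fractions 0.8, 0.2
  s2 <- pc_spectrum(diag(c(4, 1)))
  expect_equal(s2, c(0.8, 0.2), tolerance = 1e-9)

  # property: non-negative, descending, unit sum on random windows
  set.seed(22)
  for (i in 1:10) {
    s <- pc_spectrum(matrix(rnorm(60 * 5), 60, 5))
    expect_true(all(s >= 0))
    expect_true(all(diff(s) <= 1e-12))
    expect_equal(sum(s), 1, tolerance = 1e-9)
  }

  z <- pc_spectrum(matrix(1, 10, 3))
  expect_true(all(is.na(z)))
  expect_equal(attr(z, "flag"), "zero_variance")
})

test_that("DoF count applies a strict 1% threshold", {
  expect_equal(dof_count(c(1, 0, 0)), 1)
  expect_equal(dof_count(c(0.90, 0.05, 0.03, 0.011, 0.009)), 4)
  # monotone non-increasing in the threshold
  s <- c(0.6, 0.2, 0.1, 0.06, 0.04)
  counts <- vapply(c(0.005, 0.01, 0.05, 0.15), dof_count,
                   numeric(1), spectrum = s)
  expect_true(all(diff(counts) <= 0))
})

test_that("manipulative complexity meets its boundary conditions", {
  for (strategy in c("participation_ratio", "entropy")) {
    expect_equal(manipulative_complexity(rep(1 / 6, 6), strategy), 1)
    expect_equal(manipulative_complexity(c(1, 0, 0, 0, 0, 0), strategy), 0)
  }
  # participation ratio by hand: (0.5, 0.5, 0, 0) -> PR = 2, C = 1/3
  expect_equal(manipulative_complexity(c(0.5, 0.5, 0, 0)), 1 / 3,
               tolerance = 1e-12)
  expect_error(manipulative_complexity(c(1)), "length >= 2")
  expect_error(manipulative_complexity(c(0.7, 0.7)), "summing to 1")
})

test_that("dof count and complexity are scale-invariant; GV is not", {
  set.seed(23)
  w <- matrix(rnorm(61 * 6), 61, 6) %*% diag(c(4, 2, 1, 0.5, 0.1, 0.05))
  m1 <- body_metrics(w)
  m2 <- body_metrics(3.7 * w)
  expect_equal(m2$dof_count, m1$dof_count)
  expect_equal(m2$complexity, m1$complexity, tolerance = 1e-9)
  expect_equal(m2$gv / m1$gv, 3.7^(2 * 6), tolerance = 1e-6)
})

test_that("VPE equals the brute-force double loop and handles self-match", {
  set.seed(24)
  nch <- 4; len <- 61
  mk <- function() {
    m <- matrix(rnorm(len * nch), len, nch)
    colnames(m) <- paste0("ch", 1:nch)
    m
  }
  trial <- mk()
  lib <- replicate(5, mk(), simplify = FALSE)

  vpe <- velocity_profile_error(trial, lib, exclude_self = FALSE)
  oracle <- vapply(1:nch, function(j) {
    ds <- vapply(lib, function(w) 1 - cor(trial[, j], w[, j]), numeric(1))
    min(ds)
  }, numeric(1))
  expect_equal(unname(vpe), oracle, tolerance = 1e-12)
  expect_true(all(vpe >= 0 & vpe <= 2))

  # trial identical to a library member -> 0 everywhere (literal reading)
  lib2 <- c(lib, list(trial))
  expect_equal(unname(velocity_profile_error(trial, lib2,
                                             exclude_self = FALSE)),
               rep(0, nch), tolerance = 1e-12)
  # excluding the self-match restores the informative distances
  expect_equal(unname(velocity_profile_error(trial, lib2,
                                             exclude_self = TRUE)),
               oracle, tolerance = 1e-12)

  # single anti-correlated library profile -> VPE = 2
  neg <- velocity_profile_error(trial, list(-trial),
                                exclude_self = FALSE)
  expect_equal(unname(neg), rep(2, nch), tolerance = 1e-12)

  expect_error(velocity_profile_error(trial, list(trial),
                                      exclude_self = TRUE),
               "empty")

  # zero-variance channel flagged NA
  flat <- trial; flat[, 2] <- 1
  v <- velocity_profile_error(flat, lib, exclude_self = FALSE)
  expect_true(is.na(v[2]))
  expect_false(anyNA(v[-2]))
})

test_that("VPE block variability is a robust per-channel scale", {
  const <- matrix(0.5, 25, 3, dimnames = list(NULL, paste0("c", 1:3)))
  expect_equal(unname(vpe_block_variability(const)), rep(0, 3))

  set.seed(25)
  big <- matrix(1 + rnorm(1e4 * 2, 0, 0.1), 1e4, 2)
  v <- vpe_block_variability(big)
  expect_true(all(abs(v - 0.1) < 0.01))

  # permutation of trials leaves the result unchanged
  blk <- matrix(runif(25 * 3), 25, 3)
  expect_equal(vpe_block_variability(blk[sample(25), ]),
               vpe_block_variability(blk))
})

test_that("synthetic cohorts reproduce the shoulder-to-elbow variance shift", {
  # one cohort here (the multi-cohort sign test runs in the acceptance
  # suite): block 1 vs block 9 channel variances
  cfg <- cohort_config(n_subjects = 1, seed = 26)
  sp <- default_stage_params(cfg)
  chan_var <- function(trial) {
    set.seed(trial * 1000 + 26)
    k <- generate_trial_kinematics(trial, cfg, sp)
    w <- prepare_trial(k)$window
    apply(w, 2, var)
  }
  v1 <- rowMeans(vapply(1:25, chan_var, numeric(51)))
  v9 <- rowMeans(vapply(201:225, chan_var, numeric(51)))
  sh <- segment_channels("right_shoulder")
  expect_true(all(v9[sh] < v1[sh]))
  expect_gt(v9["right_elbow_y"], v1["right_elbow_y"])
})
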