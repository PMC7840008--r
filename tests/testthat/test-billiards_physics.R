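test_that("strike estimate pools the 10 pre-contact frames robustly", {
  # 10 frames at 90 Hz span ~0.111 s
  st <- cue_stream(v = c(1, 0), rate = 90, n = 30)
  expect_equal(st$timestamps[11] - st$timestamps[1], 10 / 90,
               tolerance = 1e-12)

  est <- estimate_strike(st, contact_time = st$timestamps[30])
  expect_equal(est$speed, 1, tolerance = 1e-12)
  expect_equal(est$direction, c(1, 0), tolerance = 1e-12)

  # one corrupted frame: estimate equals the sort-and-pick median oracle
  st2 <- cue_stream(v = c(1.2, 0.4), rate = 90, n = 15)
  st2$tip_positions[8, ] <- st2$tip_positions[8, ] + c(0.05, -0.03)
  contact <- st2$timestamps[15]
  est2 <- estimate_strike(st2, contact)
  dt <- diff(st2$timestamps[5:15])
  vel <- diff(st2$tip_positions[5:15, ]) / dt
  oracle <- apply(vel, 2, function(col) sort(col)[c(5, 6)])
  med <- colMeans(oracle)  # even-length median = mean of middle two
  expect_equal(est2$velocity, med, tolerance = 1e-12)
  expect_equal(est2$speed, sqrt(sum(med^2)), tolerance = 1e-12)

  expect_error(estimate_strike(cue_stream(n = 5), 1), "insufficient data")
})

test_that("aimed shots pocket the ball; deflected shots miss", {
  tab <- table_geometry()
  sh <- simulate_shot(aim_strike(tab), tab)
  expect_lt(sh$outcome$abs_error_deg, 0.01)
  expect_true(sh$outcome$success)

  off <- simulate_shot(aim_strike(tab, bearing_deg = 40), tab)
  expect_false(off$outcome$success)
  expect_gt(off$outcome$abs_error_deg, 5)
})

test_that("free roll stops at v^2 / (2a) and below the stop threshold", {
  tab <- table_geometry(target_start = c(1.0, 2.0))  # out of the cue's way
  params <- list(friction_decel = 0.5, dt = 1 / 360,
                 stop_threshold = 0.02)
  strike <- list(speed = 1.2, direction = c(0, 1))
  sh <- simulate_shot(strike, tab, params)
  path <- sh$cue_path
  travelled <- sqrt(sum((unlist(path[nrow(path), c("x", "y")]) -
                         tab$cue_start)^2))
  expect_equal(travelled, 1.2^2 / (2 * 0.5),
               tolerance = 1.2 * params$dt / travelled)
  # terminates only below the stop threshold
  last_v <- sqrt(sum((unlist(path[nrow(path), c("x", "y")]) -
                      unlist(path[nrow(path) - 1, c("x", "y")]))^2)) /
    (path$t[nrow(path)] - path$t[nrow(path) - 1])
  expect_lt(last_v, 0.02 + 0.5 * params$dt)

  expect_error(
    simulate_shot(list(speed = 50, direction = c(0, 1)), tab,
                  list(dt = 0.1)),
    "resolution error")
})

test_that("collision resolution obeys line-of-centres transfer laws", {
  set.seed(42)
  for (i in 1:25) {
    v1 <- rnorm(2); v2 <- c(0, 0)
    n <- rnorm(2); n <- n / sqrt(sum(n^2))
    if (sum(v1 * n) <= 0) n <- -n
    out <- evrlearn:::collide_balls(v1, v2, n, restitution = 1)
    # target velocity parallel to the line of centres
    cross <- abs(out$v2[1] * n[2] - out$v2[2] * n[1])
    expect_lt(cross / sqrt(sum(out$v2^2)), 1e-9)
    # energy along the line of centres conserved for e = 1, equal masses
    pre <- sum(v1 * n)^2 + sum(v2 * n)^2
    post <- sum(out$v1 * n)^2 + sum(out$v2 * n)^2
    expect_equal(post, pre, tolerance = 1e-9)
    # momentum along n conserved for any e
    e <- runif(1)
    oute <- evrlearn:::collide_balls(v1, v2, n, restitution = e)
    expect_equal(sum(oute$v1 * n) + sum(oute$v2 * n), sum(v1 * n),
                 tolerance = 1e-12)
  }
})

test_that("simulated target launch is parallel to the line of centres", {
  tab <- table_geometry()
  sh <- simulate_shot(aim_strike(tab, bearing_deg = 35), tab)
  ct <- sh$contact_time
  i <- which(sh$target_path$t == ct)
  n <- c(sh$target_path$x[i] - sh$cue_path$x[i],
         sh$target_path$y[i] - sh$cue_path$y[i])
  launch <- c(sh$target_path$x[i + 1] - sh$target_path$x[i],
              sh$target_path$y[i + 1] - sh$target_path$y[i])
  ang <- (atan2(launch[2], launch[1]) - atan2(n[2], n[1])) * 180 / pi
  expect_lt(abs(((ang + 180) %% 360) - 180), 1e-6)
})

test_that("shot outcome is equivariant under table rotation", {
  # 180-degree rotation about the table centre maps the table onto itself
  tab <- table_geometry()
  ctr <- c(tab$width / 2, tab$length / 2)
  rot <- function(p) sweep(-sweep(matrix(p, ncol = 2), 2, ctr), 2, ctr,
                           "+")
  tab_r <- table_geometry(
    pocket_positions = rot(tab$pocket_positions),
    cue_start = as.vector(rot(tab$cue_start)),
    target_start = as.vector(rot(tab$target_start)))
  st <- aim_strike(tab, bearing_deg = 30)
  st_r <- list(speed = st$speed, direction = -st$direction)
  # goal pocket 3 maps to rotated row 3
  sh <- simulate_shot(st, tab)
  sh_r <- simulate_shot(st_r, tab_r)
  expect_equal(sh_r$outcome$abs_error_deg, sh$outcome$abs_error_deg,
               tolerance = 1e-9)
  expect_identical(sh_r$outcome$success, sh$outcome$success)
})

test_that("halving dt barely changes the target launch direction", {
  tab <- table_geometry()
  st <- aim_strike(tab, bearing_deg = 20)
  d1 <- simulate_shot(st, tab, list(dt = 1 / 360))$outcome$direction_deg
  d2 <- simulate_shot(st, tab, list(dt = 1 / 720))$outcome$direction_deg
  expect_lt(abs(d1 - d2), 0.1)
})

test_that("frame calibration recovers similarity transforms exactly", {
  set.seed(9)
  A <- matrix(runif(10, 0, 2), 5, 2)

  ident <- fit_frame_transform(A, A)
  expect_equal(ident$rotation, 0, tolerance = 1e-12)
  expect_equal(ident$scale, 1, tolerance = 1e-12)
  expect_equal(ident$translation, c(0, 0), tolerance = 1e-12)
  expect_equal(ident$height_ratio, 1)

  B <- apply_similarity(A, 30 * pi / 180, 1.2, c(0.5, -0.2))
  tr <- fit_frame_transform(A, B)
  expect_equal(tr$rotation, 30 * pi / 180, tolerance = 1e-9)
  expect_equal(tr$scale, 1.2, tolerance = 1e-9)
  expect_equal(tr$translation, c(0.5, -0.2), tolerance = 1e-9)

  # 5 correspondences with heights (4 pockets + ball marker)
  h <- runif(5, 0.7, 0.9)
  tr3 <- fit_frame_transform(cbind(A, h), cbind(B, h * 1.07))
  expect_equal(tr3$height_ratio, 1.07, tolerance = 1e-9)

  expect_error(fit_frame_transform(matrix(1, 3, 2), matrix(1:6, 3, 2)),
               "degenerate geometry")
  expect_error(fit_frame_transform(A[1, , drop = FALSE],
                                   B[1, , drop = FALSE]),
               "degenerate geometry")
})

test_that("apply_transform round-trips and generalizes to held-out points", {
  set.seed(10)
  A <- matrix(runif(10, 0, 2), 5, 2)
  B <- apply_similarity(A, -0.4, 0.9, c(-1, 0.3))
  tr <- fit_frame_transform(A, B)

  p <- c(0.3, 0.7, 1.1)
  expect_equal(apply_transform(invert_transform(tr),
                               apply_transform(tr, p)),
               p, tolerance = 1e-12)

  # leave-one-out: refit without landmark 5, held-out maps within fit rms
  tr4 <- fit_frame_transform(A[1:4, ], B[1:4, ])
  pred <- apply_transform(tr4, A[5, ])
  expect_lt(sqrt(sum((pred - B[5, ])^2)), max(tr$rms, 1e-9))
})
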