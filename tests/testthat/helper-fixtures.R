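# Shared fixtures built in code: tiny deterministic kinematics, cue-tip
# streams, and landmark sets.

# A velocity matrix with a Gaussian bump of given amplitude per channel.
bump_velocity <- function(n = 180, rate = 60, peak_s = 1.5, width_s = 0.15,
                          amplitudes = NULL, channels = evr_channels()) {
  if (is.null(amplitudes)) {
    amplitudes <- stats::setNames(rep(0, length(channels)), channels)
    amplitudes[segment_channels(c("right_shoulder", "right_elbow"))] <- 100
  }
  tt <- seq(0, by = 1 / rate, length.out = n)
  v <- outer(exp(-(tt - peak_s)^2 / (2 * width_s^2)),
             amplitudes[channels])
  colnames(v) <- channels
  v
}

# A constant-velocity cue-tip stream at `rate` Hz.
cue_stream <- function(v = c(1, 0), rate = 90, n = 30, p0 = c(0, 0)) {
  ts <- seq(0, by = 1 / rate, length.out = n)
  pos <- cbind(p0[1] + v[1] * ts, p0[2] + v[2] * ts)
  list(timestamps = ts, tip_positions = pos, frame_rate = rate)
}

# Random planar similarity applied to a landmark set.
apply_similarity <- function(A, theta, s, trans) {
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(s * A %*% t(Rm), 2, trans, "+")
}

expect_angle_equal <- function(a, b, tol = 1e-9) {
  d <- abs(((a - b + 180) %% 360) - 180)
  expect_lt(d, tol)
}
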