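# Preprocessing of joint-angle recordings into aligned per-trial
# velocity-profile windows: differentiate, find the movement peak over the
# right-arm focus channels, crop a 1-s window around it.

#' Joint angular velocities by finite differences
#'
#' Differentiates each angle channel with central differences (one-sided
#' at the edges). Velocities, not raw angles, carry the analysis because
#' they are insensitive to the constant offsets and slow drift that IMU
#' angle estimates accumulate.
#'
#' @param angles samples x channels matrix (deg), or a recording list with
#'   `angles` and `rate` / `time`.
#' @param rate sampling rate (Hz); required when `angles` is a bare
#'   matrix. When a `time` vector is available it is checked for uniform
#'   sampling (1e-6 s jitter tolerance).
#' @return samples x channels matrix of velocities (deg/s).
#' @export
angular_velocity <- function(angles, rate = NULL) {
  time <- NULL
  if (is.list(angles) && !is.data.frame(angles)) {
    rate <- rate %||% angles$rate
    time <- angles$time
    angles <- angles$angles
  }
  angles <- as.matrix(angles)
  n <- nrow(angles)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (!is.null(time)) {
    dt <- diff(time)
    if (any(abs(dt - mean(dt)) > 1e-6)) {
      stop("sampling error: non-uniform timestamps beyond 1e-6 s jitter",
           call. = FALSE)
    }
    rate <- rate %||% (1 / mean(dt))
  }
  if (is.null(rate)) stop("sampling rate required", call. = FALSE)
  check_pos(rate, "rate")
  v <- matrix(0, n, ncol(angles), dimnames = dimnames(angles))
  v[2:(n - 1), ] <- (angles[3:n, , drop = FALSE] -
                     angles[1:(n - 2), , drop = FALSE]) * (rate / 2)
  v[1, ] <- (angles[2, ] - angles[1, ]) * rate
  v[n, ] <- (angles[n, ] - angles[n - 1, ]) * rate
  v
}

#' Locate the movement peak of a trial
#'
#' The trial peak is the sample at which the mean absolute angular
#' velocity across the focus channels — the 3 DoF of the right shoulder
#' and the 3 DoF of the right elbow — is maximal. All trials are aligned
#' on this peak before windowed analysis.
#'
#' @param velocity samples x channels matrix (deg/s) with column names.
#' @param channel_names optional channel names (defaults to the matrix's
#'   column names).
#' @param focus_segments segments whose DoF channels define the peak.
#' @return 1-based sample index of the peak (first maximum on ties).
#' @export
find_trial_peak <- function(velocity,
                            channel_names = colnames(velocity),
                            focus_segments = c("right_shoulder",
                                               "right_elbow")) {
  velocity <- as.matrix(velocity)
  focus <- segment_channels(focus_segments)
  miss <- setdiff(focus, channel_names)
  if (length(miss) > 0) {
    stop("schema error: missing focus channel(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  idx <- match(focus, channel_names)
  which.max(rowMeans(abs(velocity[, idx, drop = FALSE])))
}

#' Crop a 1-second window around the trial peak
#'
#' Returns the symmetric inclusive window of `round(rate) + 1` samples
#' centred on the peak (half a second each side). Trials whose peak sits
#' too close to a recording edge are rejected rather than padded: padding
#' would distort every covariance-based metric computed downstream.
#'
#' @param velocity samples x channels matrix.
#' @param peak 1-based peak sample index.
#' @param rate sampling rate (Hz).
#' @param window_s window length (s), default 1.
#' @return `window_samples x channels` matrix.
#' @export
crop_peak_window <- function(velocity, peak, rate, window_s = 1) {
  velocity <- as.matrix(velocity)
  half <- round(rate * window_s / 2)
  lo <- peak - half
  hi <- peak + half
  if (lo < 1 || hi > nrow(velocity)) {
    stop(sprintf(
      "boundary error: peak at sample %d needs window [%d, %d] of a %d-sample trial",
      peak, lo, hi, nrow(velocity)), call. = FALSE)
  }
  velocity[lo:hi, , drop = FALSE]
}

#' Full kinematic preparation of one trial
#'
#' Convenience pipeline: velocities (unless already given), peak over the
#' right-arm focus channels, 1-s window crop. Returns `NULL` with a
#' warning for trials whose peak is too close to an edge (the trial is
#' flagged, not padded).
#'
#' @param recording an `evr_trial_kinematics` object or a list with
#'   `angles` and `rate`.
#' @param focus_segments passed to [find_trial_peak()].
#' @return list with `velocity`, `peak_index`, `window`, `rate`, or
#'   `NULL` if the trial is rejected.
#' @export
prepare_trial <- function(recording,
                          focus_segments = c("right_shoulder",
                                             "right_elbow")) {
  vel <- if (!is.null(recording$velocity)) recording$velocity
         else angular_velocity(recording$angles, recording$rate)
  peak <- find_trial_peak(vel, colnames(vel), focus_segments)
  win <- tryCatch(crop_peak_window(vel, peak, recording$rate),
                  error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    NULL
                  })
  if (is.null(win)) return(NULL)
  list(velocity = vel, peak_index = peak, window = win,
       rate = recording$rate)
}
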