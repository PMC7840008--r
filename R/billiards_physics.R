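# 2D billiards shot physics and motion-capture -> virtual frame calibration.
#
# Coordinate convention (documented, the study does not define a sign):
# x across the table width (rightward seen from the shooting position),
# y toward the far cushion. Bearing 0 deg = straight toward the far
# cushion (+y); positive bearings are leftward (-x).

#' Table geometry for the shot simulator
#'
#' A pool table in the package's 2D coordinate frame (origin at the near-left
#' corner). Defaults approximate the study's physical table: an 8-ft table
#' (play field about 2.24 x 1.12 m), cue and target balls placed on the
#' table's long axis, and the far-left corner pocket as the goal.
#'
#' @param length,width play-field dimensions (m), y and x extents.
#' @param pocket_positions matrix (n x 2) of pocket centres (m); default:
#'   the four corners and two side pockets.
#' @param pocket_radius pocket capture radius (m).
#' @param cue_start,target_start length-2 ball start positions (m).
#' @param ball_radius ball radius (m); standard pool ball 28.5 mm.
#' @return An object of class `evr_table` (named list).
#' @export
table_geometry <- function(length = 2.24, width = 1.12,
                           pocket_positions = NULL,
                           pocket_radius = 0.07,
                           cue_start = c(width / 2, length * 0.25),
                           target_start = c(width / 2, length * 0.5),
                           ball_radius = 0.0285) {
  check_pos(length, "length"); check_pos(width, "width")
  check_pos(pocket_radius, "pocket_radius")
  check_pos(ball_radius, "ball_radius")
  if (is.null(pocket_positions)) {
    pocket_positions <- rbind(
      c(0, 0), c(width, 0), c(0, length), c(width, length),
      c(0, length / 2), c(width, length / 2)
    )
  }
  pocket_positions <- as.matrix(pocket_positions)
  stopifnot(ncol(pocket_positions) == 2)
  inside <- function(p) all(p >= 0) && p[1] <= width && p[2] <= length
  if (!inside(cue_start) || !inside(target_start)) {
    stop("configuration error: ball start positions must lie on the table",
         call. = FALSE)
  }
  structure(
    list(length = length, width = width,
         pocket_positions = pocket_positions,
         pocket_radius = pocket_radius,
         cue_start = as.numeric(cue_start),
         target_start = as.numeric(target_start),
         ball_radius = ball_radius),
    class = "evr_table"
  )
}

#' Estimate the strike from a cue-tip sample stream
#'
#' The collision force input is taken from the cue stick's motion just
#' before contact: per-frame tip velocities are formed by finite
#' differences, and the estimate is the componentwise median over the 10
#' frames preceding the contact time (about 0.11 s at the 90 Hz display
#' rate). The componentwise median gives one coherent velocity vector that
#' is robust to a corrupted frame; speed is its magnitude and direction
#' its unit vector.
#'
#' @param stream a list with `timestamps` (strictly increasing, s) and
#'   `tip_positions` (n x 2 matrix, m). A `frame_rate` element is allowed
#'   but the estimate only uses the timestamps.
#' @param contact_time time (s) of cue-ball contact.
#' @param n_frames number of pre-contact frames to pool (default 10).
#' @return A list with `speed` (m/s), `direction` (unit length-2 vector),
#'   and `velocity` (their product).
#' @export
estimate_strike <- function(stream, contact_time, n_frames = 10) {
  ts <- stream$timestamps
  pos <- as.matrix(stream$tip_positions)
  stopifnot(nrow(pos) == length(ts), ncol(pos) == 2)
  if (any(diff(ts) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  keep <- which(ts <= contact_time)
  if (length(keep) < n_frames + 1) {
    stop(sprintf(
      "insufficient data: need %d samples before contact, have %d",
      n_frames + 1, length(keep)), call. = FALSE)
  }
  idx <- utils::tail(keep, n_frames + 1)
  dt <- diff(ts[idx])
  vel <- diff(pos[idx, , drop = FALSE]) / dt  # n_frames per-frame velocities
  med <- apply(vel, 2, stats::median)
  speed <- sqrt(sum(med^2))
  dir <- if (speed > 0) med / speed else c(0, 0)
  list(speed = speed, direction = dir, velocity = med)
}

# Advance a ball under uniform frictional deceleration for one step.
# Returns the new position/velocity; velocity hits exactly zero when the
# deceleration would reverse it within the step.
step_ball <- function(p, v, decel, dt) {
  sp <- sqrt(sum(v^2))
  if (sp == 0) return(list(p = p, v = v))
  t_stop <- sp / decel
  h <- min(dt, t_stop)
  u <- v / sp
  p2 <- p + u * (sp * h - 0.5 * decel * h^2)
  v2 <- if (h < dt) c(0, 0) else v - u * decel * dt
  list(p = p2, v = v2)
}

# Resolve an equal-mass ball-ball collision: the velocity component along
# the unit line of centres `n` (cue -> target) transfers per restitution e,
# tangential components are untouched. Returns the post-contact velocities.
collide_balls <- function(v1, v2, n, restitution = 1) {
  n <- n / sqrt(sum(n^2))
  v_rel_n <- sum((v1 - v2) * n)
  if (v_rel_n <= 0) return(list(v1 = v1, v2 = v2))
  J <- (1 + restitution) / 2 * v_rel_n
  list(v1 = v1 - J * n, v2 = v2 + J * n)
}

# Earliest s in [0,1] at which |(p1 + s*d1) - (p2 + s*d2)| = R, or NA.
swept_contact <- function(p1, d1, p2, d2, R) {
  dp <- p1 - p2; dd <- d1 - d2
  a <- sum(dd^2); b <- 2 * sum(dp * dd); cc <- sum(dp^2) - R^2
  if (cc <= 0) return(0)
  if (a == 0) return(NA_real_)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  s <- (-b - sqrt(disc)) / (2 * a)
  if (s >= 0 && s <= 1) s else NA_real_
}

#' Simulate one billiards shot
#'
#' Integrates cue-ball and target-ball motion under uniform frictional
#' deceleration. Ball-ball contact is detected with a swept-circle test
#' each step (no tunnelling); at contact the velocity component along the
#' line of centres transfers to the target ball according to a restitution
#' model for equal masses, leaving the tangential component with the cue
#' ball. The simulation ends when all ball speeds drop below
#' `stop_threshold`. The shot succeeds when the target-ball path enters a
#' pocket's capture radius; its directional error is the absolute angle
#' between the target ball's initial movement and the direction from its
#' start to the centre of the goal pocket.
#'
#' The engine the study used hard-codes the ball-ball collision as
#' "perfectly inelastic"; a literally sticking collision cannot launch a
#' separately travelling target ball, so the default `restitution = 1`
#' implements the idealized equal-mass billiard transfer (full
#' line-of-centres exchange) and the parameter is left tunable.
#'
#' @param strike an [estimate_strike()] result (or any list with `speed`
#'   and `direction`).
#' @param table an [table_geometry()] object.
#' @param params list: `friction_decel` (m/s^2, default 0.6),
#'   `restitution` (default 1), `stop_threshold` (m/s, default 0.02),
#'   `dt` (s, default 1/360), `goal_pocket` (row index into the table's
#'   pockets, default 3 = far-left corner), `max_time` (s, default 30).
#' @return An object of class `evr_shot`: list with `cue_path` and
#'   `target_path` (data.frames `t`, `x`, `y`), `contact_time` (s or NA),
#'   `outcome` (list: `direction_deg` signed target launch bearing,
#'   `abs_error_deg`, `success`, `pocket`), and the parameters used.
#' @export
simulate_shot <- function(strike, table, params = list()) {
  stopifnot(inherits(table, "evr_table"))
  p <- utils::modifyList(list(friction_decel = 0.6, restitution = 1,
                              stop_threshold = 0.02, dt = 1 / 360,
                              goal_pocket = 3, max_time = 30), params)
  check_pos(p$friction_decel, "friction_decel")
  check_pos(p$stop_threshold, "stop_threshold")
  check_pos(p$dt, "dt")
  R <- 2 * table$ball_radius
  # tunnelling guard: one step must not skip past a whole contact diameter
  if (strike$speed * p$dt > R) {
    stop("resolution error: dt too large for contact detection at this speed",
         call. = FALSE)
  }
  cue_p <- table$cue_start
  cue_v <- strike$direction * strike$speed
  tgt_p <- table$target_start
  tgt_v <- c(0, 0)
  t <- 0
  cue_path <- list(c(0, cue_p)); tgt_path <- list(c(0, tgt_p))
  contact_time <- NA_real_
  contacted <- FALSE
  pocket_hit <- NA_integer_
  goal <- table$pocket_positions[p$goal_pocket, ]
  launch_v <- NULL
  while (t < p$max_time) {
    sp_cue <- sqrt(sum(cue_v^2)); sp_tgt <- sqrt(sum(tgt_v^2))
    if (sp_cue < p$stop_threshold && sp_tgt < p$stop_threshold) break
    s1 <- step_ball(cue_p, cue_v, p$friction_decel, p$dt)
    s2 <- step_ball(tgt_p, tgt_v, p$friction_decel, p$dt)
    if (!contacted) {
      s <- swept_contact(cue_p, s1$p - cue_p, tgt_p, s2$p - tgt_p, R)
      if (!is.na(s)) {
        # advance to the contact instant, then exchange momenta
        h <- s * p$dt
        c1 <- step_ball(cue_p, cue_v, p$friction_decel, h)
        c2 <- step_ball(tgt_p, tgt_v, p$friction_decel, h)
        cue_p <- c1$p; cue_v <- c1$v; tgt_p <- c2$p; tgt_v <- c2$v
        cv <- collide_balls(cue_v, tgt_v, tgt_p - cue_p, p$restitution)
        cue_v <- cv$v1
        tgt_v <- cv$v2
        contacted <- TRUE
        contact_time <- t + h
        launch_v <- tgt_v
        t <- t + h
        cue_path[[length(cue_path) + 1]] <- c(t, cue_p)
        tgt_path[[length(tgt_path) + 1]] <- c(t, tgt_p)
        next
      }
    }
    cue_p <- s1$p; cue_v <- s1$v; tgt_p <- s2$p; tgt_v <- s2$v
    t <- t + p$dt
    cue_path[[length(cue_path) + 1]] <- c(t, cue_p)
    tgt_path[[length(tgt_path) + 1]] <- c(t, tgt_p)
    if (contacted && is.na(pocket_hit)) {
      d2 <- rowSums(sweep(table$pocket_positions, 2, tgt_p)^2)
      hit <- which(d2 <= table$pocket_radius^2)
      if (length(hit) > 0) {
        pocket_hit <- hit[1]
        break
      }
    }
  }
  outcome <- if (contacted && !is.null(launch_v) && sum(launch_v^2) > 0) {
    dir_deg <- bearing_deg(launch_v)
    desired <- bearing_deg(goal - table$target_start)
    err <- abs(wrap_angle(dir_deg - desired))
    list(direction_deg = dir_deg, abs_error_deg = err,
         success = !is.na(pocket_hit) && pocket_hit == p$goal_pocket,
         pocket = pocket_hit)
  } else {
    list(direction_deg = NA_real_, abs_error_deg = NA_real_,
         success = FALSE, pocket = NA_integer_)
  }
  mk <- function(lst) {
    m <- do.call(rbind, lst)
    data.frame(t = m[, 1], x = m[, 2], y = m[, 3])
  }
  structure(
    list(cue_path = mk(cue_path), target_path = mk(tgt_path),
         contact_time = contact_time, outcome = outcome, params = p),
    class = "evr_shot"
  )
}

#' Construct a strike that launches the target ball at a given bearing
#'
#' Inverts the collision geometry: for the target ball to launch along a
#' desired bearing, the cue ball's centre at contact must sit one contact
#' diameter behind the target centre along that bearing; the strike points
#' the cue ball from its start position at that contact point. A bearing
#' of `NULL` aims dead-on at the goal pocket.
#'
#' @param table an [table_geometry()] object.
#' @param bearing_deg desired target-ball launch bearing (deg; 0 = toward
#'   the far cushion, positive leftward), or `NULL` to aim at
#'   `goal_pocket`.
#' @param speed strike speed (m/s).
#' @param goal_pocket pocket row index used when `bearing_deg` is `NULL`.
#' @return A strike list (`speed`, `direction`) for [simulate_shot()].
#' @export
aim_strike <- function(table, bearing_deg = NULL, speed = 2.5,
                       goal_pocket = 3) {
  stopifnot(inherits(table, "evr_table"))
  if (is.null(bearing_deg)) {
    goal <- table$pocket_positions[goal_pocket, ]
    bearing_deg <- bearing_deg(goal - table$target_start)
  }
  th <- bearing_deg * pi / 180
  u <- c(-sin(th), cos(th))            # unit launch direction
  contact <- table$target_start - 2 * table$ball_radius * u
  d <- contact - table$cue_start
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("cue ball already at the contact point", call. = FALSE)
  list(speed = speed, direction = d / nd)
}

#' Fit the motion-capture to virtual-space frame transform
#'
#' Both environments share a vertical axis, so calibration reduces to a
#' planar similarity transform (rotation + uniform scale + translation,
#' least squares over landmark correspondences) plus a linear height
#' ratio. The study's calibration used five landmarks: markers in the four
#' corner pockets plus one on the cue-ball spot.
#'
#' @param mocap,virtual n x 2 matrices of planar landmark coordinates, or
#'   n x 3 with heights in the third column.
#' @return An object of class `evr_transform`: `rotation` (radians),
#'   `scale`, `translation` (length 2), `height_ratio`, `rms` (planar fit
#'   residual).
#' @export
fit_frame_transform <- function(mocap, virtual) {
  mocap <- as.matrix(mocap); virtual <- as.matrix(virtual)
  stopifnot(nrow(mocap) == nrow(virtual), ncol(mocap) == ncol(virtual),
            ncol(mocap) %in% c(2, 3))
  if (nrow(mocap) < 2) {
    stop("degenerate geometry: need at least 2 landmark correspondences",
         call. = FALSE)
  }
  A <- mocap[, 1:2, drop = FALSE]
  B <- virtual[, 1:2, drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  va <- sum(A0^2)
  if (va == 0) {
    stop("degenerate geometry: coincident landmarks", call. = FALSE)
  }
  # closed-form planar similarity (complex least squares a*z + b)
  num_re <- sum(A0 * B0)                      # Re(conj(a) . b)
  num_im <- sum(A0[, 1] * B0[, 2] - A0[, 2] * B0[, 1])
  theta <- atan2(num_im, num_re)
  s <- sqrt(num_re^2 + num_im^2) / va
  if (s == 0) {
    stop("degenerate geometry: virtual landmarks are coincident",
         call. = FALSE)
  }
  Rm <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  trans <- cb - as.vector(s * Rm %*% ca)
  fitted <- sweep(s * A %*% t(Rm), 2, trans, "+")
  rms <- sqrt(mean(rowSums((fitted - B)^2)))
  hr <- 1
  if (ncol(mocap) == 3) {
    hm <- mocap[, 3]; hv <- virtual[, 3]
    if (sum(hm^2) > 0) hr <- sum(hm * hv) / sum(hm^2)
  }
  structure(
    list(rotation = theta, scale = s, translation = trans,
         height_ratio = hr, rms = rms),
    class = "evr_transform"
  )
}

#' Apply (or invert) a fitted frame transform
#'
#' Planar coordinates are rotated, scaled, and translated; the height (if
#' present as a third coordinate) is multiplied by the height ratio.
#'
#' @param transform an [fit_frame_transform()] result.
#' @param points length-2/3 vector or n x 2/3 matrix.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "evr_transform"))
  vec <- is.null(dim(points))
  m <- if (vec) matrix(points, nrow = 1) else as.matrix(points)
  th <- transform$rotation
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  out <- m
  out[, 1:2] <- sweep(transform$scale * m[, 1:2, drop = FALSE] %*% t(Rm),
                      2, transform$translation, "+")
  if (ncol(m) >= 3) out[, 3] <- m[, 3] * transform$height_ratio
  if (vec) as.vector(out) else out
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "evr_transform"))
  th <- -transform$rotation
  s <- 1 / transform$scale
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  structure(
    list(rotation = th, scale = s,
         translation = as.vector(-s * Rm %*% transform$translation),
         height_ratio = 1 / transform$height_ratio, rms = transform$rms),
    class = "evr_transform"
  )
}

#' Write a shot trajectory as a tidy CSV
#'
#' @param shot an [simulate_shot()] result.
#' @param path output file; columns `t`, `ball` (`cue`/`target`), `x`, `y`.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(shot, path) {
  stopifnot(inherits(shot, "evr_shot"))
  df <- rbind(cbind(ball = "cue", shot$cue_path),
              cbind(ball = "target", shot$target_path))
  df <- df[, c("t", "ball", "x", "y")]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
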