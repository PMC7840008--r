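# Task-space performance measures: directional error, block partitioning,
# success rate, and robust (t-distribution) intertrial variability with a
# within-block learning correction.

#' Directional error of a shot
#'
#' The trial error is the absolute angular difference between the target
#' ball's initial movement direction and the desired direction from its
#' start position to the centre of the pocket, wrapped to [0, 180].
#'
#' @param target_path n x 2 matrix or data.frame (`x`, `y`) of target-ball
#'   positions over time.
#' @param start length-2 start position of the target ball.
#' @param pocket_center length-2 pocket-centre position.
#' @param min_displacement minimum travel (same units as positions) for
#'   the movement direction to be defined.
#' @return Absolute angular error in degrees, or `NA` (with attribute
#'   `flag = "no_movement"`) if the ball never moved far enough — such
#'   trials are excluded upstream.
#' @seealso [shot_direction()] for the signed direction.
#' @export
directional_error <- function(target_path, start, pocket_center,
                              min_displacement = 1e-3) {
  dir <- shot_direction(target_path, start, min_displacement)
  if (is.na(dir)) return(structure(NA_real_, flag = "no_movement"))
  desired <- bearing_deg(as.numeric(pocket_center) - as.numeric(start))
  abs(wrap_angle(dir - desired))
}

#' Signed initial movement direction of the target ball
#'
#' @inheritParams directional_error
#' @return Signed bearing (deg; 0 = toward the far cushion, positive
#'   leftward) of the first displacement of at least `min_displacement`,
#'   or `NA` if the ball did not move.
#' @export
shot_direction <- function(target_path, start, min_displacement = 1e-3) {
  m <- as.matrix(as.data.frame(target_path)[, c("x", "y")])
  start <- as.numeric(start)
  disp <- sweep(m, 2, start)
  d <- sqrt(rowSums(disp^2))
  i <- which(d >= min_displacement)
  if (length(i) == 0) return(NA_real_)
  unname(bearing_deg(disp[i[1], ]))
}

#' Partition trials into consecutive blocks
#'
#' Trials are analysed in consecutive blocks of 25 (each 50-trial
#' experimental set split in two for resolution), so 300 trials give 12
#' blocks. A trailing partial block is kept and flagged.
#'
#' @param outcomes a data.frame of trial outcomes (any columns) or a
#'   vector; rows/elements are assigned in order.
#' @param block_size trials per block.
#' @return A list of blocks, each carrying attribute `partial` (logical)
#'   and `block` (1-based index).
#' @export
partition_blocks <- function(outcomes, block_size = 25) {
  block_size <- check_count(block_size, "block_size")
  n <- if (is.data.frame(outcomes)) nrow(outcomes) else length(outcomes)
  if (n == 0) return(list())
  starts <- seq(1, n, by = block_size)
  lapply(seq_along(starts), function(b) {
    idx <- starts[b]:min(starts[b] + block_size - 1, n)
    blk <- if (is.data.frame(outcomes)) outcomes[idx, , drop = FALSE]
           else outcomes[idx]
    attr(blk, "partial") <- length(idx) < block_size
    attr(blk, "block") <- b
    blk
  })
}

#' Success rate of a block
#'
#' @param block data.frame with a logical `success` column, or a logical
#'   vector.
#' @return Fraction of successful trials.
#' @export
success_rate <- function(block) {
  s <- if (is.data.frame(block)) block$success else block
  if (length(s) == 0) stop("empty block", call. = FALSE)
  mean(as.logical(s))
}

#' Robust location/scale of block errors via a t-distribution fit
#'
#' Fits a location-scale t-distribution to the values by maximum
#' likelihood and reports its location and scale as the block's centre
#' and variability; heavy tails absorb outlier shots that would inflate a
#' Gaussian SD. Degrees of freedom are estimated, bounded to [1, 100] for
#' stability (at the upper bound the fit is effectively Gaussian). With
#' fewer than 5 values the fit falls back to median and scaled MAD
#' (flagged); zero-spread input returns scale 0 at the df upper bound.
#'
#' @param x numeric values (deg).
#' @return list: `mu`, `sigma`, `df`, `converged`, `fallback`.
#' @export
fit_block_t <- function(x) {
  x <- as.numeric(x[!is.na(x)])
  n <- length(x)
  if (n == 0) stop("empty block", call. = FALSE)
  if (stats::sd(x) == 0 || n == 1) {
    return(list(mu = x[1], sigma = 0, df = 100, converged = TRUE,
                fallback = FALSE))
  }
  if (n < 5) {
    return(list(mu = stats::median(x), sigma = stats::mad(x), df = NA_real_,
                converged = TRUE, fallback = TRUE))
  }
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2]); nu <- exp(par[3])
    -sum(stats::dt((x - mu) / sigma, df = nu, log = TRUE) - log(sigma))
  }
  s0 <- max(stats::mad(x), stats::sd(x) / 10, 1e-8)
  best <- NULL
  for (nu0 in c(2, 5, 30)) {
    fit <- tryCatch(
      stats::optim(c(stats::median(x), log(s0), log(nu0)), nll,
                   method = "L-BFGS-B",
                   lower = c(-Inf, log(1e-10), 0),
                   upper = c(Inf, Inf, log(100))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(list(mu = stats::median(x), sigma = stats::mad(x), df = NA_real_,
                converged = FALSE, fallback = TRUE))
  }
  list(mu = best$par[1], sigma = exp(best$par[2]),
       df = exp(best$par[3]), converged = best$convergence == 0,
       fallback = FALSE)
}

#' Learning-corrected intertrial variability
#'
#' Within a block, some of the shot-to-shot spread is systematic learning
#' rather than noise. The corrected intertrial variability regresses the
#' signed ball direction on the within-block trial index (ordinary least
#' squares) and reports the robust t-fit scale of the residuals. The
#' residuals are inflated by `sqrt(n / (n - 2))` before the fit — the
#' standard degrees-of-freedom correction for the two regression
#' parameters, without which the scale of a 25-trial block is biased
#' low.
#'
#' @param directions signed directions (deg) of one block's trials, in
#'   order.
#' @return list as [fit_block_t()], computed on the detrended directions.
#' @export
corrected_itv <- function(directions) {
  directions <- as.numeric(directions)
  keep <- !is.na(directions)
  y <- directions[keep]
  if (length(y) < 2) stop("need at least 2 directions", call. = FALSE)
  t <- seq_along(y)
  res <- stats::lm.fit(cbind(1, t), y)$residuals
  n <- length(y)
  if (n > 2) res <- res * sqrt(n / (n - 2))
  fit_block_t(res)
}

#' Per-block performance statistics for one session
#'
#' Applies the block partition and computes, per block: the robust centre
#' and scale of the absolute errors, the success rate, and the corrected
#' intertrial variability of the signed directions.
#'
#' @param outcomes data.frame with `trial`, `direction_deg`,
#'   `abs_error_deg`, `success`.
#' @param block_size trials per block.
#' @return data.frame: `block`, `n`, `partial`, `mu`, `sigma`, `df`,
#'   `success_rate`, `corrected_sigma`.
#' @export
block_stats <- function(outcomes, block_size = 25) {
  blocks <- partition_blocks(outcomes, block_size)
  rows <- lapply(blocks, function(b) {
    ft <- fit_block_t(b$abs_error_deg)
    itv <- fit_block_t(b$direction_deg)
    citv <- corrected_itv(b$direction_deg)
    data.frame(
      block = attr(b, "block"), n = nrow(b),
      partial = attr(b, "partial"),
      mu = ft$mu, sigma = itv$sigma, df = ft$df,
      success_rate = success_rate(b),
      corrected_sigma = citv$sigma
    )
  })
  do.call(rbind, rows)
}

#' Cross-subject block summary
#'
#' @param per_subject a named list of [block_stats()] data.frames (one
#'   per subject).
#' @param column which block statistic to summarize.
#' @return data.frame: `block`, `n_subjects`, `mean`, `sd`, `sem`.
#' @export
summarize_blocks <- function(per_subject, column = "mu") {
  tall <- do.call(rbind, lapply(names(per_subject), function(s) {
    d <- per_subject[[s]]
    data.frame(subject = s, block = d$block, value = d[[column]])
  }))
  agg <- split(tall$value, tall$block)
  data.frame(
    block = as.integer(names(agg)),
    n_subjects = vapply(agg, length, integer(1)),
    mean = vapply(agg, mean, numeric(1)),
    sd = vapply(agg, stats::sd, numeric(1)),
    sem = vapply(agg, function(v) stats::sd(v) / sqrt(length(v)),
                 numeric(1)),
    row.names = NULL
  )
}
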