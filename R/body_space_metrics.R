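# Body-space learning metrics computed on the aligned 1-s velocity
# windows: covariance and generalized variance, PC spectrum and DoF count,
# manipulative complexity, and the velocity profile error (VPE).

#' Covariance of a trial's velocity window
#'
#' Sample covariance (divisor n-1) between velocity channels over the
#' window's time samples.
#'
#' @param window samples x channels matrix (deg/s).
#' @return channels x channels covariance matrix ((deg/s)^2).
#' @export
trial_covariance <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) < 2) stop("need at least 2 samples", call. = FALSE)
  stats::cov(window)
}

#' Generalized variance
#'
#' The determinant of a covariance matrix: a scalar summary of the
#' multidimensional scatter of the joint velocities within one trial.
#' Computed via eigendecomposition of the symmetrized matrix for
#' stability; tiny negative values from round-off are clipped to 0.
#'
#' @param cov square symmetric covariance matrix.
#' @param tol asymmetry tolerance relative to the largest entry.
#' @return Non-negative determinant ((deg/s)^(2d)).
#' @export
generalized_variance <- function(cov, tol = 1e-8) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov)) {
    stop("input error: covariance matrix must be square", call. = FALSE)
  }
  scale <- max(abs(cov), 1e-300)
  if (max(abs(cov - t(cov))) > tol * scale) {
    stop("input error: matrix is not symmetric", call. = FALSE)
  }
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  gv <- prod(ev)
  if (gv < 0 && abs(gv) <= tol * max(abs(ev))^nrow(cov)) gv <- 0
  max(gv, 0)
}

#' Principal-component variance spectrum of a velocity window
#'
#' Eigenvalues of the channel covariance, normalized to variance
#' fractions and sorted descending. All channels share units (deg/s), so
#' the PCA is on the covariance, not the correlation, matrix.
#'
#' @param window samples x channels matrix, or a precomputed covariance
#'   matrix (detected as square symmetric).
#' @return Numeric vector of variance fractions (non-negative, summing to
#'   1), or `NA` with attribute `flag = "zero_variance"` when the window
#'   carries no variance at all.
#' @export
pc_spectrum <- function(window) {
  window <- as.matrix(window)
  cv <- if (nrow(window) == ncol(window) &&
            max(abs(window - t(window))) <=
              1e-8 * max(abs(window), 1e-300)) {
    window
  } else {
    trial_covariance(window)
  }
  ev <- eigen((cv + t(cv)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  tot <- sum(ev)
  if (tot == 0) return(structure(NA_real_, flag = "zero_variance"))
  sort(ev / tot, decreasing = TRUE)
}

#' Count the degrees of freedom in a movement
#'
#' Number of principal components explaining strictly more than the
#' threshold fraction of variance (default 1%).
#'
#' @param spectrum variance fractions from [pc_spectrum()].
#' @param threshold variance fraction cut-off.
#' @return Integer count.
#' @export
dof_count <- function(spectrum, threshold = 0.01) {
  sum(spectrum > threshold)
}

#' Manipulative complexity of a PC spectrum
#'
#' A fixed-scale (0 to 1) summary of how evenly variance spreads across
#' principal components: C = 1 when all PCs contribute equally, C = 0
#' when a single PC explains all the variability. The default strategy is
#' the normalized participation ratio, C = (PR - 1)/(N - 1) with
#' PR = 1 / sum(lambda_i^2); the `entropy` strategy uses the normalized
#' exponential Shannon entropy (exp(H) - 1)/(N - 1). Both satisfy the
#' boundary conditions above, which are the only published anchors for
#' this quantity.
#'
#' @param spectrum variance fractions (length N >= 2, summing to 1).
#' @param strategy `"participation_ratio"` (default) or `"entropy"`.
#' @return C in [0, 1].
#' @export
manipulative_complexity <- function(spectrum,
                                    strategy = c("participation_ratio",
                                                 "entropy")) {
  strategy <- match.arg(strategy)
  l <- as.numeric(spectrum)
  N <- length(l)
  if (N < 2) stop("need a spectrum of length >= 2", call. = FALSE)
  if (any(l < -1e-12) || abs(sum(l) - 1) > 1e-9) {
    stop("spectrum must be non-negative variance fractions summing to 1",
         call. = FALSE)
  }
  eff <- switch(strategy,
    participation_ratio = 1 / sum(l^2),
    entropy = {
      p <- l[l > 0]
      exp(-sum(p * log(p)))
    })
  (eff - 1) / (N - 1)
}

#' Velocity profile error (VPE)
#'
#' Task performance measured in body space: for each joint channel, the
#' correlation distance (1 - Pearson r) between the trial's velocity
#' profile and the same channel's profile in every successful trial; the
#' minimum over the successful trials is the channel's VPE — the distance
#' to the nearest successful movement solution, which respects the
#' redundancy of the body. When the trial itself is in the library,
#' `exclude_self` (default on) removes it: a successful trial at distance
#' 0 from itself would mask the learning structure.
#'
#' @param trial_profile samples x channels window of the trial.
#' @param success_library list of samples x channels windows of
#'   successful trials (equal lengths).
#' @param exclude_self index into `success_library` to drop, or
#'   `TRUE`/`FALSE`; `TRUE` drops any library entry identical to
#'   `trial_profile`.
#' @return Named numeric vector, one VPE in [0, 2] per channel;
#'   zero-variance channels are `NA`.
#' @export
velocity_profile_error <- function(trial_profile, success_library,
                                   exclude_self = TRUE) {
  trial_profile <- as.matrix(trial_profile)
  if (is.numeric(exclude_self)) {
    success_library <- success_library[-exclude_self]
  } else if (isTRUE(exclude_self)) {
    success_library <- Filter(
      function(w) !isTRUE(all.equal(as.matrix(w), trial_profile,
                                    check.attributes = FALSE)),
      success_library)
  }
  if (length(success_library) == 0) {
    stop("undefined: success library is empty after exclusion",
         call. = FALSE)
  }
  nch <- ncol(trial_profile)
  vpe <- rep(NA_real_, nch)
  names(vpe) <- colnames(trial_profile)
  lib <- lapply(success_library, as.matrix)
  for (j in seq_len(nch)) {
    x <- trial_profile[, j]
    if (stats::sd(x) == 0) next  # flat profile: correlation undefined
    dists <- vapply(lib, function(w) {
      y <- w[, j]
      if (stats::sd(y) == 0) return(NA_real_)
      1 - stats::cor(x, y)
    }, numeric(1))
    if (all(is.na(dists))) next
    vpe[j] <- min(dists, na.rm = TRUE)
  }
  vpe
}

#' Robust within-block variability of per-channel VPEs
#'
#' Applies the same robust scale estimator as the directional intertrial
#' variability ([fit_block_t()]) to each channel's VPE values within a
#' block.
#'
#' @param vpes trials x channels matrix (or data.frame) of VPE values for
#'   one block.
#' @return Named numeric vector of per-channel scales.
#' @export
vpe_block_variability <- function(vpes) {
  vpes <- as.matrix(vpes)
  apply(vpes, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    fit_block_t(v)$sigma
  })
}

#' All body-space metrics for one trial
#'
#' @param window aligned velocity window (samples x channels).
#' @param dof_threshold variance-fraction cut-off for [dof_count()].
#' @param complexity_strategy passed to [manipulative_complexity()].
#' @return list: `gv`, `spectrum`, `dof_count`, `complexity`.
#' @export
body_metrics <- function(window, dof_threshold = 0.01,
                         complexity_strategy = "participation_ratio") {
  cv <- trial_covariance(window)
  spec <- pc_spectrum(cv)
  if (all(is.na(spec))) {
    return(list(gv = 0, spectrum = spec, dof_count = NA_integer_,
                complexity = NA_real_))
  }
  list(
    gv = generalized_variance(cv),
    spectrum = spec,
    dof_count = dof_count(spec, dof_threshold),
    complexity = manipulative_complexity(spec, complexity_strategy)
  )
}
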