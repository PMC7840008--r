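# Learning-curve models: single and double exponentials over trials
# (variable-projection least squares: linear amplitudes profiled out,
# time constants found by multi-start optimization), and the
# first-to-last-block learning delta across subjects.

tau_grid_default <- c(5, 10, 20, 40, 80, 160)

# Profiled RSS of y ~ c + columns of basis (linear least squares).
profiled_fit <- function(basis, y) {
  X <- cbind(1, basis)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit) || any(is.na(fit$coefficients))) return(NULL)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2))
}

#' Fit an exponential learning curve
#'
#' Least-squares fit of `y(t) = c + a * exp(-t / tau)` over trials. The
#' linear parameters (`c`, `a`) are profiled out, and the time constant
#' is found by local optimization in log(tau) from a fixed multi-start
#' grid (5, 10, 20, 40, 80, 160 trials) to avoid local minima.
#'
#' @param series per-trial metric values (NAs dropped).
#' @param t trial indices (default `seq_along(series)`).
#' @param tau_grid multi-start values for the time constant.
#' @return An object of class `evr_fit`: list with `model`, `params`
#'   (`c`, `a`, `tau`), `rss`, `converged`, `fitted_fn` (a function of
#'   t).
#' @export
fit_exponential <- function(series, t = seq_along(series),
                            tau_grid = tau_grid_default) {
  keep <- !is.na(series)
  y <- as.numeric(series[keep]); tt <- as.numeric(t[keep])
  if (length(y) < 10) stop("need at least 10 points", call. = FALSE)
  rss_of <- function(log_tau) {
    f <- profiled_fit(exp(-tt / exp(log_tau)), y)
    if (is.null(f)) Inf else f$rss
  }
  best <- NULL
  for (tau0 in tau_grid) {
    opt <- stats::optimize(rss_of, interval = log(c(tau0 / 4, tau0 * 4)),
                           tol = 1e-12)
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  tau <- exp(best$minimum)
  f <- profiled_fit(exp(-tt / tau), y)
  converged <- !is.null(f) && is.finite(f$rss)
  if (!converged) {
    # flat fallback: mean-only model
    f <- list(coef = c(mean(y), 0), rss = sum((y - mean(y))^2))
    tau <- NA_real_
  }
  params <- list(c = unname(f$coef[1]), a = unname(f$coef[2]), tau = tau)
  structure(
    list(model = "exponential", params = params, rss = f$rss,
         converged = converged,
         fitted_fn = function(t) params$c + params$a * exp(-t / params$tau)),
    class = "evr_fit"
  )
}

#' Fit a double-exponential learning curve
#'
#' Least-squares fit of
#' `y(t) = c + a1 * exp(-t / tau1) - a2 * exp(-t / tau2)` with
#' `tau2 < tau1` enforced by parameterization — the fast component
#' (tau2) builds the early rise and the slow component (tau1) the late
#' decay, the shape of metrics that climb over the first few dozen
#' trials and then drift down. Linear amplitudes are profiled out; the
#' two time constants are optimized from a grid of ordered start pairs.
#'
#' @inheritParams fit_exponential
#' @return An `evr_fit` object with params `c`, `a1`, `tau1`, `a2`,
#'   `tau2`.
#' @export
fit_double_exponential <- function(series, t = seq_along(series),
                                   tau_grid = tau_grid_default) {
  keep <- !is.na(series)
  y <- as.numeric(series[keep]); tt <- as.numeric(t[keep])
  if (length(y) < 20) stop("need at least 20 points", call. = FALSE)
  # par = (log tau2, log(tau1 - tau2)); keeps tau2 < tau1 unconstrained
  rss_of <- function(par) {
    tau2 <- exp(par[1]); tau1 <- tau2 + exp(par[2])
    if (!is.finite(tau1) || tau1 > 1e8) return(Inf)
    f <- profiled_fit(cbind(exp(-tt / tau1), -exp(-tt / tau2)), y)
    if (is.null(f)) Inf else f$rss
  }
  starts <- expand.grid(tau2 = tau_grid, tau1 = tau_grid)
  starts <- starts[starts$tau1 > starts$tau2, ]
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(log(starts$tau2[i]), log(starts$tau1[i] - starts$tau2[i]))
    opt <- tryCatch(
      stats::optim(p0, rss_of, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 2000)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("double-exponential fit failed from all starts", call. = FALSE)
  }
  # polish the winner
  pol <- tryCatch(
    stats::optim(best$par, rss_of, method = "BFGS",
                 control = list(reltol = 1e-14, maxit = 1000)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) best <- pol
  tau2 <- exp(best$par[1]); tau1 <- tau2 + exp(best$par[2])
  f <- profiled_fit(cbind(exp(-tt / tau1), -exp(-tt / tau2)), y)
  params <- list(c = unname(f$coef[1]), a1 = unname(f$coef[2]),
                 tau1 = tau1, a2 = unname(f$coef[3]), tau2 = tau2)
  structure(
    list(model = "double_exponential", params = params, rss = f$rss,
         converged = TRUE,
         fitted_fn = function(t) {
           params$c + params$a1 * exp(-t / params$tau1) -
             params$a2 * exp(-t / params$tau2)
         }),
    class = "evr_fit"
  )
}

#' @export
print.evr_fit <- function(x, ...) {
  cat(sprintf("%s fit: rss = %.6g, converged = %s\n", x$model, x$rss,
              x$converged))
  p <- unlist(x$params)
  cat(paste(sprintf("  %s = %.6g", names(p), p), collapse = "\n"), "\n")
  invisible(x)
}

#' First-to-last-block learning delta across subjects
#'
#' Per subject, the difference between the first and last block means of
#' a metric; across subjects, its mean, SD, SEM, and a two-sided paired
#' t-test (sidedness is a package convention).
#'
#' @param per_subject_block_means data.frame with columns `subject`,
#'   `block`, `value` (one row per subject x block), or a matrix
#'   subjects x blocks.
#' @param first_block,last_block block indices to difference.
#' @return list: `mean`, `sd`, `sem`, `t`, `p`, `n`, `differences`. With
#'   zero variance of the differences `t` and `p` are `NA` and the
#'   result carries `flag = "zero_variance"`.
#' @export
learning_delta <- function(per_subject_block_means, first_block = 1,
                           last_block = 12) {
  d <- per_subject_block_means
  if (is.matrix(d)) {
    first <- d[, first_block]; last <- d[, last_block]
  } else {
    pick <- function(b) {
      sub <- d[d$block == b, ]
      stats::setNames(sub$value, sub$subject)
    }
    first <- pick(first_block); last <- pick(last_block)
    common <- intersect(names(first), names(last))
    first <- first[common]; last <- last[common]
  }
  diffs <- first - last
  n <- length(diffs)
  if (n < 2) stop("need at least 2 subjects with both blocks",
                  call. = FALSE)
  m <- mean(diffs); s <- stats::sd(diffs)
  out <- list(mean = m, sd = s, sem = s / sqrt(n),
              t = NA_real_, p = NA_real_, n = n, differences = diffs)
  if (s > 0) {
    tt <- stats::t.test(diffs)
    out$t <- unname(tt$statistic); out$p <- tt$p.value
  } else {
    attr(out, "flag") <- "zero_variance"
  }
  out
}
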