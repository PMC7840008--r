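# Internal helpers shared across modules.

# Wrap an angle difference to (-180, 180].
wrap_angle <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# Signed bearing (deg) of a 2D vector under the package convention:
# 0 deg = straight toward the far cushion (+y), positive = leftward (-x).
bearing_deg <- function(v) {
  atan2(-v[1], v[2]) * 180 / pi
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 ||
      x != round(x)) {
    stop(sprintf("configuration error: '%s' must be a positive integer",
                 name), call. = FALSE)
  }
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop(sprintf("configuration error: '%s' must be a non-negative number",
                 name), call. = FALSE)
  }
  as.numeric(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    stop(sprintf("configuration error: '%s' must be a positive number",
                 name), call. = FALSE)
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
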