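# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.check_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("`%s` must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    .stopf("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

#' Wrap angles to the principal interval [0, 2*pi)
#' @param theta numeric vector of angles (radians)
#' @return wrapped angles
#' @export
wrap_angle <- function(theta) theta %% (2 * pi)

#' Signed circular distance a - b across the lesser angle, in (-pi, pi]
#' @param a,b angles in radians
#' @return signed differences
#' @export
circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Circular mean of angles
#' @param theta angles in radians
#' @param w optional non-negative weights
#' @return mean angle in [0, 2*pi)
#' @export
circ_mean <- function(theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(theta))
  wrap_angle(atan2(sum(w * sin(theta)), sum(w * cos(theta))))
}

# Convex blend of two angles across the lesser angle between them.
circ_blend <- function(a, b, alpha) {
  wrap_angle(a + alpha * circ_dist(b, a))
}

#' Unwrap a phase trace along time (remove 2*pi discontinuities)
#' @param theta angles in radians sampled over time
#' @return unwrapped (continuous) trace
#' @export
unwrap_phase <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  jump <- ifelse(d > pi, -2 * pi, ifelse(d < -pi, 2 * pi, 0))
  theta + c(0, cumsum(jump))
}

# Soft-normalization factors from a rates matrix (neurons x samples):
# scale_n = 1 / (range_n + const); offset_n = mean of scaled rates per neuron.
# Applying: xn = x * scale - offset. Reversing: x = (xn + offset) / scale.
soft_norm_factors <- function(rates, const) {
  rng <- apply(rates, 1L, function(r) diff(range(r)))
  scale <- 1 / (rng + const)
  scaled <- rates * scale
  list(scale = scale, offset = rowMeans(scaled))
}

soft_norm_apply <- function(rates, f) rates * f$scale - f$offset
soft_norm_revert <- function(rates, f) (rates + f$offset) / f$scale
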