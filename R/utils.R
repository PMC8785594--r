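# Internal helpers shared across modules.

#' Round half away from zero to a fixed number of decimals
#'
#' Clinical reports in this package round rates, times and doses half-up
#' (54.99 -> 55.0), unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ruplaque_invalid_input", "ruplaque_error")))
}

stop_infeasible <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("ruplaque_infeasible", "ruplaque_error")))
}

# trapezoidal integral
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# linear interpolation that errors outside the table range
interp_strict <- function(x, y, xout, what = "value") {
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9)) {
    stop_invalid("%s interpolation outside table range [%g, %g]",
                 what, min(x), max(x))
  }
  stats::approx(x, y, xout, rule = 2)$y
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop_invalid("cannot normalize a zero vector")
  v / n
}

# in-plane unit vector at angle phi (radians) from the posterior pole axis
# (+x); positive angles rotate toward +y (temporal side).
u_phi <- function(phi) c(cos(phi), sin(phi), 0)

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# orthonormal basis perpendicular to unit vector a
perp_basis <- function(a) {
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(pracma_cross(ref, a))
  e2 <- pracma_cross(a, e1)
  list(e1 = e1, e2 = e2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
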