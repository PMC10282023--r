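#' circART: two-sample tests for circular data
#'
#' Two-sample hypothesis tests for angular observations, centred on the
#' Angular Randomisation Test (ART), whose statistic is the sum of geodesic
#' angular distances over all cross-sample pairs and whose significance is
#' assessed by permutation. Comparator tests (Watson's U2, Watson-Wheeler,
#' Rao spacing frequencies), samplers for three circular families, and a
#' Monte-Carlo power / type-I error framework are included.
#'
#' @useDynLib circART, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pchisq runif rnorm setNames
#' @importFrom utils head modifyList
#' @keywords internal
"_PACKAGE"

TWO_PI <- 2 * pi

stop_if_not_finite <- function(x, arg) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(!is.finite(x))) {
    stop("`", arg, "` must be finite numeric, got ",
         if (length(x) == 0L) "empty input" else "non-finite values",
         call. = FALSE)
  }
  invisible(x)
}

#' Wrap angles into [0, 2*pi)
#'
#' Reduces any finite angle (in radians) modulo \eqn{2\pi} into the half-open
#' interval \eqn{[0, 2\pi)}. Exact multiples of \eqn{2\pi} map to 0. The
#' function is idempotent and vectorised.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of the same length, all elements in \eqn{[0, 2\pi)}.
#' @examples
#' wrap_angle(c(2 * pi, -pi / 2, 7.5 * pi))
#' @export
wrap_angle <- function(x) {
  stop_if_not_finite(x, "x")
  w <- x %% TWO_PI
  # %% can return 2*pi itself for tiny negative inputs via rounding
  w[w >= TWO_PI] <- 0
  w
}

#' Convert degrees to wrapped radians
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles in radians, wrapped into \eqn{[0, 2\pi)}.
#' @examples
#' to_radians(c(180, 360, 450))
#' @export
to_radians <- function(x) {
  stop_if_not_finite(x, "x")
  wrap_angle(x * pi / 180)
}

#' Geodesic (shortest-arc) distance between angles
#'
#' The shorter of the two arc lengths separating two points on the unit
#' circle: \eqn{D(a, b) = \min(\Delta, 2\pi - \Delta)} with
#' \eqn{\Delta = |a - b| \bmod 2\pi}. The result lies in \eqn{[0, \pi]}, is
#' symmetric in its arguments, and is invariant under rotating or reflecting
#' both arguments together. Inputs need not be pre-wrapped. Vectorised with
#' the usual recycling rules.
#'
#' @param a,b Numeric vectors of angles in radians.
#' @return Numeric vector of distances in \eqn{[0, \pi]}.
#' @examples
#' geodesic_distance(0, pi)        # antipodal: pi
#' geodesic_distance(pi / 4, 7 * pi / 4)  # pi/2, the short way round
#' @export
geodesic_distance <- function(a, b) {
  stop_if_not_finite(a, "a")
  stop_if_not_finite(b, "b")
  d <- abs(a - b) %% TWO_PI
  pmin(d, TWO_PI - d)
}

#' Construct a sample of circular observations
#'
#' Validates and wraps a vector of angles into \eqn{[0, 2\pi)}, recording the
#' unit the data arrived in. All test functions accept either a plain numeric
#' vector of radians or an `angle_sample`.
#'
#' @param x Numeric vector of angles, length at least 1.
#' @param unit Unit of `x`: `"radians"` (default) or `"degrees"`.
#' @return An object of class `angle_sample`: a numeric vector of wrapped
#'   radians with attribute `unit` recording the input unit.
#' @examples
#' angle_sample(c(0, 90, 180), unit = "degrees")
#' @export
angle_sample <- function(x, unit = c("radians", "degrees")) {
  unit <- match.arg(unit)
  stop_if_not_finite(x, "x")
  if (length(x) < 1L) stop("an angle_sample needs at least one angle", call. = FALSE)
  ang <- if (unit == "degrees") to_radians(x) else wrap_angle(x)
  structure(ang, class = "angle_sample", unit = unit)
}

#' @export
print.angle_sample <- function(x, ...) {
  cat("angle_sample: ", length(x), " angles (radians, wrapped to [0, 2pi)),",
      " recorded in ", attr(x, "unit"), "\n", sep = "")
  print(as.numeric(x), ...)
  invisible(x)
}

# Coerce test input to a bare numeric vector of wrapped radians.
as_angles <- function(x, arg = deparse(substitute(x))) {
  if (inherits(x, "angle_sample")) return(as.numeric(x))
  stop_if_not_finite(x, arg)
  if (length(x) < 1L) stop("`", arg, "` must contain at least one angle", call. = FALSE)
  wrap_angle(as.numeric(x))
}
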