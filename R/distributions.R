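#' Sample from a von Mises distribution
#'
#' Exact draws from \eqn{VM(\mu, \kappa)} by the Best-Fisher rejection
#' algorithm, wrapped into \eqn{[0, 2\pi)}. The concentration \eqn{\kappa = 0}
#' short-circuits to the circular uniform distribution. Uses R's global RNG,
#' so results are reproducible under `set.seed()`.
#'
#' @param mu Mean direction in radians.
#' @param kappa Concentration parameter, `kappa >= 0`; 0 gives circular
#'   uniform.
#' @param size Number of draws, at least 1.
#' @return An [angle_sample] of `size` wrapped radians.
#' @examples
#' set.seed(1)
#' sample_von_mises(pi / 3, kappa = 8, size = 5)
#' @export
sample_von_mises <- function(mu, kappa, size) {
  stop_if_not_finite(mu, "mu")
  stop_if_not_finite(kappa, "kappa")
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  if (size < 1) stop("`size` must be >= 1", call. = FALSE)
  size <- as.integer(size)
  if (kappa == 0) {
    return(angle_sample(runif(size, 0, TWO_PI)))
  }
  angle_sample(mu + rvm_centred(size, kappa))
}

# Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler for
# VM(0, kappa), vectorised in batches. Accepted deviates are kept in
# proposal order so the output is a deterministic function of the RNG stream.
rvm_centred <- function(n, kappa) {
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(32L, ceiling(1.3 * (n - length(out))))
    u1 <- runif(m)
    u2 <- runif(m)
    u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cq <- kappa * (r - f)
    ok <- (cq * (2 - cq) - u2 > 0) | (log(cq / u2) + 1 - cq >= 0)
    theta <- sign(u3 - 0.5) * acos(f)
    out <- c(out, theta[ok])
  }
  out[seq_len(n)]
}

#' Sample from an axial von Mises distribution
#'
#' A 50/50 mixture of \eqn{VM(\mu, \kappa)} and \eqn{VM(\mu + \pi, \kappa)}:
#' two equal modes on opposite sides of the circle, as arises for undirected
#' body-axis orientations. Each draw picks a mode with probability one half.
#'
#' @inheritParams sample_von_mises
#' @param mu Direction of the first of the two antipodal modes, radians.
#' @return An [angle_sample] of `size` wrapped radians.
#' @examples
#' set.seed(1)
#' sample_axial_von_mises(0, kappa = 8, size = 5)
#' @export
sample_axial_von_mises <- function(mu, kappa, size) {
  stop_if_not_finite(mu, "mu")
  stop_if_not_finite(kappa, "kappa")
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  if (size < 1) stop("`size` must be >= 1", call. = FALSE)
  size <- as.integer(size)
  mode_flip <- pi * (runif(size) < 0.5)
  if (kappa == 0) {
    return(angle_sample(mode_flip + runif(size, 0, TWO_PI)))
  }
  angle_sample(mu + mode_flip + rvm_centred(size, kappa))
}

#' Sample from a wrapped skew-normal distribution
#'
#' Draws a latent skew-normal variable by the convolution representation
#' (\eqn{\delta = \alpha / \sqrt{1 + \alpha^2}};
#' \eqn{Z = \delta |U_0| + \sqrt{1 - \delta^2}\, U_1} with independent
#' standard normals \eqn{U_0, U_1}), then returns
#' \eqn{(\xi + \rho Z) \bmod 2\pi}. With \eqn{\alpha = 0} this reduces to a
#' wrapped normal with location \eqn{\xi} and scale \eqn{\rho}; increasing
#' \eqn{|\alpha|} increases skew (positive \eqn{\alpha}: left skew).
#'
#' @param xi Location parameter, radians.
#' @param rho Dispersion (scale) parameter, `rho > 0`.
#' @param alpha Shape (skewness) parameter; 0 gives a symmetric distribution.
#' @param size Number of draws, at least 1.
#' @return An [angle_sample] of `size` wrapped radians.
#' @examples
#' set.seed(1)
#' sample_wrapped_skew_normal(0, rho = 1, alpha = 30, size = 5)
#' @export
sample_wrapped_skew_normal <- function(xi, rho, alpha, size) {
  stop_if_not_finite(xi, "xi")
  stop_if_not_finite(rho, "rho")
  stop_if_not_finite(alpha, "alpha")
  if (rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  if (size < 1) stop("`size` must be >= 1", call. = FALSE)
  size <- as.integer(size)
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(size)
  u1 <- rnorm(size)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  angle_sample(xi + rho * z)
}

#' Specify a circular distribution
#'
#' A tagged parameter bundle naming one of the three generative families used
#' by the simulation framework, checked against that family's constraints.
#'
#' @param family One of `"von_mises"`, `"axial_von_mises"`,
#'   `"wrapped_skew_normal"`.
#' @param mu Mean direction (radians); von Mises families only. For the axial
#'   family, the first of the two antipodal modes.
#' @param kappa Concentration, `>= 0`; von Mises families only.
#' @param xi Location (radians); wrapped skew-normal only.
#' @param rho Dispersion, `> 0`; wrapped skew-normal only.
#' @param alpha Shape; wrapped skew-normal only.
#' @return An object of class `distribution_spec`.
#' @examples
#' distribution_spec("von_mises", mu = 0, kappa = 2)
#' distribution_spec("wrapped_skew_normal", xi = 0, rho = 1, alpha = 30)
#' @export
distribution_spec <- function(family = c("von_mises", "axial_von_mises",
                                         "wrapped_skew_normal"),
                              mu = NULL, kappa = NULL,
                              xi = NULL, rho = NULL, alpha = NULL) {
  family <- match.arg(family)
  spec <- if (family == "wrapped_skew_normal") {
    if (is.null(xi) || is.null(rho) || is.null(alpha)) {
      stop("wrapped_skew_normal requires `xi`, `rho` and `alpha`", call. = FALSE)
    }
    if (!is.null(mu) || !is.null(kappa)) {
      stop("`mu`/`kappa` do not apply to the wrapped skew-normal family",
           call. = FALSE)
    }
    if (rho <= 0) stop("`rho` must be > 0", call. = FALSE)
    list(family = family, xi = wrap_angle(xi), rho = rho, alpha = alpha)
  } else {
    if (is.null(mu) || is.null(kappa)) {
      stop(family, " requires `mu` and `kappa`", call. = FALSE)
    }
    if (!is.null(xi) || !is.null(rho) || !is.null(alpha)) {
      stop("`xi`/`rho`/`alpha` do not apply to the ", family, " family",
           call. = FALSE)
    }
    if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
    list(family = family, mu = wrap_angle(mu), kappa = kappa)
  }
  structure(spec, class = "distribution_spec")
}

#' @export
format.distribution_spec <- function(x, ...) {
  if (x$family == "wrapped_skew_normal") {
    sprintf("WSN(xi=%g, rho=%g, alpha=%g)", x$xi, x$rho, x$alpha)
  } else {
    sprintf("%s(mu=%g, kappa=%g)",
            if (x$family == "von_mises") "VM" else "axialVM", x$mu, x$kappa)
  }
}

#' @export
print.distribution_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Draw a sample from a distribution_spec
#'
#' @param spec A [distribution_spec].
#' @param size Number of draws.
#' @return An [angle_sample].
#' @examples
#' set.seed(1)
#' sample_angles(distribution_spec("von_mises", mu = 0, kappa = 2), 10)
#' @export
sample_angles <- function(spec, size) {
  stopifnot(inherits(spec, "distribution_spec"))
  switch(spec$family,
    von_mises = sample_von_mises(spec$mu, spec$kappa, size),
    axial_von_mises = sample_axial_von_mises(spec$mu, spec$kappa, size),
    wrapped_skew_normal =
      sample_wrapped_skew_normal(spec$xi, spec$rho, spec$alpha, size)
  )
}
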