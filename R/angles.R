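#' Angle unit conversion
#'
#' All internal computation in this package is in radians; degrees appear only
#' at file and display boundaries (CSV columns, JSON parameter files).
#'
#' @param deg,rad angles in degrees / radians.
#' @return numeric vector of converted angles.
#' @export
deg2rad <- function(deg) deg * pi / 180

#' @rdname deg2rad
#' @export
rad2deg <- function(rad) rad * 180 / pi

#' Wrap angles into a half-open interval
#'
#' @param x angles (radians).
#' @param lower lower edge of the target interval; the interval is
#'   `[lower, lower + 2*pi)`.
#' @return wrapped angles.
#' @export
wrap_angle <- function(x, lower = 0) {
  (x - lower) %% (2 * pi) + lower
}

## log I0(kappa), overflow-safe: besselI(expon.scaled) returns I0(x)*exp(-x)
## but underflows to 0 beyond x ~ 1e5, where the asymptotic expansion
## I0(x) ~ e^x/sqrt(2 pi x) * (1 + 1/(8x) + 9/(128 x^2) + ...) is already
## accurate to full double precision
log_bessel_i0 <- function(x) {
  out <- x
  small <- x <= 5e4
  if (any(small)) {
    xs <- x[small]
    out[small] <- log(besselI(xs, 0, expon.scaled = TRUE)) + xs
  }
  if (any(!small)) {
    xl <- x[!small]
    out[!small] <- xl - 0.5 * log(2 * pi * xl) +
      log1p(1 / (8 * xl) + 9 / (128 * xl^2) + 225 / (3072 * xl^3))
  }
  out
}

#' von Mises density
#'
#' Circular analogue of the Gaussian: `exp(kappa*cos(theta - mu)) /
#' (2*pi*I0(kappa))`, where `I0` is the modified Bessel function of order 0.
#' Used throughout the observer model for the light-from-above prior over
#' illuminant tilt and for the observation noise on gradient and highlight
#' tilts.
#'
#' @param theta angle(s) at which to evaluate (radians).
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0); `kappa = 0` is the uniform density
#'   `1/(2*pi)`.
#' @param log if `TRUE` return the log density.
#' @return density per radian (vectorized over `theta`).
#' @export
von_mises_density <- function(theta, mu, kappa, log = FALSE) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  ld <- kappa * cos(theta - mu) - log(2 * pi) - log_bessel_i0(kappa)
  if (log) ld else exp(ld)
}

#' Full width at half height of a von Mises density
#'
#' The angular width (in degrees) over which the density exceeds half its peak
#' value: `2*acos(1 - log(2)/kappa)`. For `kappa < log(2)` the density never
#' falls to half its peak and the width is reported as 360 degrees.
#'
#' @param kappa concentration parameter(s), >= 0.
#' @return width in degrees (vectorized).
#' @examples
#' vm_fwhm(7.5) # a broad light prior, roughly 69 degrees
#' @export
vm_fwhm <- function(kappa) {
  if (any(kappa < 0)) stop("kappa must be non-negative")
  w <- rep(360, length(kappa))
  ok <- kappa >= log(2)
  w[ok] <- rad2deg(2 * acos(1 - log(2) / kappa[ok]))
  w
}
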