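#' Scene cross-section of a semi-ellipsoidal surface
#'
#' The stimulus geometry is analysed in the plane spanned by the viewing and
#' illuminant vectors. The concave surface cross-section is the lower half of
#' the ellipse `x^2 + z^2/d^2 = 1`: half-width normalized to 1, `d` the depth
#' expansion factor (depth semi-axis / half-width). The coordinate origin sits
#' at rim level directly above the concavity, `x` horizontal toward the
#' illuminant side and `z` toward the viewer.
#'
#' @param d depth expansion factor (> 0).
#' @param theta_l illuminant slant: angle between illuminant and view vector,
#'   radians, in `[0, pi/2)`.
#' @return an object of class `scene_section`.
#' @export
scene_section <- function(d, theta_l) {
  stopifnot(is.numeric(d), length(d) == 1, is.finite(d), d > 0,
            is.numeric(theta_l), length(theta_l) == 1, is.finite(theta_l),
            theta_l >= 0, theta_l < pi / 2)
  structure(list(d = d, theta_l = theta_l), class = "scene_section")
}

#' @export
print.scene_section <- function(x, ...) {
  cat(sprintf("scene section: depth factor %.3f, illuminant slant %.1f deg\n",
              x$d, rad2deg(x$theta_l)))
  invisible(x)
}

as_scene_section <- function(x, theta_l = NULL) {
  if (inherits(x, "scene_section")) x else scene_section(x, theta_l)
}

#' Specular highlight location on a concave semi-elliptical section
#'
#' The highlight sits at the surface point whose normal bisects the angle
#' between the view vector and the illuminant vector. On the concave section
#' the wall facing the illuminant is the bright wall; the bisector condition
#' reduces to `x/sqrt(1 - x^2) = tan(theta_l/2)/d`. The returned `x_s` is the
#' magnitude of the horizontal highlight coordinate; `side` records that the
#' highlight lies on the wall facing the illuminant (the wall opposite the
#' illuminant side of the rim).
#'
#' @param section a [scene_section()], or the depth factor `d` when `theta_l`
#'   is given separately.
#' @param theta_l illuminant slant (radians), used when `section` is numeric.
#' @return list with `x_s` (magnitude, in `[0, 1)`), `z_s` (depth coordinate,
#'   `<= 0`) and `side`.
#' @examples
#' highlight_location(1, deg2rad(60))$x_s # sin(30 deg) = 0.5
#' @export
highlight_location <- function(section, theta_l = NULL) {
  sec <- as_scene_section(section, theta_l)
  t_half <- tan(sec$theta_l / 2)
  x_s <- t_half / sqrt(sec$d^2 + t_half^2)
  list(x_s = x_s,
       z_s = -sec$d * sqrt(1 - x_s^2),
       side = "facing_illuminant")
}

#' Bas-relief family: illuminant slant implied by a depth estimate
#'
#' A highlight observed at horizontal position `x_s` is consistent with a
#' one-dimensional family of (depth, illuminant slant) scene interpretations:
#' for an estimated depth factor `d_hat` the required slant is
#' `2*atan(d_hat * x_s / sqrt(1 - x_s^2))`. Round-trips with
#' [highlight_location()].
#'
#' @param x_s highlight horizontal coordinate magnitude, `|x_s| < 1`.
#' @param d_hat estimated depth expansion factor(s) (> 0); vectorized.
#' @return required illuminant slant(s), radians.
#' @export
bas_relief_slant <- function(x_s, d_hat) {
  stopifnot(length(x_s) == 1, abs(x_s) < 1, all(d_hat > 0))
  slant <- 2 * atan(d_hat * abs(x_s) / sqrt(1 - x_s^2))
  if (any(slant >= pi)) stop("implied slant >= pi is geometrically meaningless")
  slant
}

#' Rim occlusion angle
#'
#' Angle between the view vector and the vector pointing from the candidate
#' highlight location (at the depth implied by `d_hat`) to the occluding rim
#' on the illuminant side. The highlight sits on the wall facing the
#' illuminant at `(-x_s, -d_hat*sqrt(1-x_s^2))`; the far rim is at `(1, 0)`,
#' so the angle is `atan((1 + x_s) / (d_hat * sqrt(1 - x_s^2)))`. Strictly
#' decreasing in `d_hat` and tending to `pi/2` for a flat surface.
#'
#' @inheritParams bas_relief_slant
#' @return rim angle(s), radians.
#' @export
rim_angle <- function(x_s, d_hat) {
  stopifnot(length(x_s) == 1, abs(x_s) < 1, all(d_hat > 0))
  atan((1 + abs(x_s)) / (d_hat * sqrt(1 - x_s^2)))
}

#' Feasibility boundary of concave scene interpretations
#'
#' For a rendered configuration (true depth factor and illuminant slant) the
#' observed highlight position pins a one-dimensional bas-relief family of
#' concave interpretations. Interpretations whose required illuminant slant
#' exceeds the rim angle are physically infeasible: the rim would occlude the
#' light ray generating the highlight. This function tabulates both curves
#' over a grid of estimated depth factors and locates the critical depth
#' (smallest `d_hat` with `theta_l >= theta_r`) by bisection.
#'
#' @param true_section a [scene_section()] (or depth factor with `theta_l`).
#' @param theta_l illuminant slant (radians) when a bare depth is given.
#' @param d_hat_range range of estimated depth factors to tabulate.
#' @param n_grid number of grid points (also used to pre-bracket the root).
#' @param tol absolute bisection tolerance on `d_hat` (the slant difference is
#'   resolved well below 1e-6 rad at this tolerance).
#' @return object of class `feasibility_curve`: a list with `curve` (data frame
#'   of `d_hat`, `theta_l`, `theta_r`, `feasible`), `x_s`, `d_crit`,
#'   `theta_crit`, and the true configuration. `d_crit` is `NA` with a
#'   `"no crossing in range"` note when the grid excludes the crossing.
#' @examples
#' fc <- feasibility_curve(scene_section(0.5, deg2rad(68)))
#' fc$d_crit               # about 0.61
#' rad2deg(fc$theta_crit)  # about 79 degrees
#' @export
feasibility_curve <- function(true_section, theta_l = NULL,
                              d_hat_range = c(0.05, 3), n_grid = 512,
                              tol = 1e-6) {
  sec <- as_scene_section(true_section, theta_l)
  stopifnot(length(d_hat_range) == 2, d_hat_range[1] > 0,
            d_hat_range[2] > d_hat_range[1], n_grid >= 8)
  hl <- highlight_location(sec)
  x_s <- hl$x_s
  if (bas_relief_slant(x_s, sec$d) >= rim_angle(x_s, sec$d))
    stop("true configuration does not render a visible highlight")

  d_hat <- seq(d_hat_range[1], d_hat_range[2], length.out = n_grid)
  th_l <- bas_relief_slant(x_s, d_hat)
  th_r <- rim_angle(x_s, d_hat)
  gap <- th_l - th_r # strictly increasing in d_hat

  d_crit <- NA_real_
  theta_crit <- NA_real_
  note <- NULL
  if (gap[1] >= 0 || gap[n_grid] < 0) {
    note <- "no crossing in range"
  } else {
    i <- which(gap >= 0)[1]
    lo <- d_hat[i - 1]
    hi <- d_hat[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (bas_relief_slant(x_s, mid) - rim_angle(x_s, mid) >= 0) hi <- mid
      else lo <- mid
    }
    d_crit <- (lo + hi) / 2
    theta_crit <- bas_relief_slant(x_s, d_crit)
  }
  structure(list(
    curve = data.frame(d_hat = d_hat, theta_l = th_l, theta_r = th_r,
                       feasible = th_l < th_r),
    x_s = x_s, d = sec$d, theta_l_true = sec$theta_l,
    d_crit = d_crit, theta_crit = theta_crit, note = note
  ), class = "feasibility_curve")
}

#' @export
print.feasibility_curve <- function(x, ...) {
  cat(sprintf("feasibility curve for (d = %.3f, slant = %.1f deg), highlight at x_s = %.4f\n",
              x$d, rad2deg(x$theta_l_true), x$x_s))
  if (is.na(x$d_crit)) {
    cat(" ", x$note, "\n")
  } else {
    cat(sprintf("  concave interpretations infeasible beyond d_hat = %.4f (slant %.2f deg)\n",
                x$d_crit, rad2deg(x$theta_crit)))
  }
  invisible(x)
}

#' Highlight eccentricity on a dome stimulus
#'
#' The third experiment's stimuli are spherical-cap domes of unit half-width
#' and depth `depth_ratio`, cut from a sphere of radius
#' `R = (1 + depth_ratio^2) / (2 * depth_ratio)`. Sphere normals are radial,
#' so the highlight sits where the radial direction bisects view and
#' illuminant vectors; its image-plane distance from the dome centre, as a
#' fraction of the dome half-width, is `R * sin(slant/2)`. Increasing in
#' slant, decreasing in depth.
#'
#' @param depth_ratio dome depth / half-width, in `(0, 1]`; vectorized.
#' @param slant illuminant slant (radians); vectorized.
#' @return eccentricity (dimensionless fraction of the dome half-width).
#' @export
dome_eccentricity <- function(depth_ratio, slant) {
  stopifnot(all(depth_ratio > 0), all(depth_ratio <= 1), all(slant >= 0))
  R <- (1 + depth_ratio^2) / (2 * depth_ratio)
  ecc <- R * sin(slant / 2)
  # highlight must lie on the cap: polar angle from the axis at most the rim's
  on_cap <- (ecc <= 1 + 1e-12) & (cos(slant / 2) >= (R - depth_ratio) / R - 1e-12)
  if (any(!on_cap)) stop("highlight falls outside the spherical cap")
  ecc
}

#' Monte-Carlo probability that a concave interpretation is infeasible
#'
#' Bridges the occlusion geometry to the observer model's scalar occlusion
#' parameter: given uncertainty about the perceived depth factor, scene
#' interpretations are sampled along the bas-relief family fixed by the
#' rendered highlight, with optional additional slant jitter, and the fraction
#' falling in the infeasible region (required slant at or beyond the rim
#' angle) is returned. Depth estimates are drawn from a log-normal centred on
#' the true depth, respecting the one-dimensional structure of the ambiguity.
#'
#' @param true_section a [scene_section()] (or depth factor with `theta_l`).
#' @param theta_l illuminant slant (radians) when a bare depth is given.
#' @param depth_uncertainty log-normal spread (sdlog) of the depth estimate
#'   (>= 0; 0 means the true depth is known).
#' @param slant_uncertainty circular (wrapped normal) sd of additional slant
#'   jitter, radians (>= 0).
#' @param n_samples Monte-Carlo sample count.
#' @param seed integer seed; sampling is reproducible.
#' @return estimated occlusion probability in `[0, 1]`.
#' @export
occlusion_probability <- function(true_section, theta_l = NULL,
                                  depth_uncertainty = 0.35,
                                  slant_uncertainty = 0,
                                  n_samples = 1e5, seed = 1) {
  sec <- as_scene_section(true_section, theta_l)
  stopifnot(depth_uncertainty >= 0, slant_uncertainty >= 0, n_samples >= 1)
  x_s <- highlight_location(sec)$x_s
  if (depth_uncertainty == 0 && slant_uncertainty == 0) {
    return(as.numeric(bas_relief_slant(x_s, sec$d) >= rim_angle(x_s, sec$d)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  d_hat <- sec$d * exp(stats::rnorm(n_samples, 0, depth_uncertainty))
  slant_hat <- 2 * atan(d_hat * abs(x_s) / sqrt(1 - x_s^2))
  if (slant_uncertainty > 0)
    slant_hat <- abs(slant_hat + stats::rnorm(n_samples, 0, slant_uncertainty))
  mean(slant_hat >= rim_angle(x_s, d_hat))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
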