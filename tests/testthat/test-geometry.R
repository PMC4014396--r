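test_that("highlight location matches the circular closed form and a grid-search oracle", {
  # circle: radial normals make the bisector condition x_s = sin(theta_l/2)
  for (th in deg2rad(seq(0, 89, by = 1))) {
    expect_equal(highlight_location(1, th)$x_s, sin(th / 2), tolerance = 1e-9)
  }
  # frontal illumination puts the highlight at the apex for any depth
  expect_equal(highlight_location(0.5, 0)$x_s, 0)

  # independent oracle: maximize alignment of the surface normal with the
  # view/illuminant bisector over a dense grid of surface points
  grid_oracle <- function(d, th) {
    x <- seq(0, 1 - 1e-9, length.out = 2e5)
    nrm <- cbind(x, sqrt(1 - x^2) / d)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    x[which.max(nrm %*% c(sin(th / 2), cos(th / 2)))]
  }
  for (case in list(c(0.5, 68), c(1.3, 40), c(0.8, 75))) {
    hl <- highlight_location(case[1], deg2rad(case[2]))
    expect_equal(hl$x_s, grid_oracle(case[1], deg2rad(case[2])),
                 tolerance = 1e-4)
    # point lies on the ellipse, below rim level
    expect_equal(hl$x_s^2 + hl$z_s^2 / case[1]^2, 1, tolerance = 1e-9)
    expect_lt(hl$z_s, 0)
  }
  expect_equal(highlight_location(0.5, deg2rad(68))$x_s, 0.8033498,
               tolerance = 1e-6)
})

test_that("bas-relief slant round-trips with the highlight location", {
  set.seed(1)
  for (i in 1:25) {
    d <- runif(1, 0.1, 2.5)
    th <- runif(1, 0, pi / 2 - 0.01)
    x_s <- highlight_location(d, th)$x_s
    expect_equal(bas_relief_slant(x_s, d), th, tolerance = 1e-9)
  }
  expect_equal(bas_relief_slant(0, 1.7), 0)
  # frozen from grid-search inversion of highlight_location
  expect_equal(rad2deg(bas_relief_slant(0.803, 0.6)), 77.905, tolerance = 1e-2)
})

test_that("rim angle has the right limits, value and monotonicity", {
  expect_equal(rad2deg(rim_angle(0.803, 1e-9)), 90, tolerance = 1e-5)
  # frozen from explicit vector components: highlight at
  # (-x_s, -d*sqrt(1-x_s^2)), far rim at (1, 0)
  x_s <- 0.803
  d <- 0.5
  v <- c(1 + x_s, d * sqrt(1 - x_s^2))
  expect_equal(rim_angle(x_s, d), atan2(v[1], v[2]), tolerance = 1e-12)
  expect_equal(rad2deg(rim_angle(x_s, d)), 80.615, tolerance = 1e-2)
  expect_lt(rim_angle(0.803, 0.8), rim_angle(0.803, 0.5))
  d_grid <- seq(0.05, 3, length.out = 100)
  expect_true(all(diff(rim_angle(0.4, d_grid)) < 0))
})

test_that("feasibility curve reproduces the printed occlusion threshold", {
  fc <- feasibility_curve(scene_section(0.5, deg2rad(68)))
  expect_equal(fc$d_crit, 0.6, tolerance = 0.03)
  expect_equal(rad2deg(fc$theta_crit), 79, tolerance = 1.5 / 79)
  # equivalently: depth overestimated by ~20%+, slant by ~16%+
  expect_equal(fc$d_crit / 0.5 - 1, 0.20, tolerance = 0.10)
  expect_equal(rad2deg(fc$theta_crit) / 68 - 1, 0.16, tolerance = 0.10)
  expect_gt(fc$d_crit, 0.5)

  # curve monotonicity over the tabulated range
  expect_true(all(diff(fc$curve$theta_l) > 0))
  expect_true(all(diff(fc$curve$theta_r) < 0))
  # the rendered configuration itself is feasible
  expect_true(fc$curve$feasible[which.min(abs(fc$curve$d_hat - 0.5))])

  # d_crit exceeds the true depth whenever the configuration renders a
  # visible highlight (deep, steeply lit sections are rejected up front)
  set.seed(2)
  for (i in 1:10) {
    d <- runif(1, 0.2, 1.2)
    th <- runif(1, deg2rad(20), deg2rad(75))
    f <- tryCatch(feasibility_curve(scene_section(d, th),
                                    d_hat_range = c(0.02, 50)),
                  error = function(e) e)
    if (inherits(f, "error")) {
      expect_match(conditionMessage(f), "does not render a visible highlight")
    } else if (!is.na(f$d_crit)) {
      expect_gt(f$d_crit, d)
    }
  }

  # range excluding the crossing is reported, not fabricated
  f2 <- feasibility_curve(scene_section(0.5, deg2rad(68)),
                          d_hat_range = c(0.05, 0.3))
  expect_true(is.na(f2$d_crit))
  expect_match(f2$note, "no crossing in range")
})

test_that("dome eccentricity follows the spherical-cap geometry", {
  expect_equal(dome_eccentricity(0.7, 0), 0)
  for (s in deg2rad(seq(10, 80, by = 10)))
    expect_equal(dome_eccentricity(1, s), sin(s / 2), tolerance = 1e-12)
  # monotone increasing in slant, decreasing in depth over the dome design
  # grid, wherever the highlight stays on the cap (the shallowest dome at the
  # steepest slants puts the bisector point beyond the rim)
  slants <- deg2rad(seq(25, 75, by = 10))
  depths <- c(0.25, 0.5, 0.75, 1)
  on_cap <- function(h, s) {
    R <- (1 + h^2) / (2 * h)
    R * sin(s / 2) <= 1 & cos(s / 2) >= (R - h) / R
  }
  for (d in depths) {
    ok <- slants[on_cap(d, slants)]
    expect_true(all(diff(dome_eccentricity(d, ok)) > 0))
  }
  for (s in slants) {
    ok <- depths[on_cap(depths, s)]
    expect_true(all(diff(dome_eccentricity(ok, s)) < 0))
  }
  expect_lt(dome_eccentricity(0.5, deg2rad(45)),
            dome_eccentricity(0.25, deg2rad(45)))
  # shallow dome + extreme slant: bisector point beyond the rim
  expect_error(dome_eccentricity(0.1, deg2rad(60)), "outside")
})

test_that("occlusion probability is a seeded Monte-Carlo bridge with the right limits", {
  # zero uncertainty: deterministic feasibility of the true configuration
  expect_identical(occlusion_probability(0.5, deg2rad(68), 0, 0), 0)
  expect_identical(occlusion_probability(1, deg2rad(75), 0, 0), 1)
  # reproducible
  p1 <- occlusion_probability(0.5, deg2rad(68), 0.35, 0, n_samples = 2e4, seed = 9)
  p2 <- occlusion_probability(0.5, deg2rad(68), 0.35, 0, n_samples = 2e4, seed = 9)
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 < 1)
  # monotone in true depth at equal spreads (deeper truth sits closer to the
  # infeasible region)
  p_deep <- occlusion_probability(1.0, deg2rad(68), 0.35, 0,
                                  n_samples = 1e5, seed = 3)
  expect_lte(p1, p_deep)
  # monotone in true slant
  p_slant <- occlusion_probability(0.5, deg2rad(80), 0.35, 0,
                                   n_samples = 1e5, seed = 3)
  p_base <- occlusion_probability(0.5, deg2rad(68), 0.35, 0,
                                  n_samples = 1e5, seed = 3)
  expect_lte(p_base, p_slant)
})
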