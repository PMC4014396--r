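test_that("von Mises density is normalized and matches quadrature", {
  expect_equal(von_mises_density(1.3, 0.2, 0), 1 / (2 * pi))
  for (kap in c(0.5, 2, 5, 50, 500)) {
    expect_equal(circle_quad(function(x) von_mises_density(x, 1, kap)), 1,
                 tolerance = 1e-8)
  }
  expect_equal(von_mises_density(0, 0, 2), exp(2) / (2 * pi * besselI(2, 0)),
               tolerance = 1e-12)
  expect_error(von_mises_density(0, 0, -1), "non-negative")
})

test_that("von Mises width at half height behaves at its limits and on the reference fits", {
  expect_lt(vm_fwhm(1e6), 0.2)
  expect_equal(vm_fwhm(log(2)), 180)
  expect_equal(vm_fwhm(0.3), 360) # never falls to half its peak
  # average width of the ten observers' fitted light priors
  tab <- reference_observer_params()
  kap <- tab$kappa_phi[tab$observer %in% c(1, 2, 4:11)]
  expect_length(kap, 10)
  expect_equal(mean(vm_fwhm(kap)), 68.9, tolerance = 0.5 / 68.9)
})

test_that("hypothesis enumeration matches exhaustive generate-and-filter", {
  for (d in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    obs <- trial_observation(1, d[1], if (d[1]) 1 else NA,
                             1 + pi, d[2], if (d[2]) 2 else NA)
    h <- enumerate_hypotheses(obs)
    expect_equal(nrow(h), oracle_hypothesis_count(d[1], d[2]))
    # no hypothesis without an unoccluded cause explains a highlight
    if (d[1] == 1) {
      expect_false(any(h$chi_1 == "matte" & h$beta_1 == "absent"))
      # convex shiny objects cannot have their highlight occluded, so a
      # convex target with a highlight and a local illuminant would show two
      expect_false(any(h$tau_1 == "convex" & h$chi_1 == "shiny" &
                         h$beta_1 == "present"))
    } else {
      # a convex shiny object always shows its highlight
      expect_false(any(h$tau_1 == "convex" & h$chi_1 == "shiny"))
    }
  }
})

test_that("hypothesis priors multiply independent factors and sum to one over the universe", {
  p <- random_params(11)
  # law of total probability over the full unconstrained universe
  total <- 0
  for (a1 in brute_object_universe()) for (a2 in brute_object_universe())
    total <- total + brute_object_prior(a1, p) * brute_object_prior(a2, p)
  expect_equal(total, 1, tolerance = 1e-12)
  # the same sum assembled from the per-delta enumerations (counts 0/1 only
  # cover the in-design patterns; the convex shiny+local double-highlight
  # configuration carries the remaining mass)
  mass <- 0
  for (d in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    obs <- trial_observation(0, d[1], if (d[1]) 0 else NA,
                             pi, d[2], if (d[2]) 0 else NA)
    h <- enumerate_hypotheses(obs)
    mass <- mass + sum(hypothesis_prior(h, p))
  }
  # both causes visible at once: convex shiny-with-local, or concave with
  # neither cause occluded
  double1 <- p$p_convex * p$p_shiny * p$p_local +
    (1 - p$p_convex) * p$p_shiny * p$p_local * (1 - p$p_os) * (1 - p$p_om)
  expect_equal(mass, (1 - double1)^2, tolerance = 1e-12)

  # certainty in convexity zeroes every concave hypothesis
  p1 <- model_params(p_convex = 1)
  obs <- trial_observation(0.3)
  h <- enumerate_hypotheses(obs)
  pri <- hypothesis_prior(h, p1)
  expect_true(all(pri[h$tau_1 == "concave" | h$tau_2 == "concave"] == 0))

  # direct product for one concrete hypothesis at the reference mean values
  pm <- reference_observer_params("mean")
  h1 <- enumerate_hypotheses(trial_observation(0.3))
  row <- h1[h1$alpha == 1 & h1$tau_1 == "convex" & h1$tau_2 == "convex" &
              h1$chi_1 == "matte" & h1$chi_2 == "matte" &
              h1$beta_1 == "absent" & h1$beta_2 == "absent", ]
  expect_equal(hypothesis_prior(row, pm),
               0.80 * 0.75^2 * 0.39^2 * 0.22^2, tolerance = 1e-12)
})

test_that("closed-form tilt marginal agrees with quadrature", {
  # a lone normalized prior integrates to one
  expect_equal(phi_marginal(numeric(0), numeric(0), 3.2, 0.5), 1)
  # opposite equal kernels cancel: resultant 0, I0(0) = 1 in the numerator
  val <- phi_marginal(c(4, 4), c(0.7, 0.7 + pi), prior_kappa = 0)
  expect_equal(val, 1 / ((2 * pi)^2 * besselI(4, 0)^2), tolerance = 1e-12)
  # arbitrary three-kernel case against a dense trapezoid quadrature
  kap <- c(2, 5, 1)
  ph <- c(0.3, 1.7, 4.0)
  oracle <- circle_quad(function(phi)
    vm_pdf(phi, 0.4, 2.5) * vm_pdf(ph[1], phi, kap[1]) *
      vm_pdf(ph[2], phi, kap[2]) * vm_pdf(ph[3], phi, kap[3]), 1e5)
  expect_equal(phi_marginal(kap, ph, 2.5, 0.4), oracle, tolerance = 1e-8)
  # log-Bessel path survives concentrations that overflow exp()
  expect_true(is.finite(phi_marginal(c(800, 900), c(0, 0.1), 700, 0,
                                     log = TRUE)))
})

test_that("trial likelihood kernels behave as the generative story dictates", {
  obs <- trial_observation(1.1)
  h <- enumerate_hypotheses(obs)
  row <- h[h$alpha == 1 & h$tau_1 == "convex" & h$tau_2 == "concave" &
             h$chi_1 == "matte" & h$chi_2 == "matte" &
             h$beta_1 == "absent" & h$beta_2 == "absent", ]
  # near-delta gradient noise: the marginal collapses onto the light prior
  # density at the gradient-consistent tilt
  p_inf <- model_params(mu = 0.4, kappa_phi = 2, kappa_n = 5e4)
  lik <- trial_likelihood(obs, row, p_inf)
  lik_opp <- trial_likelihood(obs, h[h$alpha == 1 & h$tau_1 == "concave" &
                                       h$tau_2 == "convex" &
                                       h$chi_1 == "matte" & h$chi_2 == "matte" &
                                       h$beta_1 == "absent" &
                                       h$beta_2 == "absent", ], p_inf)
  expect_equal(lik / lik_opp,
               von_mises_density(1.1, 0.4, 2) / von_mises_density(1.1 - pi, 0.4, 2),
               tolerance = 1e-3)

  # a local-illuminant highlight contributes a flat 1/(2*pi) in gamma
  p <- random_params(5)
  lik_at <- function(g) {
    o <- trial_observation(1.1, 1, g)
    hh <- enumerate_hypotheses(o)
    r <- hh[hh$alpha == 1 & hh$tau_1 == "convex" & hh$chi_1 == "matte" &
              hh$beta_1 == "present" & hh$tau_2 == "concave" &
              hh$chi_2 == "matte" & hh$beta_2 == "absent", ]
    trial_likelihood(o, r, p)
  }
  expect_equal(lik_at(0.2), lik_at(3.9), tolerance = 1e-12)

  # specular kernel: aligned vs opposite highlight likelihood ratio e^(2*kappa_n)
  spec_lik <- function(g) {
    o <- trial_observation(1.1, 1, g)
    hh <- enumerate_hypotheses(o)
    r <- hh[hh$alpha == 1 & hh$tau_1 == "convex" & hh$chi_1 == "shiny" &
              hh$beta_1 == "absent" & hh$tau_2 == "concave" &
              hh$chi_2 == "matte" & hh$beta_2 == "absent", ]
    trial_likelihood(o, r, model_params(kappa_phi = 0, kappa_n = 3), log = TRUE)
  }
  # with a flat light prior the ratio depends only on the resultants: the two
  # gradient kernels sit at the same phase, so aligned vs opposite highlight
  # gives resultants 3*kappa_n vs kappa_n (and e^(2*kappa_n) asymptotically)
  li0 <- function(x) log(besselI(x, 0, TRUE)) + x
  expect_equal(spec_lik(1.1) - spec_lik(1.1 + pi), li0(9) - li0(3),
               tolerance = 1e-9)
})

test_that("posterior over convexity has the model's symmetries and biases", {
  # symmetric horizontal case is exactly ambiguous in the highlight-free
  # universe; with highlight-bearing hypotheses active, the absence of a
  # highlight is itself (slightly) informative about curvature, so the
  # posterior only approaches 0.5 as the gradient noise vanishes
  p_sym0 <- model_params(mu = 0, kappa_phi = 4, p_convex = 0.5, p_single = 1,
                         p_shiny = 0, p_os = 0, kappa_n = 3, p_local = 0,
                         p_om = 0)
  expect_equal(posterior_convex(trial_observation(pi / 2), p_sym0), 0.5,
               tolerance = 1e-9)
  p_sym <- model_params(mu = 0, kappa_phi = 4, p_convex = 0.5, p_single = 1,
                        p_shiny = 0.3, p_os = 0.4, kappa_n = 3,
                        p_local = 0.3, p_om = 0.1)
  expect_equal(posterior_convex(trial_observation(pi / 2), p_sym), 0.5,
               tolerance = 0.02)
  p_sharp <- model_params(mu = 0, kappa_phi = 4, p_convex = 0.5, p_single = 1,
                          p_shiny = 0.3, p_os = 0.4, kappa_n = 50,
                          p_local = 0.3, p_om = 0.1)
  expect_equal(posterior_convex(trial_observation(pi / 2), p_sharp), 0.5,
               tolerance = 1e-6)
  # flat-prior neutrality at any orientation
  p_flat <- model_params(mu = 0, kappa_phi = 0, p_convex = 0.5, p_single = 1,
                         p_shiny = 0, p_os = 0, kappa_n = 4, p_local = 0,
                         p_om = 0)
  for (th in seq(0, 2 * pi, length.out = 9))
    expect_equal(posterior_convex(trial_observation(th), p_flat), 0.5,
                 tolerance = 1e-9)
  # near-delta noise closed form at the prior mean
  p3 <- model_params(mu = 0.7, kappa_phi = 3, p_convex = 0.5, p_single = 1,
                     p_shiny = 0, p_os = 0, kappa_n = 1e4, p_local = 0,
                     p_om = 0)
  expect_equal(posterior_convex(trial_observation(0.7), p3),
               1 / (1 + exp(-2 * 3)), tolerance = 1e-4)

  # complementarity under the single-light symmetric prior (highlight-free
  # universe): opposite-gradient posteriors sum to one
  p_c <- model_params(mu = 0.3, kappa_phi = 4, p_convex = 0.5, p_single = 1,
                      p_shiny = 0, p_os = 0, kappa_n = 3, p_local = 0, p_om = 0)
  for (th in seq(0, 2 * pi, length.out = 11)) {
    expect_equal(posterior_convex(trial_observation(th), p_c) +
                   posterior_convex(trial_observation(th + pi), p_c),
                 1, tolerance = 1e-9)
  }

  # an aligned highlight raises the convexity posterior, monotonically in p_os
  pm <- reference_observer_params("mean")
  mm <- posterior_convex(trial_observation(pi / 2), pm)
  sm <- posterior_convex(trial_observation(pi / 2, 1, pi / 2), pm)
  expect_gt(sm, mm)
  sm_pos <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(po) {
    pp <- pm
    pp$p_os <- po
    posterior_convex(trial_observation(pi / 2, 1, pi / 2), pp)
  }, numeric(1))
  expect_true(all(diff(sm_pos) > 0))

  # tilt-shift equivariance: rotating all tilts and mu together changes nothing
  p <- random_params(7)
  for (shift in c(0.5, 2.1)) {
    p_shift <- p
    p_shift$mu <- wrap_angle(p$mu + shift, -pi)
    o1 <- trial_observation(1.0, 1, 1.4)
    o2 <- trial_observation(1.0 + shift, 1, 1.4 + shift)
    expect_equal(posterior_convex(o2, p_shift), posterior_convex(o1, p),
                 tolerance = 1e-9)
  }
})

test_that("posterior over convexity matches the brute-force quadrature oracle", {
  p <- random_params(21)
  trials <- random_trials(12, 22)
  for (obs in trials) {
    expect_equal(posterior_convex(obs, p), oracle_posterior_convex(obs, p),
                 tolerance = 1e-6)
  }
})

test_that("posterior over specularity discounts misaligned highlights", {
  pm <- reference_observer_params("mean")
  expect_error(posterior_shiny(trial_observation(1), pm), "delta_target")
  p0 <- pm; p0$p_shiny <- 0
  expect_equal(posterior_shiny(trial_observation(1, 1, 1), p0), 0)
  p1 <- pm; p1$p_local <- 0
  expect_equal(posterior_shiny(trial_observation(1, 1, 1), p1), 1)
  aligned <- posterior_shiny(trial_observation(pi / 2, 1, pi / 2), pm)
  opposite <- posterior_shiny(trial_observation(pi / 2, 1, pi / 2 + pi), pm)
  expect_gt(aligned, opposite)
  # decreasing in the angular offset over the half circle
  offs <- seq(0, pi, length.out = 7)
  ps <- vapply(offs, function(o)
    posterior_shiny(trial_observation(pi / 2, 1, pi / 2 + o), pm), numeric(1))
  expect_true(all(diff(ps) < 0))
  # oracle agreement
  p <- random_params(31)
  obs <- trial_observation(2.2, 1, 0.9)
  expect_equal(posterior_shiny(obs, p),
               oracle_posterior_convex(obs, p, return_shiny = TRUE),
               tolerance = 1e-6)
})

test_that("probability matching with an optional lapse maps posterior to response", {
  pm <- reference_observer_params("mean")
  obs <- trial_observation(0.9, 1, 1.2)
  post <- posterior_convex(obs, pm)
  expect_equal(response_probability(obs, pm), post)
  nm <- c("mu", "kappa_phi", "p_convex", "p_single", "p_shiny", "p_os",
          "kappa_n", "p_local", "p_om")
  p_lapse <- do.call(model_params, c(unclass(pm)[nm], list(lapse = 1)))
  expect_equal(response_probability(obs, p_lapse), 0.5)
  p_l <- do.call(model_params, c(unclass(pm)[nm], list(lapse = 0.1)))
  expect_equal(response_probability(obs, p_l), 0.9 * post + 0.05)
})
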