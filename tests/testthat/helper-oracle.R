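# Independent oracles for the observer model, kept deliberately naive:
# trapezoid quadrature over illuminant tilt instead of the closed-form Bessel
# marginal, and exhaustive generate-and-filter hypothesis enumeration instead
# of the per-object case tables.

vm_pdf <- function(theta, mu, kappa) {
  exp(kappa * cos(theta - mu)) / (2 * pi * besselI(kappa, 0))
}

# trapezoid integral over the circle (periodic integrand, n equal panels)
circle_quad <- function(f, n = 1e4) {
  phi <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  sum(f(phi)) * 2 * pi / n
}

# all hidden-variable assignments for one object, ignoring the observation
brute_object_universe <- function() {
  out <- list()
  for (tau in c("convex", "concave")) for (chi in c("shiny", "matte"))
    for (beta in c("present", "absent")) {
      occ_s_vals <- if (tau == "concave" && chi == "shiny") 0:1 else NA
      occ_m_vals <- if (tau == "concave" && beta == "present") 0:1 else NA
      for (os in occ_s_vals) for (om in occ_m_vals)
        out[[length(out) + 1]] <- list(tau = tau, chi = chi, beta = beta,
                                       occ_s = os, occ_m = om)
    }
  out
}

brute_visible_count <- function(a) {
  spec_vis <- a$chi == "shiny" && !(isTRUE(a$occ_s == 1))
  local_vis <- a$beta == "present" && !(isTRUE(a$occ_m == 1))
  as.integer(spec_vis) + as.integer(local_vis)
}

brute_object_prior <- function(a, p) {
  pr <- (if (a$tau == "convex") p$p_convex else 1 - p$p_convex) *
    (if (a$chi == "shiny") p$p_shiny else 1 - p$p_shiny) *
    (if (a$beta == "present") p$p_local else 1 - p$p_local)
  if (!is.na(a$occ_s)) pr <- pr * (if (a$occ_s == 1) p$p_os else 1 - p$p_os)
  if (!is.na(a$occ_m)) pr <- pr * (if (a$occ_m == 1) p$p_om else 1 - p$p_om)
  pr
}

# which visible cause produced the observed highlight (NA if none visible)
brute_cause <- function(a) {
  if (a$chi == "shiny" && !(isTRUE(a$occ_s == 1))) "spec"
  else if (a$beta == "present" && !(isTRUE(a$occ_m == 1))) "local"
  else NA_character_
}

# per-object likelihood factors as a function of the object's illuminant tilt
brute_object_lik <- function(phi, a, theta, gamma, p) {
  off <- if (a$tau == "convex") 0 else pi
  lik <- vm_pdf(theta, phi + off, p$kappa_n)
  cause <- brute_cause(a)
  if (!is.na(cause)) {
    lik <- lik * (if (cause == "spec") vm_pdf(gamma, phi + off, p$kappa_n)
                  else 1 / (2 * pi))
  }
  lik
}

# posterior P(target convex) by exhaustive enumeration + quadrature
oracle_posterior_convex <- function(obs, p, n_nodes = 1e4,
                                    return_shiny = FALSE) {
  uni <- brute_object_universe()
  num <- 0
  num_shiny <- 0
  den <- 0
  for (a1 in uni) for (a2 in uni) {
    if (brute_visible_count(a1) != obs$delta_target) next
    if (brute_visible_count(a2) != obs$delta_distractor) next
    prior <- brute_object_prior(a1, p) * brute_object_prior(a2, p)
    for (alpha in 1:2) {
      pa <- if (alpha == 1) p$p_single else 1 - p$p_single
      if (prior * pa == 0) next
      if (alpha == 1) {
        lik <- circle_quad(function(phi)
          vm_pdf(phi, p$mu, p$kappa_phi) *
            brute_object_lik(phi, a1, obs$theta_target, obs$gamma_target, p) *
            brute_object_lik(phi, a2, obs$theta_distractor,
                             obs$gamma_distractor, p), n_nodes)
      } else {
        lik <- circle_quad(function(phi)
          vm_pdf(phi, p$mu, p$kappa_phi) *
            brute_object_lik(phi, a1, obs$theta_target, obs$gamma_target, p),
          n_nodes) *
          circle_quad(function(phi)
            vm_pdf(phi, p$mu, p$kappa_phi) *
              brute_object_lik(phi, a2, obs$theta_distractor,
                               obs$gamma_distractor, p), n_nodes)
      }
      w <- prior * pa * lik
      den <- den + w
      if (a1$tau == "convex") num <- num + w
      if (a1$chi == "shiny") num_shiny <- num_shiny + w
    }
  }
  if (return_shiny) num_shiny / den else num / den
}

# count of distinct consistent hypotheses (occlusion indicators included)
oracle_hypothesis_count <- function(delta_target, delta_distractor) {
  uni <- brute_object_universe()
  n1 <- sum(vapply(uni, function(a) brute_visible_count(a) == delta_target,
                   logical(1)))
  n2 <- sum(vapply(uni, function(a) brute_visible_count(a) == delta_distractor,
                   logical(1)))
  2L * n1 * n2
}

# random in-design trial observations (radians), mixed highlight patterns
random_trials <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    th <- runif(1, 0, 2 * pi)
    d1 <- rbinom(1, 1, 0.5)
    d2 <- rbinom(1, 1, 0.5)
    trial_observation(
      theta_target = th, delta_target = d1,
      gamma_target = if (d1 == 1) runif(1, 0, 2 * pi) else NA,
      theta_distractor = th + pi, delta_distractor = d2,
      gamma_distractor = if (d2 == 1) runif(1, 0, 2 * pi) else NA)
  })
}

random_params <- function(seed) {
  set.seed(seed)
  model_params(mu = runif(1, -pi / 4, pi / 4),
               kappa_phi = runif(1, 0.5, 12),
               p_convex = runif(1, 0.2, 0.95),
               p_single = runif(1, 0.2, 0.95),
               p_shiny = runif(1, 0.1, 0.9),
               p_os = runif(1, 0.05, 0.9),
               kappa_n = runif(1, 0.5, 12),
               p_local = runif(1, 0.1, 0.9),
               p_om = runif(1, 0.05, 0.9))
}
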