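#' A single two-alternative forced-choice trial observation
#'
#' The observable variables of one trial: the shading-gradient tilts of the
#' target and distractor objects, the presence/absence of a highlight on each,
#' and (when present) the highlight angular positions. Tilts are measured in
#' the image plane, 0 = bright at top, increasing clockwise, radians. In the
#' experimental designs the two gradients are always in opposition
#' (`theta_distractor = theta_target + pi`). Dome-stimulus trials additionally
#' carry a depth ratio and illuminant slant, which the standard nine-parameter
#' model does not consume (occlusion enters through scalar probabilities).
#'
#' @param theta_target,theta_distractor gradient tilts (radians).
#' @param delta_target,delta_distractor highlight presence flags (0/1).
#' @param gamma_target,gamma_distractor highlight tilts (radians); must be
#'   given exactly when the corresponding flag is 1.
#' @param depth_ratio,slant optional dome-stimulus descriptors.
#' @return an object of class `trial_observation`.
#' @export
trial_observation <- function(theta_target, delta_target = 0,
                              gamma_target = NA_real_,
                              theta_distractor = theta_target + pi,
                              delta_distractor = 0,
                              gamma_distractor = NA_real_,
                              depth_ratio = NA_real_, slant = NA_real_) {
  obs <- list(theta_target = wrap_angle(theta_target),
              theta_distractor = wrap_angle(theta_distractor),
              delta_target = as.integer(delta_target),
              delta_distractor = as.integer(delta_distractor),
              gamma_target = if (is.na(gamma_target)) NA_real_ else wrap_angle(gamma_target),
              gamma_distractor = if (is.na(gamma_distractor)) NA_real_ else wrap_angle(gamma_distractor),
              depth_ratio = depth_ratio, slant = slant)
  for (side in c("target", "distractor")) {
    d <- obs[[paste0("delta_", side)]]
    g <- obs[[paste0("gamma_", side)]]
    if (!d %in% 0:1) stop("delta flags must be 0 or 1")
    if (d == 1 && is.na(g))
      stop("gamma_", side, " must be given when delta_", side, " = 1")
    if (d == 0 && !is.na(g))
      stop("gamma_", side, " must be absent when delta_", side, " = 0")
  }
  structure(obs, class = "trial_observation")
}

## Per-object hidden-variable assignments consistent with an observed
## highlight count. A visible highlight needs an unoccluded cause (specular
## surface or local illuminant); occlusion is possible only for concave
## objects; a hypothesis must predict exactly the observed count, so for
## delta = 1 a convex shiny object cannot also carry a local illuminant.
## occ_s / occ_m are NA where the corresponding cause is inapplicable.
object_cases <- function(delta) {
  if (delta == 0) {
    data.frame(
      tau   = c("convex", "concave", "concave", "concave", "concave"),
      chi   = c("matte", "matte", "shiny", "matte", "shiny"),
      beta  = c("absent", "absent", "absent", "present", "present"),
      occ_s = c(NA, NA, 1L, NA, 1L),
      occ_m = c(NA, NA, NA, 1L, 1L),
      cause = c(NA, NA, NA, NA, NA),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      tau   = c("convex", "concave", "convex", "concave", "concave", "concave"),
      chi   = c("shiny", "shiny", "matte", "matte", "shiny", "shiny"),
      beta  = c("absent", "absent", "present", "present", "present", "present"),
      occ_s = c(NA, 0L, NA, NA, 1L, 0L),
      occ_m = c(NA, NA, NA, 0L, 0L, 1L),
      cause = c("spec", "spec", "local", "local", "local", "spec"),
      stringsAsFactors = FALSE)
  }
}

#' Enumerate scene hypotheses consistent with a trial observation
#'
#' Every discrete assignment of the hidden scene variables (illuminant count
#' `alpha`, per-object curvature sign `tau`, specular index `chi`,
#' local-illuminant flag `beta`, and occlusion indicators for concave objects
#' with an active cause) whose predicted count of visible highlights per
#' object equals the observed presence flags. The `cause_*` columns record
#' which cause produced a visible highlight (`"spec"` or `"local"`), which
#' determines the highlight-tilt likelihood kernel.
#'
#' @param obs a [trial_observation()].
#' @return data frame, one row per hypothesis.
#' @export
enumerate_hypotheses <- function(obs) {
  stopifnot(inherits(obs, "trial_observation"))
  c1 <- object_cases(obs$delta_target)
  c2 <- object_cases(obs$delta_distractor)
  i <- rep(seq_len(nrow(c1)), times = nrow(c2))
  j <- rep(seq_len(nrow(c2)), each = nrow(c1))
  pairs <- cbind(stats::setNames(c1[i, ], paste0(names(c1), "_1")),
                 stats::setNames(c2[j, ], paste0(names(c2), "_2")))
  out <- rbind(cbind(alpha = 1L, pairs), cbind(alpha = 2L, pairs))
  rownames(out) <- NULL
  out
}

#' Prior probability of scene hypotheses
#'
#' Product of the independent priors over illuminant count, curvature sign,
#' specular index and local-illuminant flag, times the occlusion factors
#' `p_os` / `1 - p_os` and `p_om` / `1 - p_om` where the corresponding
#' indicators are defined. Summed over the full unconstrained hypothesis
#' universe these priors total 1.
#'
#' @param h data frame of hypotheses as returned by [enumerate_hypotheses()]
#'   (vectorized over rows).
#' @param params a [model_params()].
#' @return numeric vector of prior probabilities.
#' @export
hypothesis_prior <- function(h, params) {
  stopifnot(inherits(params, "model_params"))
  pr <- ifelse(h$alpha == 1L, params$p_single, 1 - params$p_single)
  for (k in 1:2) {
    tau <- h[[paste0("tau_", k)]]
    chi <- h[[paste0("chi_", k)]]
    beta <- h[[paste0("beta_", k)]]
    occ_s <- h[[paste0("occ_s_", k)]]
    occ_m <- h[[paste0("occ_m_", k)]]
    pr <- pr *
      ifelse(tau == "convex", params$p_convex, 1 - params$p_convex) *
      ifelse(chi == "shiny", params$p_shiny, 1 - params$p_shiny) *
      ifelse(beta == "present", params$p_local, 1 - params$p_local) *
      ifelse(is.na(occ_s), 1, ifelse(occ_s == 1L, params$p_os, 1 - params$p_os)) *
      ifelse(is.na(occ_m), 1, ifelse(occ_m == 1L, params$p_om, 1 - params$p_om))
  }
  pr
}

## log of the integral over the shared tilt phi of a von Mises prior times a
## product of von Mises observation kernels, each kernel centred on phi (its
## observed value entering through the phase). Closed form via the resultant
## of the summed cosine terms:
##   integral = I0(R) / ((2*pi)^m * I0(prior_kappa) * prod I0(kappa_j)),
## m = number of observation kernels. Works elementwise on vectors of phases.
log_phi_marginal <- function(obs_kappa, obs_phase, prior_kappa, prior_mu) {
  z <- prior_kappa * exp(1i * prior_mu)
  if (length(obs_kappa))
    z <- z + colSums(matrix(obs_kappa * exp(1i * obs_phase),
                            nrow = length(obs_kappa)))
  log_bessel_i0(Mod(z)) - log_bessel_i0(prior_kappa) -
    sum(log_bessel_i0(obs_kappa)) - length(obs_kappa) * log(2 * pi)
}

#' Closed-form marginal over illuminant tilt
#'
#' Integrates, over the circle, a von Mises prior on the illuminant tilt
#' multiplied by von Mises observation kernels centred on that tilt (one per
#' observed gradient or highlight). The product of exponentials collapses to a
#' single cosine term whose amplitude is the resultant length `R` of the
#' summed `(kappa, phase)` terms, giving
#' `I0(R) / ((2*pi)^m * I0(prior_kappa) * prod(I0(kappa_j)))` with `m` the
#' number of observation kernels. Computed via log-Bessel throughout, so large
#' concentrations do not overflow.
#'
#' @param kappas concentrations of the observation kernels (>= 0); may be
#'   empty.
#' @param phases observed phases of the kernels (radians), same length.
#' @param prior_kappa,prior_mu concentration and mean of the tilt prior.
#' @param log if `TRUE`, return the log marginal.
#' @return the marginal likelihood contribution (a density over the observed
#'   angles).
#' @export
phi_marginal <- function(kappas, phases, prior_kappa = 0, prior_mu = 0,
                         log = FALSE) {
  stopifnot(length(kappas) == length(phases), all(kappas >= 0),
            prior_kappa >= 0)
  lm <- log_phi_marginal(kappas, phases, prior_kappa, prior_mu)
  if (log) lm else exp(lm)
}

## Kernel bundle for one object under one hypothesis row: von Mises phases
## (relative to the object's illuminant tilt) plus the count of uniform
## (local-illuminant) highlight factors.
object_kernels <- function(theta, gamma, tau, cause, params, ignore_gamma) {
  off <- if (tau == "convex") 0 else pi
  kap <- params$kappa_n
  phase <- theta - off
  n_local <- 0L
  if (!is.na(cause)) {
    if (cause == "spec" && !ignore_gamma) {
      kap <- c(kap, params$kappa_n)
      phase <- c(phase, gamma - off)
    } else if (cause == "local") {
      n_local <- 1L
    }
  }
  list(kappa = kap, phase = phase, n_local = n_local)
}

#' Likelihood of a trial observation under one scene hypothesis
#'
#' Under a single global illuminant (`alpha = 1`) the two objects' gradient
#' kernels — and any specular-highlight kernels — share one illuminant tilt,
#' marginalized in closed form against the light prior. Under two windowed
#' illuminants each object gets an independent tilt with the same prior, so
#' the marginal factorizes. Gradient kernels are centred on the illuminant
#' tilt for convex objects and on tilt + pi for concave; a visible specular
#' highlight contributes a kernel at the gradient-consistent position with the
#' same concentration `kappa_n`; a highlight caused by a local illuminant
#' contributes the uniform density `1/(2*pi)`.
#'
#' @param obs a [trial_observation()].
#' @param h a one-row hypothesis data frame (a row of
#'   [enumerate_hypotheses()]).
#' @param params a [model_params()].
#' @param ignore_gamma drop highlight-tilt kernels entirely (used by the
#'   reduced model that attributes every highlight to specular reflection and
#'   ignores its position).
#' @param log if `TRUE`, return the log likelihood.
#' @return likelihood density of the observed tilts given the hypothesis.
#' @export
trial_likelihood <- function(obs, h, params, ignore_gamma = FALSE,
                             log = FALSE) {
  stopifnot(inherits(obs, "trial_observation"), nrow(h) == 1)
  k1 <- object_kernels(obs$theta_target, obs$gamma_target,
                       h$tau_1, h$cause_1, params, ignore_gamma)
  k2 <- object_kernels(obs$theta_distractor, obs$gamma_distractor,
                       h$tau_2, h$cause_2, params, ignore_gamma)
  ll_local <- -(k1$n_local + k2$n_local) * log(2 * pi)
  if (h$alpha == 1L) {
    ll <- log_phi_marginal(c(k1$kappa, k2$kappa), c(k1$phase, k2$phase),
                           params$kappa_phi, params$mu) + ll_local
  } else {
    ll <- log_phi_marginal(k1$kappa, k1$phase, params$kappa_phi, params$mu) +
      log_phi_marginal(k2$kappa, k2$phase, params$kappa_phi, params$mu) +
      ll_local
  }
  if (log) ll else exp(ll)
}

log_sum_exp <- function(x) {
  x <- x[x > -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

posterior_mass <- function(obs, params, ignore_gamma = FALSE) {
  h <- enumerate_hypotheses(obs)
  lp <- log(hypothesis_prior(h, params))
  keep <- lp > -Inf
  ll <- rep(-Inf, nrow(h))
  for (i in which(keep))
    ll[i] <- trial_likelihood(obs, h[i, ], params, ignore_gamma, log = TRUE)
  list(h = h, lw = lp + ll)
}

#' Posterior probability that the target object is convex
#'
#' Sums prior-times-likelihood over all scene hypotheses in which the target
#' is convex, normalized by the total over all hypotheses consistent with the
#' observed highlight pattern.
#'
#' @inheritParams trial_likelihood
#' @return probability in `[0, 1]`.
#' @export
posterior_convex <- function(obs, params, ignore_gamma = FALSE) {
  pm <- posterior_mass(obs, params, ignore_gamma)
  den <- log_sum_exp(pm$lw)
  if (den == -Inf) stop("degenerate posterior: all hypotheses have zero mass")
  exp(log_sum_exp(pm$lw[pm$h$tau_1 == "convex"]) - den)
}

#' Posterior probability that the target surface is specular
#'
#' Defined for trials where the target carries a highlight: the posterior mass
#' of hypotheses with a shiny target, against the alternative that the
#' highlight is a local-illumination effect on a matte surface. Decreasing in
#' the angular offset between the highlight and the gradient-consistent
#' position.
#'
#' @inheritParams trial_likelihood
#' @return probability in `[0, 1]`.
#' @export
posterior_shiny <- function(obs, params, ignore_gamma = FALSE) {
  stopifnot(inherits(obs, "trial_observation"))
  if (obs$delta_target != 1L)
    stop("posterior_shiny requires a highlight on the target (delta_target = 1)")
  pm <- posterior_mass(obs, params, ignore_gamma)
  den <- log_sum_exp(pm$lw)
  if (den == -Inf) stop("degenerate posterior: all hypotheses have zero mass")
  exp(log_sum_exp(pm$lw[pm$h$chi_1 == "shiny"]) - den)
}

#' Probability of a "convex" report
#'
#' The decision rule is probability matching: the observer reports "convex"
#' with probability equal to the posterior, optionally mixed with an
#' unbiased lapse.
#'
#' @inheritParams trial_likelihood
#' @return probability of a convex report.
#' @export
response_probability <- function(obs, params, ignore_gamma = FALSE) {
  p <- posterior_convex(obs, params, ignore_gamma)
  (1 - params$lapse) * p + params$lapse * 0.5
}
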