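## Vectorized evaluation of the convex-report probability over a trial table.
## Semantics are identical to response_probability() applied row by row (a
## property the test suite asserts). The trial-dependent structure — the
## admissible hypothesis pairs per highlight pattern and the complex kernel
## sums entering each tilt resultant — does not depend on the parameters, so
## it is prebuilt once per table (likelihood_context) and each evaluation
## reduces to a few vectorized Bessel calls. This is what makes
## maximum-likelihood fitting on tens of thousands of trials practical.

trials_radians <- function(trials) {
  list(th1 = deg2rad(trials$theta_target_deg),
       th2 = deg2rad(trials$theta_distractor_deg),
       d1 = as.integer(trials$delta_target),
       d2 = as.integer(trials$delta_distractor),
       g1 = deg2rad(trials$gamma_target_deg),
       g2 = deg2rad(trials$gamma_distractor_deg))
}

## integer-coded hidden-variable factors for one object's admissible cases,
## plus deduplicated kernel sums (cases sharing curvature sign and highlight
## kernel have identical tilt resultants)
object_ctx <- function(cases, theta, gamma, ignore_gamma) {
  has_g <- !is.na(cases$cause) & cases$cause == "spec" & !ignore_gamma
  off <- ifelse(cases$tau == "convex", 0, pi)
  sig <- paste(off, has_g)
  keep <- !duplicated(sig)
  map <- match(sig, sig[keep])
  S <- vapply(which(keep), function(i) {
    s <- exp(1i * (theta - off[i]))
    if (has_g[i]) s <- s + exp(1i * (gamma - off[i]))
    s
  }, complex(length(theta)))
  S <- matrix(S, nrow = length(theta))
  list(
    S = S,
    n_vm = (1L + has_g)[keep],
    map = map,
    # prior component indices: value 1 never contributes (log factor 0)
    tau = ifelse(cases$tau == "convex", 2L, 3L),
    chi = ifelse(cases$chi == "shiny", 2L, 3L),
    beta = ifelse(cases$beta == "present", 2L, 3L),
    occ_s = ifelse(is.na(cases$occ_s), 1L, ifelse(cases$occ_s == 1L, 2L, 3L)),
    occ_m = ifelse(is.na(cases$occ_m), 1L, ifelse(cases$occ_m == 1L, 2L, 3L)),
    n_local = as.integer(!is.na(cases$cause) & cases$cause == "local"),
    convex = cases$tau == "convex"
  )
}

build_group_ctx <- function(th1, th2, g1, g2, d1, d2, ignore_gamma) {
  o1 <- object_ctx(object_cases(d1), th1, g1, ignore_gamma)
  o2 <- object_ctx(object_cases(d2), th2, g2, ignore_gamma)
  n1 <- length(o1$tau)
  n2 <- length(o2$tau)
  i_of <- rep(seq_len(n1), each = n2)
  j_of <- rep(seq_len(n2), times = n1)
  a_of <- o1$map[i_of]
  b_of <- o2$map[j_of]
  d1u <- ncol(o1$S)
  d2u <- ncol(o2$S)
  # distinct kernel sums for the shared-illuminant branch
  Sp <- o1$S[, rep(seq_len(d1u), each = d2u), drop = FALSE] +
    o2$S[, rep(seq_len(d2u), times = d1u), drop = FALSE]
  list(o1 = o1, o2 = o2, i_of = i_of, j_of = j_of, a_of = a_of, b_of = b_of,
       Sp = Sp, pcol = (a_of - 1L) * d2u + b_of,
       n_vm_pair = o1$n_vm[a_of] + o2$n_vm[b_of],
       n_loc_pair = o1$n_local[i_of] + o2$n_local[j_of],
       conv_pair = o1$convex[i_of],
       n = length(th1))
}

## the prior log-factors of each case, via integer indexing (index 1 = "not
## applicable", log factor 0)
case_log_priors <- function(o, params, p_os, p_om) {
  ltau <- c(0, log(params$p_convex), log1p(-params$p_convex))
  lchi <- c(0, log(params$p_shiny), log1p(-params$p_shiny))
  lbeta <- c(0, log(params$p_local), log1p(-params$p_local))
  loccs <- c(0, log(p_os), log1p(-p_os))
  loccm <- c(0, log(p_om), log1p(-p_om))
  ltau[o$tau] + lchi[o$chi] + lbeta[o$beta] + loccs[o$occ_s] + loccm[o$occ_m]
}

group_posterior <- function(g, params, p_os, p_om) {
  kn <- params$kappa_n
  zp <- params$kappa_phi * exp(1i * params$mu)
  li0_kphi <- log_bessel_i0(params$kappa_phi)
  li0_kn <- log_bessel_i0(kn)
  l2pi <- log(2 * pi)
  lp1 <- case_log_priors(g$o1, params, p_os, p_om)
  lp2 <- case_log_priors(g$o2, params, p_os, p_om)
  lc <- lp1[g$i_of] + lp2[g$j_of] - g$n_vm_pair * li0_kn -
    (g$n_vm_pair + g$n_loc_pair) * l2pi
  # shared illuminant: joint resultant; windowed: per-object marginals
  P <- log_bessel_i0(Mod(zp + kn * g$Sp))
  B1 <- log_bessel_i0(Mod(zp + kn * g$o1$S))
  B2 <- log_bessel_i0(Mod(zp + kn * g$o2$S))
  W <- cbind(P[, g$pcol, drop = FALSE],
             B1[, g$a_of, drop = FALSE] + B2[, g$b_of, drop = FALSE])
  shift <- c(lc + log(params$p_single) - li0_kphi,
             lc + log1p(-params$p_single) - 2 * li0_kphi)
  W <- W + rep(shift, each = g$n)
  m <- W[cbind(seq_len(g$n), max.col(W, ties.method = "first"))]
  E <- exp(W - m)
  tot <- rowSums(E)
  num <- rowSums(E[, rep(g$conv_pair, 2L), drop = FALSE])
  if (any(!is.finite(tot) | tot <= 0))
    stop("degenerate posterior: all hypotheses have zero mass")
  num / tot
}

likelihood_context <- function(trials, ignore_highlights = FALSE,
                               ignore_gamma = FALSE,
                               p_os = NULL, p_om = NULL) {
  tr <- trials_radians(trials)
  n <- length(tr$th1)
  os_key <- if (is.null(p_os)) rep("", n) else p_os
  om_key <- if (is.null(p_om)) rep("", n) else p_om
  if (!is.null(p_os)) stopifnot(length(p_os) == n)
  if (!is.null(p_om)) stopifnot(length(p_om) == n)
  if (ignore_highlights) {
    tr$d1[] <- 0L
    tr$d2[] <- 0L
    tr$g1[] <- NA_real_
    tr$g2[] <- NA_real_
  }
  if (any(tr$d1 == 1L & !is.finite(tr$g1)) ||
        any(tr$d2 == 1L & !is.finite(tr$g2)))
    stop("highlight tilt missing on a trial with a highlight present")
  key <- paste(tr$d1, tr$d2, os_key, om_key)
  groups <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    i1 <- idx[1]
    list(idx = idx,
         p_os = if (is.null(p_os)) NA_real_ else p_os[i1],
         p_om = if (is.null(p_om)) NA_real_ else p_om[i1],
         ctx = build_group_ctx(tr$th1[idx], tr$th2[idx], tr$g1[idx],
                               tr$g2[idx], tr$d1[i1], tr$d2[i1],
                               ignore_gamma))
  })
  list(groups = groups, n = n)
}

context_posteriors <- function(ctx, params) {
  post <- numeric(ctx$n)
  for (g in ctx$groups) {
    post[g$idx] <- group_posterior(
      g$ctx, params,
      p_os = if (is.na(g$p_os)) params$p_os else g$p_os,
      p_om = if (is.na(g$p_om)) params$p_om else g$p_om)
  }
  post
}

#' Convex-report probabilities for a trial table
#'
#' Vectorized equivalent of [response_probability()] for every row of a trial
#' table in the package's CSV schema (angles in degrees at this boundary).
#' Used by the likelihood machinery and the response simulator.
#'
#' @param trials data frame in the trial-table schema (see [read_trials()]).
#' @param params a [model_params()].
#' @param ignore_highlights strip the highlight observables before evaluation
#'   (the reduced models without highlight parameters score every trial as if
#'   both objects were matte).
#' @param ignore_gamma drop highlight-tilt kernels (see [trial_likelihood()]).
#' @param p_os,p_om optional per-trial overrides of the occlusion
#'   probabilities (vectors of length `nrow(trials)`), used to couple the
#'   dome-stimulus simulation to the occlusion geometry.
#' @return vector of convex-report probabilities.
#' @export
response_probabilities <- function(trials, params, ignore_highlights = FALSE,
                                   ignore_gamma = FALSE,
                                   p_os = NULL, p_om = NULL) {
  stopifnot(inherits(params, "model_params"))
  ctx <- likelihood_context(trials, ignore_highlights, ignore_gamma,
                            p_os, p_om)
  post <- context_posteriors(ctx, params)
  (1 - params$lapse) * post + params$lapse * 0.5
}
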