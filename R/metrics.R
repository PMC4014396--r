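#' Mutual information of a 2x2 contingency table
#'
#' Plug-in estimator, in bits, of the mutual information between highlight
#' presence and reported curvature sign:
#' `sum p(h,s) * log2(p(h,s) / (p(h) p(s)))`, with `0*log(0) = 0`. Bounded by
#' 1 bit for two binary variables.
#'
#' @param table a 2x2 matrix of non-negative counts, rows = highlight
#'   present/absent, columns = response convex/concave.
#' @return mutual information in bits.
#' @examples
#' mutual_information(matrix(c(30, 10, 10, 30), 2)) # about 0.189 bits
#' @export
mutual_information <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  total <- sum(table)
  if (total == 0) stop("empty contingency table")
  p <- table / total
  pr <- rowSums(p)
  pc <- colSums(p)
  terms <- p * log2(p / outer(pr, pc))
  sum(terms[p > 0])
}

#' Mutual information between highlight presence and reported shape, per
#' orientation bin
#'
#' For each target shading orientation, builds a 2x2 table from two paired
#' conditions — highlight present on the target versus absent — and computes
#' the plug-in MI. The pairing follows the two analyses of the study designs:
#' `"sm-mm"` contrasts target-highlight trials with no-highlight trials;
#' `"sm-ms"` contrasts target-highlight with distractor-highlight trials.
#'
#' @param trials trial table including `response_convex`.
#' @param pairing `"sm-mm"` or `"sm-ms"`.
#' @return data frame of class `mi_curve`: `orientation_deg`, `mi` (bits;
#'   `NA` where a bin lacks one of the paired conditions), and the four cell
#'   counts.
#' @export
mi_curve <- function(trials, pairing = c("sm-mm", "sm-ms")) {
  pairing <- match.arg(pairing)
  absent_cond <- if (pairing == "sm-mm") "MM" else "MS"
  keep <- trials$condition %in% c("SM", absent_cond)
  tr <- trials[keep & !is.na(trials$response_convex), ]
  bins <- sort(unique(tr$theta_target_deg))
  out <- data.frame(orientation_deg = bins, mi = NA_real_,
                    n_hl_convex = NA_integer_, n_hl_concave = NA_integer_,
                    n_nohl_convex = NA_integer_, n_nohl_concave = NA_integer_)
  for (i in seq_along(bins)) {
    b <- tr[tr$theta_target_deg == bins[i], ]
    hl <- b$condition == "SM"
    counts <- matrix(c(sum(hl & b$response_convex == 1),
                       sum(!hl & b$response_convex == 1),
                       sum(hl & b$response_convex == 0),
                       sum(!hl & b$response_convex == 0)), 2)
    out[i, 3:6] <- c(counts[1, ], counts[2, ])
    if (all(rowSums(counts) > 0)) out$mi[i] <- mutual_information(counts)
  }
  class(out) <- c("mi_curve", "data.frame")
  out
}

#' Weighted average of per-observer MI curves
#'
#' Convex combination of observers' MI curves per orientation bin. In the
#' study's group analyses each observer is weighted by their overall
#' MI(highlight, shape), so observers whose perception is unmodulated by
#' highlights do not dilute the curve.
#'
#' @param curves list of [mi_curve()] results (or data frames with
#'   `orientation_deg` and `mi`) on a common orientation grid.
#' @param weights non-negative observer weights, not all zero; equal weights
#'   give the plain mean.
#' @return data frame `orientation_deg`, `mi`.
#' @export
weighted_observer_average <- function(curves, weights) {
  stopifnot(length(curves) == length(weights), all(weights >= 0))
  if (sum(weights) == 0) stop("weights must not all be zero")
  grid <- curves[[1]]$orientation_deg
  for (cv in curves)
    if (!identical(cv$orientation_deg, grid))
      stop("curves must share one orientation grid")
  mi <- sapply(curves, `[[`, "mi")
  data.frame(orientation_deg = grid,
             mi = as.vector(mi %*% weights) / sum(weights))
}

#' Maximum-likelihood cumulative-Gaussian psychometric fit
#'
#' Fits `P(convex) = Phi((x - threshold) / scale)` to Bernoulli data by
#' maximum likelihood (probit GLM; no lapse or guess parameters). The 50%
#' threshold is the location parameter.
#'
#' @param x stimulus levels (one per trial, or one per aggregated cell).
#' @param response binary responses, or number of convex responses per cell
#'   when `n` is given.
#' @param n optional trial counts per cell (aggregated input).
#' @return object of class `psychometric_fit`: `threshold_50`, `slope`
#'   (probit slope per unit of `x`), `log_likelihood`, `reliable` flag
#'   (`FALSE` for non-increasing or degenerate fits or a threshold outside
#'   the sampled range).
#' @export
fit_psychometric <- function(x, response, n = NULL) {
  if (is.null(n)) {
    n <- rep(1L, length(response))
  }
  stopifnot(length(x) == length(response), length(n) == length(response),
            all(response >= 0), all(response <= n))
  if (length(unique(x)) < 4)
    stop("need at least 4 stimulus levels spanning the transition")
  fit <- suppressWarnings(
    stats::glm(cbind(response, n - response) ~ x,
               family = stats::binomial(link = "probit")))
  a <- stats::coef(fit)[1]
  b <- stats::coef(fit)[2]
  threshold <- as.numeric(-a / b)
  reliable <- is.finite(threshold) && b > 0 && fit$converged &&
    threshold >= min(x) && threshold <= max(x)
  structure(list(threshold_50 = threshold,
                 slope = as.numeric(b),
                 scale = as.numeric(1 / b),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 reliable = reliable),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("cumulative-Gaussian fit: 50%% threshold = %.2f, scale = %.2f%s\n",
              x$threshold_50, x$scale,
              if (x$reliable) "" else " (flagged unreliable)"))
  invisible(x)
}

#' Per-cell psychometric baselines for the dome-stimulus experiment
#'
#' For each (observer, depth, slant) cell, fits a psychometric function to the
#' matte (no-highlight) trials and returns the shading tilt at which convex
#' and concave reports balance. Because the proportion of convex reports over
#' tilts 90-270 degrees is symmetric about 180 under the generative model,
#' the fit is performed on the folded axis `|tilt - 180|` (the angular
#' distance from the lights-from-below direction), where the proportion is
#' monotone; the folded threshold maps back to a pair of tilts `180 +/- u`.
#'
#' @param trials dome-experiment trial table with responses.
#' @return data frame: `observer_id`, `depth_ratio`, `slant_deg`,
#'   `threshold_fold` (folded 50% point, clamped to the sampled range),
#'   `baseline_tilt_deg` (nearest sampled folded tilt), `reliable`.
#' @export
exp3_baselines <- function(trials) {
  matte <- trials[trials$condition == "MM" & !is.na(trials$response_convex), ]
  if (!nrow(matte)) stop("no matte (MM) trials to fit baselines on")
  matte$fold <- abs(matte$theta_target_deg - 180)
  cells <- unique(matte[, c("observer_id", "depth_ratio", "slant_deg")])
  rownames(cells) <- NULL
  res <- cells
  res$threshold_fold <- NA_real_
  res$baseline_tilt_deg <- NA_real_
  res$reliable <- FALSE
  folds <- sort(unique(matte$fold))
  for (i in seq_len(nrow(cells))) {
    sub <- matte[matte$observer_id == cells$observer_id[i] &
                   matte$depth_ratio == cells$depth_ratio[i] &
                   matte$slant_deg == cells$slant_deg[i], ]
    agg <- stats::aggregate(response_convex ~ fold, sub,
                            function(r) c(k = sum(r), n = length(r)))
    k <- agg$response_convex[, "k"]
    n <- agg$response_convex[, "n"]
    ft <- try(fit_psychometric(agg$fold, k, n), silent = TRUE)
    if (inherits(ft, "try-error")) next
    th <- min(max(ft$threshold_50, min(folds)), max(folds))
    res$threshold_fold[i] <- th
    res$baseline_tilt_deg[i] <- folds[which.min(abs(folds - th))]
    res$reliable[i] <- ft$reliable
  }
  res
}

#' Highlight effect relative to the per-cell 50% baseline
#'
#' The dome-stimulus analysis: within each (observer, depth, slant) cell the
#' matte trials define the shading tilt at which reports are balanced
#' (50% convex); the highlight effect is the proportion of convex reports on
#' highlight trials at the sampled tilt(s) closest to that baseline — 0.5
#' means the highlight has no effect.
#'
#' @param trials dome-experiment trial table with responses.
#' @param baselines optional result of [exp3_baselines()]; computed from the
#'   matte trials when missing.
#' @return list with `cells` (effect per observer x depth x slant),
#'   `by_slant` and `by_depth` (effect averaged over the other factor).
#' @export
highlight_effect <- function(trials, baselines = NULL) {
  if (is.null(baselines)) baselines <- exp3_baselines(trials)
  hl <- trials[trials$condition == "SM" & !is.na(trials$response_convex), ]
  hl$fold <- abs(hl$theta_target_deg - 180)
  eff <- baselines
  eff$effect <- NA_real_
  for (i in seq_len(nrow(eff))) {
    if (is.na(eff$baseline_tilt_deg[i])) next
    sub <- hl[hl$observer_id == eff$observer_id[i] &
                hl$depth_ratio == eff$depth_ratio[i] &
                hl$slant_deg == eff$slant_deg[i] &
                hl$fold == eff$baseline_tilt_deg[i], ]
    if (nrow(sub)) eff$effect[i] <- mean(sub$response_convex)
  }
  by_slant <- stats::aggregate(effect ~ slant_deg, eff, mean, na.rm = TRUE)
  by_depth <- stats::aggregate(effect ~ depth_ratio, eff, mean, na.rm = TRUE)
  list(cells = eff, by_slant = by_slant, by_depth = by_depth)
}
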