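PARAM_NAMES <- c("mu", "kappa_phi", "p_convex", "p_single", "p_shiny",
                 "p_os", "kappa_n", "p_local", "p_om")
PROB_PARAMS <- c("p_convex", "p_single", "p_shiny", "p_os", "p_local", "p_om")

#' Observer-model parameters
#'
#' The nine free parameters of the full generative model of convex/concave
#' report, plus an optional lapse rate:
#'
#' * `mu`: mean of the von Mises prior over illuminant tilt (radians; 0 =
#'   light from directly above).
#' * `kappa_phi`: concentration of the light prior (>= 0).
#' * `p_convex`: prior probability that an object is convex.
#' * `p_single`: prior probability of a single global illuminant,
#'   `p(alpha = 1)`; two windowed illuminants have probability `1 - p_single`.
#' * `p_shiny`: prior probability that an object's surface is specular.
#' * `p_os`: probability that, for a concave object, the rim occludes the ray
#'   that would generate a specular highlight.
#' * `kappa_n`: concentration of the von Mises observation noise on gradient
#'   tilt, shared with the highlight-misalignment kernel (>= 0).
#' * `p_local`: prior probability of a local illuminant (a spotlight-like
#'   secondary source that can explain a highlight on a matte surface).
#' * `p_om`: probability that a concave object's local illuminant is occluded.
#' * `lapse`: probability of a stimulus-independent random (0.5/0.5) report.
#'
#' @param mu,kappa_phi,p_convex,p_single,p_shiny,p_os,kappa_n,p_local,p_om
#'   see Details.
#' @param lapse lapse rate in `[0, 1]`, default 0.
#' @return an object of class `model_params` (a named list).
#' @export
model_params <- function(mu = 0, kappa_phi = 7.5, p_convex = 0.75,
                         p_single = 0.8, p_shiny = 0.61, p_os = 0.38,
                         kappa_n = 5, p_local = 0.78, p_om = 0.2,
                         lapse = 0) {
  p <- list(mu = wrap_angle(mu, -pi), kappa_phi = kappa_phi,
            p_convex = p_convex, p_single = p_single, p_shiny = p_shiny,
            p_os = p_os, kappa_n = kappa_n, p_local = p_local, p_om = p_om,
            lapse = lapse)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  for (nm in c(PROB_PARAMS, "lapse")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
      stop(sprintf("parameter '%s' must be a single probability in [0, 1]", nm))
  }
  for (nm in c("kappa_phi", "kappa_n")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop(sprintf("parameter '%s' must be a single non-negative number", nm))
  }
  if (!is.numeric(p$mu) || length(p$mu) != 1 || !is.finite(p$mu))
    stop("parameter 'mu' must be a single finite angle (radians)")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("observer-model parameters:\n")
  cat(sprintf("  light prior: mu = %.1f deg, kappa_phi = %.2f (FWHH %.1f deg)\n",
              rad2deg(x$mu), x$kappa_phi, vm_fwhm(x$kappa_phi)))
  cat(sprintf("  priors: p_convex = %.2f, p_single = %.2f, p_shiny = %.2f, p_local = %.2f\n",
              x$p_convex, x$p_single, x$p_shiny, x$p_local))
  cat(sprintf("  occlusion: p_os = %.2f, p_om = %.2f; noise kappa_n = %.2f",
              x$p_os, x$p_om, x$kappa_n))
  if (x$lapse > 0) cat(sprintf("; lapse = %.2f", x$lapse))
  cat("\n")
  invisible(x)
}

#' Reference per-observer parameter estimates
#'
#' Maximum-likelihood estimates of the nine model parameters for the ten
#' observers of the convex/concave judgement experiments that motivated this
#' model, together with their across-observer mean and SD. `mu` is in
#' radians. These values serve as realistic generating parameters for
#' synthetic observers and as inputs to summary computations (e.g. the mean
#' width of the fitted light prior).
#'
#' @param observer `NULL` for the full table (one row per observer plus
#'   `"mean"` and `"sd"` rows), or a single observer id / `"mean"` to get a
#'   [model_params()] object.
#' @return a data frame, or a `model_params` when `observer` is given.
#' @examples
#' mean(vm_fwhm(reference_observer_params()$kappa_phi[1:10])) # about 68.9 deg
#' @export
reference_observer_params <- function(observer = NULL) {
  tab <- data.frame(
    observer = c("1", "2", "4", "5", "6", "7", "8", "9", "10", "11",
                 "mean", "sd"),
    mu = c(-0.35, -0.29, -0.36, 0.02, 0.16, 0.02, 0.14, 0.20, -0.07, -0.01,
           -0.05, 0.21),
    kappa_phi = c(2.5, 3.5, 1.6, 20.0, 9.7, 9.6, 4.2, 1.6, 20.0, 2.3,
                  7.5, 7.2),
    p_convex = c(1.00, 0.82, 0.78, 0.98, 0.50, 0.46, 0.56, 0.98, 1.00, 0.44,
                 0.75, 0.24),
    p_single = c(1.00, 1.00, 0.94, 0.70, 1.00, 1.00, 1.00, 0.39, 0.96, 0.00,
                 0.80, 0.34),
    p_shiny = c(0.41, 0.95, 1.00, 0.89, 0.00, 0.52, 0.29, 1.00, 0.99, 0.00,
                0.61, 0.41),
    p_os = c(0.06, 0.40, 0.00, 0.51, 0.26, 1.00, 0.53, 0.01, 0.06, 1.00,
             0.38, 0.38),
    kappa_n = c(14.8, 2.6, 2.0, 4.6, 2.6, 3.5, 1.4, 3.9, 2.0, 12.3,
                5.0, 4.7),
    p_local = c(0.88, 0.88, 1.00, 0.95, 0.90, 0.75, 0.44, 0.95, 1.00, 0.00,
                0.78, 0.32),
    p_om = c(0.39, 0.00, 0.00, 0.09, 0.24, 0.07, 0.13, 0.10, 0.17, 0.80,
             0.20, 0.24),
    stringsAsFactors = FALSE
  )
  if (is.null(observer)) return(tab)
  row <- tab[tab$observer == as.character(observer), , drop = FALSE]
  if (nrow(row) != 1) stop("unknown observer id: ", observer)
  do.call(model_params, as.list(row[, PARAM_NAMES]))
}

#' Read / write model parameters as JSON
#'
#' The file format stores the nine named parameters with `mu` in degrees (the
#' package's file-boundary convention), plus an optional `lapse`.
#'
#' @param path file path.
#' @param params a [model_params()] object.
#' @return `read_model_params` returns a [model_params()];
#'   `write_model_params` returns `path` invisibly.
#' @export
read_model_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  missing <- setdiff(PARAM_NAMES, names(raw))
  if (length(missing))
    stop("parameter file missing fields: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(raw), c(PARAM_NAMES, "lapse"))
  if (length(extra))
    stop("parameter file has unknown fields: ", paste(extra, collapse = ", "))
  raw$mu <- deg2rad(raw$mu)
  do.call(model_params, raw)
}

#' @rdname read_model_params
#' @export
write_model_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  out <- unclass(params)
  out$mu <- rad2deg(out$mu)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
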