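new_design <- function(df, experiment, factors) {
  df$trial_index <- seq_len(nrow(df))
  cols <- c("observer_id", "experiment", "trial_index", "condition",
            "theta_target_deg", "theta_distractor_deg",
            "delta_target", "delta_distractor",
            "gamma_target_deg", "gamma_distractor_deg",
            "depth_ratio", "slant_deg", "response_convex")
  for (cc in setdiff(cols, names(df))) df[[cc]] <- NA
  df <- df[, cols]
  attr(df, "factors") <- factors
  df
}

#' Trial designs of the three experiments
#'
#' Deterministic full-factorial trial templates (responses unfilled), one row
#' per trial, in the package's trial-table schema with angles in degrees.
#'
#' * Experiment 1: 24 target shading orientations (0 to 345 in 15-degree
#'   steps) x 4 highlight conditions (MM, MS, SM, SS: target/distractor
#'   matte or shiny) x 16 repetitions = 1536 trials. Highlights sit at the
#'   gradient-consistent position (`gamma = theta`).
#' * Experiment 2: 16 shading orientations (22.5-degree steps) x 10 highlight
#'   positions (36-degree steps, independent of the shading) x 2 conditions
#'   (SM, MS) x 12 repetitions = 3840 trials.
#' * Experiment 3: dome stimuli; 4 depth ratios (0.25, 0.5, 0.75, 1) x 6
#'   illuminant slants (25 to 75 degrees) x 7 illuminant tilts (90 to 270
#'   degrees) x 2 specularity conditions (MM, SM; highlight yoked to the
#'   shading gradient) x 6 repetitions = 2016 trials. The
#'   `highlight_eccentricity` attribute is unused by the standard model but
#'   the per-trial dome descriptors are carried in `depth_ratio` and
#'   `slant_deg`.
#'
#' The distractor gradient always opposes the target gradient
#' (`theta_distractor = theta_target + 180`).
#'
#' @return data frame of trial templates with a `factors` attribute recording
#'   the factor grids.
#' @export
design_exp1 <- function() {
  orientations <- seq(0, 345, by = 15)
  conditions <- c("MM", "MS", "SM", "SS")
  g <- expand.grid(rep = 1:16, theta = orientations, condition = conditions,
                   stringsAsFactors = FALSE)
  target_shiny <- g$condition %in% c("SM", "SS")
  distractor_shiny <- g$condition %in% c("MS", "SS")
  df <- data.frame(
    experiment = 1L, condition = g$condition,
    theta_target_deg = g$theta,
    theta_distractor_deg = (g$theta + 180) %% 360,
    delta_target = as.integer(target_shiny),
    delta_distractor = as.integer(distractor_shiny),
    gamma_target_deg = ifelse(target_shiny, g$theta, NA_real_),
    gamma_distractor_deg = ifelse(distractor_shiny, (g$theta + 180) %% 360,
                                  NA_real_),
    stringsAsFactors = FALSE)
  new_design(df, 1L, list(orientations = orientations,
                          conditions = conditions, repetitions = 16L))
}

#' @rdname design_exp1
#' @export
design_exp2 <- function() {
  orientations <- seq(0, 360 - 22.5, by = 22.5)
  highlight_positions <- seq(0, 324, by = 36)
  conditions <- c("SM", "MS")
  g <- expand.grid(rep = 1:12, theta = orientations,
                   gamma = highlight_positions, condition = conditions,
                   stringsAsFactors = FALSE)
  on_target <- g$condition == "SM"
  df <- data.frame(
    experiment = 2L, condition = g$condition,
    theta_target_deg = g$theta,
    theta_distractor_deg = (g$theta + 180) %% 360,
    delta_target = as.integer(on_target),
    delta_distractor = as.integer(!on_target),
    gamma_target_deg = ifelse(on_target, g$gamma, NA_real_),
    gamma_distractor_deg = ifelse(!on_target, g$gamma, NA_real_),
    stringsAsFactors = FALSE)
  new_design(df, 2L, list(orientations = orientations,
                          highlight_positions = highlight_positions,
                          conditions = conditions, repetitions = 12L))
}

#' @rdname design_exp1
#' @export
design_exp3 <- function() {
  depths <- c(0.25, 0.5, 0.75, 1)
  slants <- seq(25, 75, by = 10)
  tilts <- seq(90, 270, by = 30)
  conditions <- c("MM", "SM")
  g <- expand.grid(rep = 1:6, theta = tilts, slant = slants, depth = depths,
                   condition = conditions, stringsAsFactors = FALSE)
  on_target <- g$condition == "SM"
  df <- data.frame(
    experiment = 3L, condition = g$condition,
    theta_target_deg = g$theta,
    theta_distractor_deg = (g$theta + 180) %% 360,
    delta_target = as.integer(on_target),
    delta_distractor = 0L,
    gamma_target_deg = ifelse(on_target, g$theta, NA_real_),
    gamma_distractor_deg = NA_real_,
    depth_ratio = g$depth, slant_deg = g$slant,
    stringsAsFactors = FALSE)
  new_design(df, 3L, list(depths = depths, slants = slants, tilts = tilts,
                          conditions = conditions, repetitions = 6L))
}

## geometry-linked occlusion probabilities per unique (depth, slant) cell
geometry_linked_p_os <- function(trials, depth_uncertainty = 0.35,
                                 slant_uncertainty = 0, n_samples = 2e4,
                                 seed = 1) {
  key <- paste(trials$depth_ratio, trials$slant_deg)
  p <- numeric(nrow(trials))
  for (k in unique(key)) {
    idx <- which(key == k)
    p[idx] <- occlusion_probability(
      trials$depth_ratio[idx[1]], deg2rad(trials$slant_deg[idx[1]]),
      depth_uncertainty = depth_uncertainty,
      slant_uncertainty = slant_uncertainty,
      n_samples = n_samples, seed = seed)
  }
  p
}

#' Simulate a model observer on a trial design
#'
#' Draws each convex/concave report independently from the generative model's
#' convex-report probability ([response_probabilities()]), after shuffling the
#' trial order (the experiments randomly interleave conditions). Seeded and
#' fully reproducible: the same `(design, params, seed)` gives a byte-identical
#' table.
#'
#' @param design trial template from [design_exp1()] and friends (or any
#'   trial table in the schema).
#' @param params generating [model_params()].
#' @param seed integer seed.
#' @param n_sessions number of repetitions of the whole design.
#' @param observer_id label written to the `observer_id` column.
#' @param occlusion `"fixed"` uses the scalar `p_os`/`p_om` of `params` for
#'   every trial; `"geometry"` substitutes, per dome-stimulus cell, the
#'   Monte-Carlo occlusion probability implied by the stimulus depth and
#'   slant ([occlusion_probability()]), producing the depth- and
#'   slant-dependence of the highlight effect.
#' @param depth_uncertainty,slant_uncertainty spread parameters passed to
#'   [occlusion_probability()] in `"geometry"` mode.
#' @param ignore_highlights simulate an observer blind to highlights (the
#'   restricted-model control), scoring every trial as if both objects were
#'   matte.
#' @return trial table with `response_convex` filled (1 = convex report).
#' @export
simulate_observer <- function(design, params, seed, n_sessions = 1,
                              observer_id = "sim",
                              occlusion = c("fixed", "geometry"),
                              depth_uncertainty = 0.35,
                              slant_uncertainty = 0,
                              ignore_highlights = FALSE) {
  occlusion <- match.arg(occlusion)
  stopifnot(inherits(params, "model_params"), is.numeric(seed))
  trials <- design[rep(seq_len(nrow(design)), times = n_sessions), ]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trials <- trials[sample.int(nrow(trials)), ]
  rownames(trials) <- NULL
  p_os <- NULL
  if (occlusion == "geometry") {
    if (any(is.na(trials$depth_ratio)))
      stop("geometry-linked occlusion needs dome descriptors (depth_ratio, slant_deg)")
    p_os <- geometry_linked_p_os(trials, depth_uncertainty, slant_uncertainty,
                                 seed = seed)
  }
  p <- response_probabilities(trials, params, p_os = p_os,
                              ignore_highlights = ignore_highlights)
  trials$response_convex <- stats::rbinom(nrow(trials), 1, p)
  trials$observer_id <- observer_id
  trials$trial_index <- seq_len(nrow(trials))
  attr(trials, "generating_params") <- params
  attr(trials, "seed") <- seed
  trials
}

#' Write a canonical fixture suite of simulated observers
#'
#' Simulates three observers per experiment at the reference mean parameters,
#' plus one control observer generated from the restricted two-parameter model
#' (single light, uniform convexity prior, highlights ignored), and writes one
#' CSV per observer-experiment plus a JSON manifest recording seeds and
#' generating parameters, from which the files can be regenerated exactly.
#'
#' @param out_dir output directory (created if needed).
#' @param seed base integer seed; per-file seeds are derived from it.
#' @return invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(out_dir, seed = 20140508) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mean_params <- reference_observer_params("mean")
  control_params <- model_params(mu = 0, kappa_phi = 5, p_convex = 0.5,
                                 p_single = 1, p_shiny = 0, p_os = 0,
                                 kappa_n = 100, p_local = 0, p_om = 0)
  designs <- list(design_exp1(), design_exp2(), design_exp3())
  manifest <- list(base_seed = seed,
                   generator = paste0("specocc ", utils::packageVersion("specocc")),
                   mean_params = unclass(mean_params),
                   control_params = unclass(control_params),
                   files = list())
  for (exp in 1:3) {
    for (obs in 1:3) {
      s <- seed %% 1e6 * 100 + exp * 10 + obs
      id <- sprintf("sim%d", obs)
      file <- sprintf("observer_%s_exp%d.csv", id, exp)
      tab <- simulate_observer(designs[[exp]], mean_params, seed = s,
                               observer_id = id)
      write_trials(tab, file.path(out_dir, file))
      manifest$files[[file]] <- list(observer = id, experiment = exp,
                                     seed = s, params = "mean_params")
    }
  }
  s <- seed %% 1e6 * 100 + 99
  file <- "observer_control_exp1.csv"
  tab <- simulate_observer(designs[[1]], control_params, seed = s,
                           observer_id = "control", ignore_highlights = TRUE)
  write_trials(tab, file.path(out_dir, file))
  manifest$files[[file]] <- list(observer = "control", experiment = 1,
                                 seed = s, params = "control_params")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
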