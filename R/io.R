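TRIAL_COLUMNS <- c("observer_id", "experiment", "trial_index", "condition",
                   "theta_target_deg", "theta_distractor_deg",
                   "delta_target", "delta_distractor",
                   "gamma_target_deg", "gamma_distractor_deg",
                   "depth_ratio", "slant_deg", "response_convex")

#' Read and validate a trial table CSV
#'
#' The schema has one row per 2AFC trial with the columns (in order):
#' `observer_id, experiment, trial_index, condition, theta_target_deg,
#' theta_distractor_deg, delta_target, delta_distractor, gamma_target_deg,
#' gamma_distractor_deg, depth_ratio, slant_deg, response_convex`. Angles are
#' degrees at the file boundary and are wrapped to `[0, 360)` on read;
#' missing angular fields are empty, not 0. Validation reports missing/extra
#' columns by name and any row where a highlight tilt is present without its
#' presence flag (or vice versa).
#'
#' @param path CSV file path.
#' @return validated trial table (data frame).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(TRIAL_COLUMNS, names(df))
  extra <- setdiff(names(df), TRIAL_COLUMNS)
  if (length(missing) || length(extra))
    stop("trial table schema mismatch",
         if (length(missing)) paste0("; missing columns: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra columns: ",
                                   paste(extra, collapse = ", ")))
  df <- df[, TRIAL_COLUMNS]
  validate_trials(df)
  for (col in c("theta_target_deg", "theta_distractor_deg",
                "gamma_target_deg", "gamma_distractor_deg"))
    df[[col]] <- ifelse(is.na(df[[col]]), NA_real_, df[[col]] %% 360)
  df
}

validate_trials <- function(df) {
  bad_delta <- which(!(df$delta_target %in% 0:1) | !(df$delta_distractor %in% 0:1))
  if (length(bad_delta))
    stop("delta flags must be 0/1; offending rows: ",
         paste(utils::head(bad_delta, 5), collapse = ", "))
  for (side in c("target", "distractor")) {
    d <- df[[paste0("delta_", side)]]
    g <- df[[paste0("gamma_", side, "_deg")]]
    bad <- which((d == 1 & is.na(g)) | (d == 0 & !is.na(g)))
    if (length(bad))
      stop(sprintf("gamma_%s inconsistent with delta_%s at rows: %s",
                   side, side, paste(utils::head(bad, 5), collapse = ", ")))
  }
  ang <- df[, c("theta_target_deg", "theta_distractor_deg")]
  if (any(!is.finite(as.matrix(ang))))
    stop("gradient tilts must be finite")
  invisible(df)
}

#' @rdname read_trials
#' @param trials trial table to write.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing))
    stop("trial table missing columns: ", paste(missing, collapse = ", "))
  utils::write.csv(trials[, TRIAL_COLUMNS], path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' A run configuration names the pipeline stages to execute and their
#' options, with a mandatory global seed (stochastic stages have no silent
#' default seed).
#'
#' @param path YAML file path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run config must set an explicit seed")
  if (is.null(cfg$out_dir)) stop("run config must set out_dir")
  structure(cfg, class = c("run_config", "list"))
}

#' Summary report over a set of trial tables
#'
#' Emits CSV summaries from simulated (or any schema-conformant) trial
#' tables: convex-report proportion per orientation and condition with a
#' model overlay when parameters are supplied, MI curves, and — for
#' dome-stimulus tables — the highlight effect by depth and slant. Figures
#' (when `make_plots = TRUE` and ggplot2 is installed) are regenerable from
#' the CSVs alone. Reruns on identical inputs are byte-identical.
#'
#' @param trials a trial table or list of them (e.g. one per observer).
#' @param out_dir output directory, created if needed.
#' @param params optional [model_params()] for predicted-probability overlay.
#' @param make_plots also write PNG figures.
#' @return invisibly, the paths written.
#' @export
run_report <- function(trials, out_dir, params = NULL, make_plots = FALSE) {
  if (is.data.frame(trials)) trials <- list(trials)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(trials, function(x) x[, TRIAL_COLUMNS]))
  tab <- tab[!is.na(tab$response_convex), ]
  if (!nrow(tab)) stop("run_report: no responses found in the supplied trials")
  paths <- character(0)

  prop <- stats::aggregate(response_convex ~ experiment + condition +
                             theta_target_deg, tab, mean)
  names(prop)[names(prop) == "response_convex"] <- "prop_convex"
  prop <- prop[order(prop$experiment, prop$condition, prop$theta_target_deg), ]
  if (!is.null(params)) {
    key <- paste(tab$experiment, tab$condition, tab$theta_target_deg)
    pred <- response_probabilities(tab, params)
    prop$model_prob <- stats::aggregate(
      pred ~ key, data.frame(pred = pred, key = key), mean)$pred[
        match(paste(prop$experiment, prop$condition, prop$theta_target_deg),
              sort(unique(key)))]
  }
  p1 <- file.path(out_dir, "proportion_convex.csv")
  utils::write.csv(prop, p1, row.names = FALSE)
  paths <- c(paths, p1)

  for (pairing in c("sm-mm", "sm-ms")) {
    sub <- tab[tab$experiment %in% 1:2, ]
    conds <- c("SM", if (pairing == "sm-mm") "MM" else "MS")
    if (all(conds %in% sub$condition)) {
      mi <- mi_curve(sub, pairing)
      pmi <- file.path(out_dir, sprintf("mi_curve_%s.csv",
                                        gsub("-", "_", pairing)))
      utils::write.csv(mi, pmi, row.names = FALSE)
      paths <- c(paths, pmi)
    }
  }

  if (any(tab$experiment == 3)) {
    eff <- highlight_effect(tab[tab$experiment == 3, ])
    p3a <- file.path(out_dir, "highlight_effect_by_slant.csv")
    p3b <- file.path(out_dir, "highlight_effect_by_depth.csv")
    utils::write.csv(eff$by_slant, p3a, row.names = FALSE)
    utils::write.csv(eff$by_depth, p3b, row.names = FALSE)
    paths <- c(paths, p3a, p3b)
  }

  if (make_plots && requireNamespace("ggplot2", quietly = TRUE)) {
    gg <- ggplot2::ggplot(prop, ggplot2::aes(x = theta_target_deg,
                                             y = prop_convex,
                                             colour = condition)) +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(~experiment) +
      ggplot2::labs(x = "shading orientation (deg)",
                    y = "proportion convex")
    if (!is.null(params))
      gg <- gg + ggplot2::geom_line(ggplot2::aes(y = model_prob))
    pp <- file.path(out_dir, "proportion_convex.png")
    ggplot2::ggsave(pp, gg, width = 9, height = 4, dpi = 120)
    paths <- c(paths, pp)
  }
  invisible(paths)
}
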