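#' Pipeline configuration
#'
#' Bundles every tunable of the processing chain.  The defaults reproduce
#' the reference pipeline: 6th order zero-lag Butterworth at fc = 20 Hz,
#' prominence-screened peak event detection, 101-point cycle
#' normalization, pointwise-CI 95% bands, and alpha = 0.05 statistics.
#'
#' @param fc_hz Filter cutoff, Hz.
#' @param order Butterworth order (single-pass design).
#' @param min_sep_frac,prom_frac Event-detection thresholds (see
#'   [detect_events()]).
#' @param band_type `"ci"` or `"prediction"` (see [mean_band()]).
#' @param alpha Significance level of the statistical layer.
#' @param belt_speed Belt speed in m/s; `NA` = use each recording's own.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(fc_hz = 20, order = 6, min_sep_frac = 0.5,
                            prom_frac = 0.2, band_type = "ci",
                            alpha = 0.05, belt_speed = NA_real_) {
  structure(list(fc_hz = fc_hz, order = order,
                 min_sep_frac = min_sep_frac, prom_frac = prom_frac,
                 band_type = band_type, alpha = alpha,
                 belt_speed = belt_speed),
            class = "pipeline_config")
}

#' Process one trial end to end
#'
#' Runs the full per-trial chain: zero-lag filtering, per-limb gait-event
#' detection, cycle segmentation anchored on the back-right heel strike,
#' the 18 joint-angle series and their per-cycle 101-point curves, and the
#' 53-parameter per-cycle table.
#'
#' @param rec A [trial_recording()].
#' @param config A [pipeline_config()].
#' @return Object of class `gait_analysis`: list with `recording`
#'   (filtered), `events`, `cycles`, `angles`, `curves`
#'   (`101 x 18 x n_cycles`), `mean_curves` (`101 x 18`), `bands`,
#'   `parameters` (data frame) and `config`.
#' @export
process_trial <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "trial_recording"))
  belt <- if (is.finite(config$belt_speed)) config$belt_speed
          else rec$belt_speed
  if (!is.finite(belt))
    stop("belt speed unknown: set it on the recording or in the config")
  filtered <- filter_trial(rec, filter_spec(config$fc_hz, config$order))
  events <- detect_gait_events(filtered, config$min_sep_frac,
                               config$prom_frac)
  cycles <- segment_cycles(events)
  angles <- compute_joint_angles(filtered)
  curves <- cycle_curves(angles, cycles)
  mean_curves <- matrix(NA_real_, 101L, ncol(angles),
                        dimnames = list(NULL, colnames(angles)))
  bands <- vector("list", ncol(angles))
  names(bands) <- colnames(angles)
  for (j in colnames(angles)) {
    cs <- t(curves[, j, ])
    cs <- cs[stats::complete.cases(cs), , drop = FALSE]
    if (nrow(cs) >= 2L) {
      bands[[j]] <- mean_band(cs, type = config$band_type)
      mean_curves[, j] <- bands[[j]]$mean
    }
  }
  parameters <- cycle_parameter_table(filtered, cycles, events, belt,
                                      angles)
  structure(list(recording = filtered, events = events, cycles = cycles,
                 angles = angles, curves = curves,
                 mean_curves = mean_curves, bands = bands,
                 parameters = parameters, config = config),
            class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf("<gait_analysis> condition %s: %d cycles, %d anomalous; %d joint angles x 101 points\n",
              x$recording$condition, nrow(x$parameters),
              sum(x$parameters$anomaly), ncol(x$mean_curves)))
  invisible(x)
}

#' Run the full pipeline over a set of trials
#'
#' Orchestrates import (paths or in-memory recordings), per-trial
#' processing, the statistical comparison layer (when at least a reference
#' and a harness condition are present) and the per-case report.  All
#' outputs are deterministic: identical inputs yield identical tables.
#'
#' @param config A [pipeline_config()].
#' @param trials Named list of inputs, one per condition (names from
#'   `reference`, `harness`, `harness_leash`): file paths (native dialect)
#'   or `trial_recording` objects.
#' @param output_dir Directory for the artifact bundle (created if
#'   needed); `NULL` = no files written.
#' @param report Also write the figure report (see [build_report()]).
#' @return List with `analyses` (per condition), `normality`,
#'   `comparisons`, `rms` and the written `files`.
#' @export
run_pipeline <- function(config = pipeline_config(), trials,
                         output_dir = NULL, report = !is.null(output_dir)) {
  stopifnot(is.list(trials), length(trials) >= 1L, !is.null(names(trials)))
  analyses <- list()
  for (cond in names(trials)) {
    tr <- trials[[cond]]
    if (is.character(tr)) {
      message("importing ", tr)
      tr <- read_trial(tr)
    }
    tr$condition <- cond
    message("processing condition '", cond, "' (", n_frames(tr),
            " frames)")
    analyses[[cond]] <- process_trial(tr, config)
    message("  -> ", nrow(analyses[[cond]]$parameters), " cycles")
  }
  tables <- lapply(analyses, `[[`, "parameters")
  normality <- normality_screen(tables, alpha = config$alpha)
  comparisons <- NULL
  rms <- NULL
  if (all(c("reference", "harness") %in% names(analyses))) {
    comparisons <- comparison_matrix(tables, alpha = config$alpha)
    rms <- lapply(analyses[setdiff(names(analyses), "reference")],
                  function(a) rms_score_table(
                    analyses$reference$mean_curves, a$mean_curves))
  }
  files <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in names(analyses)) {
      f <- file.path(output_dir, paste0("parameters_", cond, ".csv"))
      write_parameters(analyses[[cond]]$parameters, f)
      files <- c(files, f)
    }
    f <- file.path(output_dir, "normality.csv")
    utils::write.csv(normality$table, f, row.names = FALSE)
    files <- c(files, f)
    if (!is.null(comparisons)) {
      f <- file.path(output_dir, "ks_tests.csv")
      utils::write.csv(comparisons$table, f, row.names = FALSE)
      files <- c(files, f)
      f <- file.path(output_dir, "rms_scores.csv")
      rms_df <- data.frame(joint_angle = joint_angle_names(),
                           do.call(cbind, rms), check.names = FALSE)
      utils::write.csv(rms_df, f, row.names = FALSE)
      files <- c(files, f)
    }
    f <- file.path(output_dir, "summary.json")
    jsonlite::write_json(list(
      conditions = names(analyses),
      n_cycles = lapply(tables, nrow),
      pct_normal = normality$per_trial,
      alpha = config$alpha), f, auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    files <- c(files, f)
    if (report)
      files <- c(files, build_report(analyses, output_dir)$files)
  }
  invisible(list(analyses = analyses, normality = normality,
                 comparisons = comparisons, rms = rms, files = files))
}
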