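#' Build the per-case comparison report
#'
#' Generates the standard visual report for one dog's trial set: the 18
#' joint-angle panels (mean curve with 95% band per condition), the 4
#' sagittal paw-path panels, the 53 scalar-parameter distribution panels
#' (violin silhouettes with overlaid per-cycle points), and -- when a
#' reference and at least one other condition are present -- the KS and
#' RMS statistics tables.  Conditions contribute to every panel for which
#' their data exist; panels with missing data are annotated, never
#' silently omitted.  The bundle is deterministic: identical inputs yield
#' identical tables and identically sized figure sets.
#'
#' @param analyses Named list of `gait_analysis` objects (one per
#'   condition), as returned by [process_trial()] or found in
#'   [run_pipeline()] output.
#' @param output_dir Directory to write into (created if needed).
#' @param format Figure format: `"png"` or `"pdf"`.
#' @return Invisibly, a list with `files`, `n_angle_panels` (18),
#'   `n_paw_panels` (4), `n_parameter_panels` (53), and the statistics
#'   tables included.
#' @export
build_report <- function(analyses, output_dir, format = c("png", "pdf")) {
  format <- match.arg(format)
  if (!is.list(analyses) || !length(analyses))
    stop("need at least one processed trial")
  if (inherits(analyses, "gait_analysis")) analyses <- list(analyses)
  if (is.null(names(analyses)) || !all(nzchar(names(analyses))))
    names(analyses) <- vapply(analyses, function(a)
      a$recording$condition, "")
  if (!all(vapply(analyses, inherits, logical(1), "gait_analysis")))
    stop("analyses must be gait_analysis objects (see process_trial)")
  n_cyc <- vapply(analyses, function(a) nrow(a$parameters), integer(1))
  if (all(n_cyc == 0L)) stop("no processed cycles in any trial")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  dev <- switch(format, png = function(f, w, h)
    grDevices::png(f, w, h, res = 110), pdf = function(f, w, h)
      grDevices::pdf(f, w / 110, h / 110))
  files <- character(0)

  # --- joint-angle panels: mean +/- band per condition -------------------
  band_df <- do.call(rbind, lapply(names(analyses), function(cond) {
    a <- analyses[[cond]]
    do.call(rbind, lapply(joint_angle_names(), function(j) {
      b <- a$bands[[j]]
      if (is.null(b))
        return(data.frame(condition = cond, joint = j, percent = 50,
                          mean = NA_real_, lower = NA_real_,
                          upper = NA_real_))
      data.frame(condition = cond, joint = j, percent = 0:100,
                 mean = b$mean, lower = b$lower, upper = b$upper)
    }))
  }))
  band_df$joint <- factor(band_df$joint, levels = joint_angle_names())
  p <- ggplot2::ggplot(band_df,
                       ggplot2::aes(x = .data$percent, y = .data$mean,
                                    colour = .data$condition,
                                    fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~joint, ncol = 3, scales = "free_y",
                        drop = FALSE) +
    ggplot2::labs(x = "gait cycle (%)", y = "joint angle (deg)") +
    ggplot2::theme_minimal(base_size = 9)
  f <- file.path(output_dir, paste0("joint_angles.", format))
  dev(f, 1400, 1800); print(p); grDevices::dev.off()
  files <- c(files, f)

  # --- paw-path panels ---------------------------------------------------
  paw_df <- do.call(rbind, lapply(names(analyses), function(cond) {
    a <- analyses[[cond]]
    do.call(rbind, lapply(LIMBS, function(l) {
      tr <- tryCatch(do.call(rbind, lapply(seq_along(a$cycles),
        function(k) {
          pp <- paw_path(a$recording, l, a$cycles[[k]])
          pp$cycle <- k; pp
        })), error = function(e) NULL)
      if (is.null(tr))
        return(data.frame(condition = cond, limb = l, x = NA_real_,
                          z = NA_real_, cycle = NA_integer_))
      cbind(condition = cond, limb = l, tr)
    }))
  }))
  paw_df$limb <- factor(paw_df$limb, levels = LIMBS)
  p <- ggplot2::ggplot(paw_df,
                       ggplot2::aes(x = .data$x, y = .data$z,
                                    colour = .data$condition,
                                    group = interaction(.data$condition,
                                                        .data$cycle))) +
    ggplot2::geom_path(alpha = 0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(~limb, ncol = 2, drop = FALSE) +
    ggplot2::labs(x = "fore-aft position (mm)",
                  y = "vertical position (mm)") +
    ggplot2::theme_minimal(base_size = 9)
  f <- file.path(output_dir, paste0("paw_paths.", format))
  dev(f, 1200, 900); print(p); grDevices::dev.off()
  files <- c(files, f)

  # --- scalar-parameter distribution panels ------------------------------
  reg <- parameter_registry()
  par_df <- do.call(rbind, lapply(names(analyses), function(cond) {
    tab <- analyses[[cond]]$parameters
    do.call(rbind, lapply(reg, function(pm) data.frame(
      condition = cond, parameter = pm, cycle = tab$cycle,
      value = tab[[pm]])))
  }))
  par_df$parameter <- factor(par_df$parameter, levels = reg)
  # deterministic horizontal spread of the per-cycle points
  par_df$offset <- 0.35 * (par_df$cycle %% 7 - 3) / 3
  with_data <- stats::aggregate(is.finite(par_df$value),
                                by = par_df[c("condition", "parameter")],
                                FUN = sum)
  p <- ggplot2::ggplot(par_df[is.finite(par_df$value), ],
                       ggplot2::aes(x = .data$condition, y = .data$value,
                                    fill = .data$condition)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA, scale = "width",
                         na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(x = as.numeric(factor(.data$condition)) +
                                       .data$offset),
                        size = 0.3, alpha = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~parameter, ncol = 6, scales = "free_y",
                        drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 7) +
    ggplot2::theme(axis.text.x =
                     ggplot2::element_text(angle = 45, hjust = 1))
  f <- file.path(output_dir, paste0("parameters_violin.", format))
  dev(f, 1800, 2000); print(p); grDevices::dev.off()
  files <- c(files, f)

  # --- statistics tables -------------------------------------------------
  tables <- lapply(analyses, `[[`, "parameters")
  normality <- normality_screen(tables)
  f <- file.path(output_dir, "report_normality.csv")
  utils::write.csv(normality$table, f, row.names = FALSE)
  files <- c(files, f)
  comparisons <- NULL; rms <- NULL
  if (all(c("reference", "harness") %in% names(analyses))) {
    comparisons <- comparison_matrix(tables)
    f <- file.path(output_dir, "report_ks.csv")
    utils::write.csv(comparisons$table, f, row.names = FALSE)
    files <- c(files, f)
    rms <- lapply(analyses[setdiff(names(analyses), "reference")],
                  function(a) rms_score_table(
                    analyses$reference$mean_curves, a$mean_curves))
    f <- file.path(output_dir, "report_rms.csv")
    utils::write.csv(data.frame(joint_angle = joint_angle_names(),
                                do.call(cbind, rms),
                                check.names = FALSE),
                     f, row.names = FALSE)
    files <- c(files, f)
  }

  # --- index -------------------------------------------------------------
  missing_note <- with_data[with_data$x == 0, , drop = FALSE]
  idx <- c("# Gait comparison report", "",
           paste0("Conditions: ", paste(names(analyses), collapse = ", ")),
           paste0("Cycles per condition: ",
                  paste(names(n_cyc), n_cyc, sep = "=", collapse = ", ")),
           "",
           "Panels: 18 joint angles, 4 paw paths, 53 parameter distributions.",
           if (nrow(missing_note))
             c("", "Missing data (no finite values):",
               paste0("- ", missing_note$condition, " / ",
                      missing_note$parameter)),
           "", "Files:", paste0("- ", basename(files)))
  f <- file.path(output_dir, "report.md")
  writeLines(unlist(idx), f)
  files <- c(files, f)

  invisible(list(files = files, n_angle_panels = 18L, n_paw_panels = 4L,
                 n_parameter_panels = length(reg),
                 normality = normality, comparisons = comparisons,
                 rms = rms))
}
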