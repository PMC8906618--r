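#' Anderson-Darling test of composite normality
#'
#' Tests whether a sample is drawn from a normal distribution with
#' unspecified mean and variance, using the small-sample-corrected
#' Anderson-Darling statistic and the standard p-value approximation for
#' the composite case.  Samples of fewer than 8 values are reported as
#' `"insufficient"` (the test is unreliable there); constant samples are
#' degenerate and reported as non-normal.
#'
#' @param x Numeric sample.
#' @param alpha Significance level for the `pass` flag (default 0.05).
#' @return List with `statistic`, `p_value`, `pass` (`TRUE` when
#'   `p_value > alpha`), and `status` (`"ok"`, `"insufficient"` or
#'   `"degenerate"`).
#' @export
anderson_darling_normal <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 8L)
    return(list(statistic = NA_real_, p_value = NA_real_, pass = NA,
                status = "insufficient"))
  if (stats::sd(x) == 0)
    return(list(statistic = Inf, p_value = 0, pass = FALSE,
                status = "degenerate"))
  t <- nortest::ad.test(x)
  list(statistic = unname(t$statistic), p_value = unname(t$p.value),
       pass = unname(t$p.value) > alpha, status = "ok")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs.  The exact
#' p-value is used for small tie-free samples (both sizes below
#' `exact_below`); otherwise the asymptotic two-sided approximation.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alpha Significance level for the `same_distribution` flag.
#' @param exact_below Sample-size threshold for the exact p-value.
#' @return List with `statistic` (D), `p_value`, and `same_distribution`
#'   (`TRUE` when `p_value > alpha`, i.e. H0 of identical distributions is
#'   not rejected).
#' @export
ks_two_sample <- function(a, b, alpha = 0.05, exact_below = 30L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) < exact_below && length(b) < exact_below && !ties
  t <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(statistic = unname(t$statistic), p_value = unname(t$p.value),
       same_distribution = unname(t$p.value) > alpha)
}

#' Root-mean-square deviation between two 101-point mean curves
#'
#' The per-joint score comparing a trial's average joint-angle curve with
#' the reference average: the square root of the mean squared pointwise
#' difference over the 101 cycle percents, in degrees.  Zero iff the
#' curves are identical; a constant offset of d degrees scores exactly d.
#'
#' @param ref,trial Numeric vectors of length 101 (average joint angle at
#'   0..100% of the gait cycle).
#' @return RMS deviation in degrees.
#' @export
rms_curve_error <- function(ref, trial) {
  if (length(ref) != 101L || length(trial) != 101L)
    stop("mean curves must have exactly 101 samples")
  sqrt(sum((ref - trial)^2) / 101)
}

#' Per-joint RMS scores of a trial against a reference
#'
#' @param ref_curves,trial_curves `101 x 18` matrices of average joint
#'   angles (columns as [joint_angle_names()]).
#' @return Named numeric vector of 18 RMS scores in degrees (`NA` where a
#'   curve is missing).
#' @export
rms_score_table <- function(ref_curves, trial_curves) {
  stopifnot(nrow(ref_curves) == 101L, nrow(trial_curves) == 101L)
  nms <- colnames(ref_curves)
  vapply(stats::setNames(nms, nms), function(j) {
    r <- ref_curves[, j]; t <- trial_curves[, j]
    if (anyNA(r) || anyNA(t)) NA_real_ else rms_curve_error(r, t)
  }, numeric(1))
}

#' Normality screen of per-cycle parameter tables
#'
#' Runs the Anderson-Darling normality test on every (trial, parameter)
#' sample of per-cycle values.
#'
#' @param tables Named list of parameter tables
#'   ([cycle_parameter_table()]), one per trial.
#' @param alpha Significance level.
#' @return Object of class `normality_report`: data frame `table` with
#'   columns `trial`, `parameter`, `n`, `statistic`, `p_value`, `pass`,
#'   `status`, plus the [summarize_pass_rates()] marginals.
#' @export
normality_screen <- function(tables, alpha = 0.05) {
  stopifnot(is.list(tables), length(tables) >= 1L,
            !is.null(names(tables)))
  reg <- parameter_registry()
  rows <- do.call(rbind, lapply(names(tables), function(tr) {
    tab <- tables[[tr]]
    do.call(rbind, lapply(reg, function(p) {
      x <- tab[[p]]
      r <- anderson_darling_normal(x[is.finite(x)], alpha)
      data.frame(trial = tr, parameter = p, n = sum(is.finite(x)),
                 statistic = r$statistic, p_value = r$p_value,
                 pass = r$pass, status = r$status)
    }))
  }))
  marg <- summarize_pass_rates(rows)
  structure(list(table = rows, per_parameter = marg$per_parameter,
                 per_trial = marg$per_trial, alpha = alpha),
            class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  ok <- x$table$status == "ok"
  cat(sprintf("<normality_report> %d trials x %d parameters; %.1f%% pass at alpha = %g\n",
              length(unique(x$table$trial)),
              length(unique(x$table$parameter)),
              100 * mean(x$table$pass[ok]), x$alpha))
  invisible(x)
}

#' Marginal pass percentages
#'
#' Summarizes a table of pass/fail test outcomes into the two marginal
#' views: per parameter, the percentage of trials (cases) passing; per
#' trial, the percentage of parameters passing.  Missing cells
#' (insufficient or absent samples) are excluded from the denominators,
#' which are reported alongside.
#'
#' @param results Data frame with columns `trial`, `parameter` and a
#'   logical `pass` (`NA` = missing cell).
#' @return List of data frames `per_parameter` (`parameter`, `n_cases`,
#'   `pct_pass`) and `per_trial` (`trial`, `n_parameters`, `pct_pass`).
#' @export
summarize_pass_rates <- function(results) {
  stopifnot(all(c("trial", "parameter", "pass") %in% names(results)))
  by_of <- function(key, nkey) {
    parts <- split(results$pass, results[[key]])
    df <- data.frame(key = names(parts),
                     n = vapply(parts, function(p) sum(!is.na(p)),
                                integer(1)),
                     pct_pass = vapply(parts, function(p)
                       if (all(is.na(p))) NA_real_
                       else 100 * mean(p, na.rm = TRUE), numeric(1)))
    names(df) <- c(key, nkey, "pct_pass")
    rownames(df) <- NULL
    df
  }
  list(per_parameter = by_of("parameter", "n_cases"),
       per_trial = by_of("trial", "n_parameters"))
}

#' Condition-comparison matrix of KS tests
#'
#' For one dog-harness combination, compares each of the 53 parameters'
#' per-cycle distributions between the three condition pairs (reference vs
#' harness, harness vs harness+leash, reference vs harness+leash) with the
#' two-sample Kolmogorov-Smirnov test: 3 x 53 tests.  Parameters missing
#' in either trial yield missing cells, never silent drops.  Each test is
#' evaluated at raw alpha (no multiple-testing correction, matching the
#' screening character of the analysis); Holm adjustment across the 53
#' tests of a comparison is available via `adjust = "holm"`.
#'
#' @param tables Named list of per-cycle parameter tables; names must
#'   include `reference` and `harness`, optionally `harness_leash`.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return Object of class `comparison_result`: data frame `table` with
#'   `comparison`, `parameter`, `n_a`, `n_b`, `statistic`, `p_value`,
#'   `same_distribution`.
#' @export
comparison_matrix <- function(tables, alpha = 0.05, adjust = "none") {
  stopifnot(all(c("reference", "harness") %in% names(tables)))
  pairs <- list(c("reference", "harness"))
  if ("harness_leash" %in% names(tables))
    pairs <- c(pairs, list(c("harness", "harness_leash"),
                           c("reference", "harness_leash")))
  reg <- parameter_registry()
  rows <- do.call(rbind, lapply(pairs, function(pr) {
    tab <- do.call(rbind, lapply(reg, function(p) {
      a <- tables[[pr[1]]][[p]]; b <- tables[[pr[2]]][[p]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (!length(a) || !length(b))
        return(data.frame(comparison = paste(pr, collapse = "_vs_"),
                          parameter = p, n_a = length(a), n_b = length(b),
                          statistic = NA_real_, p_value = NA_real_,
                          same_distribution = NA))
      r <- ks_two_sample(a, b, alpha)
      data.frame(comparison = paste(pr, collapse = "_vs_"), parameter = p,
                 n_a = length(a), n_b = length(b), statistic = r$statistic,
                 p_value = r$p_value, same_distribution = r$same_distribution)
    }))
    if (adjust != "none") {
      tab$p_value <- stats::p.adjust(tab$p_value, method = adjust)
      tab$same_distribution <- ifelse(is.na(tab$p_value), NA,
                                      tab$p_value > alpha)
    }
    tab
  }))
  structure(list(table = rows, alpha = alpha, adjust = adjust),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  ok <- !is.na(x$table$same_distribution)
  cat(sprintf("<comparison_result> %d KS tests (%d comparisons x %d parameters), %.1f%% unchanged at alpha = %g\n",
              sum(ok), length(unique(x$table$comparison)),
              length(unique(x$table$parameter)),
              100 * mean(x$table$same_distribution[ok]), x$alpha))
  invisible(x)
}
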