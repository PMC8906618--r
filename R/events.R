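#' Fore-aft paw-to-girdle phase signal of a limb
#'
#' The signed fore-aft (canonical x) position of the limb's paw marker
#' (index 5) relative to its girdle marker (index 2: greater tubercle for
#' forelimbs, greater trochanter for hindlimbs), in mm.  The paw is
#' farthest cranial of the girdle at heel strike and farthest caudal at
#' toe-off, so local maxima/minima of this signal locate the gait events.
#'
#' @param rec A [trial_recording()] (normally after [filter_trial()]).
#' @param limb `"FR"`, `"FL"`, `"BR"` or `"BL"`.
#' @return Numeric series, one value per frame (positive = paw cranial of
#'   girdle).
#' @export
limb_phase_signal <- function(rec, limb) {
  limb <- match.arg(limb, LIMBS)
  paw <- marker_series(rec, paste0(limb, PAW_IDX), "x")
  girdle <- marker_series(rec, paste0(limb, GIRDLE_IDX), "x")
  paw - girdle
}

# Dominant period of a roughly periodic series, in samples, from the first
# substantial local maximum of its autocorrelation.
dominant_period <- function(x, max_lag = floor(length(x) / 2)) {
  x <- x - mean(x)
  if (max_lag < 3L) return(NA_real_)
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                   demean = FALSE)$acf[, 1, 1]
  lag <- seq_along(ac) - 1L
  # local maxima of the acf at positive lags
  cand <- which(diff(sign(diff(ac))) < 0) + 1L
  cand <- cand[lag[cand] > 1L & ac[cand] > 0.2]
  if (!length(cand)) return(NA_real_)
  lag[cand[which.max(ac[cand])]]
}

# Local extrema with prominences.  Returns indices of strict local maxima
# of x (plateaus take their first sample) and the prominence of each.
local_maxima <- function(x) {
  n <- length(x)
  d <- diff(x)
  # collapse plateaus: use sign of surrounding slopes
  s <- sign(d)
  nz <- which(s != 0)
  if (!length(nz)) return(list(idx = integer(0), prom = numeric(0)))
  s_filled <- s
  for (i in seq_len(n - 1L)) if (s_filled[i] == 0 && i > 1)
    s_filled[i] <- s_filled[i - 1]
  idx <- which(diff(s_filled) < 0) + 1L
  idx <- idx[idx > 1L & idx < n]
  prom <- vapply(idx, function(i) {
    left_min <- x[i]; j <- i
    while (j > 1L && x[j - 1L] <= x[i]) { j <- j - 1L; left_min <- min(left_min, x[j]) }
    left_base <- if (j == 1L && x[j] <= x[i]) min(left_min, x[1]) else left_min
    right_min <- x[i]; j <- i
    while (j < n && x[j + 1L] <= x[i]) { j <- j + 1L; right_min <- min(right_min, x[j]) }
    right_base <- right_min
    x[i] - max(left_base, right_base)
  }, numeric(1))
  list(idx = idx, prom = prom)
}

# Keep peaks with prominence >= min_prom, then enforce a minimum
# separation, retaining the more prominent of any conflicting pair.
select_peaks <- function(peaks, min_prom, min_sep) {
  keep <- peaks$prom >= min_prom
  idx <- peaks$idx[keep]; prom <- peaks$prom[keep]
  if (length(idx) <= 1L) return(idx)
  ord <- order(prom, decreasing = TRUE)
  chosen <- integer(0)
  for (i in ord) {
    if (all(abs(idx[i] - chosen) >= min_sep)) chosen <- c(chosen, idx[i])
  }
  sort(chosen)
}

#' Detect heel-strike and toe-off events in a phase signal
#'
#' Heel strikes are the local maxima of the fore-aft paw-to-girdle signal
#' (paw farthest cranial), toe-offs its local minima (paw farthest caudal).
#' Candidate extrema are screened by prominence (default 20% of the
#' signal's interquartile range -- scale-free across body sizes) and by a
#' minimum separation of half the dominant period (estimated from the
#' signal's autocorrelation).  Strict heel-strike/toe-off alternation is
#' then enforced by keeping the most prominent extremum of any same-kind
#' run.
#'
#' @param x Phase signal from [limb_phase_signal()]; should cover at least
#'   two stride periods.
#' @param frame_rate Sampling frequency in Hz.
#' @param min_sep_frac Minimum extremum separation as a fraction of the
#'   dominant period.
#' @param prom_frac Minimum prominence as a fraction of the signal IQR.
#' @return List with integer frame indices `heel_strikes` and `toe_offs`
#'   (each strictly increasing).
#' @export
detect_events <- function(x, frame_rate, min_sep_frac = 0.5,
                          prom_frac = 0.2) {
  if (!all(is.finite(x))) stop("phase signal must be finite")
  iqr <- stats::IQR(x)
  if (iqr <= .Machine$double.eps)
    stop("detection error: phase signal has no structure (constant?)")
  period <- dominant_period(x)
  min_sep <- if (is.finite(period)) min_sep_frac * period else 1
  min_prom <- prom_frac * iqr
  maxima <- local_maxima(x)
  minima <- local_maxima(-x)
  hs <- select_peaks(maxima, min_prom, min_sep)
  to <- select_peaks(minima, min_prom, min_sep)
  if (!length(hs) || !length(to))
    stop("detection error: no extrema found")
  # enforce alternation: within any run of same-kind events keep the most
  # prominent one
  ev <- data.frame(idx = c(hs, to),
                   kind = rep(c("hs", "to"), c(length(hs), length(to))),
                   prom = c(maxima$prom[match(hs, maxima$idx)],
                            minima$prom[match(to, minima$idx)]))
  ev <- ev[order(ev$idx), ]
  run <- cumsum(c(TRUE, ev$kind[-1] != ev$kind[-nrow(ev)]))
  keep <- unlist(lapply(split(seq_len(nrow(ev)), run), function(i)
    i[which.max(ev$prom[i])]), use.names = FALSE)
  ev <- ev[sort(keep), ]
  list(heel_strikes = ev$idx[ev$kind == "hs"],
       toe_offs = ev$idx[ev$kind == "to"])
}

#' Detect gait events for all four limbs
#'
#' @param rec A (filtered) [trial_recording()].
#' @param min_sep_frac,prom_frac Passed to [detect_events()].
#' @return A `gait_events` object: named list over limbs `FR`, `FL`, `BR`,
#'   `BL`, each holding `heel_strikes` and `toe_offs` frame indices, with
#'   the frame rate attached.
#' @export
detect_gait_events <- function(rec, min_sep_frac = 0.5, prom_frac = 0.2) {
  ev <- lapply(stats::setNames(LIMBS, LIMBS), function(l)
    detect_events(limb_phase_signal(rec, l), rec$frame_rate,
                  min_sep_frac, prom_frac))
  structure(ev, frame_rate = rec$frame_rate, class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat("<gait_events>\n")
  for (l in names(x))
    cat(sprintf("  %s: %d heel strikes, %d toe-offs\n", l,
                length(x[[l]]$heel_strikes), length(x[[l]]$toe_offs)))
  invisible(x)
}

#' Segment a recording into gait cycles
#'
#' A gait cycle spans two consecutive heel strikes of the back-right limb
#' (marker BR5).  Each cycle records the other limbs' events falling inside
#' `[start, end)`; cycles in which any limb lacks exactly one heel strike
#' and one toe-off are flagged incomplete (kept, not dropped).
#'
#' @param events A `gait_events` object from [detect_gait_events()].
#' @param frame_rate Sampling frequency in Hz (defaults to the rate stored
#'   in `events`).
#' @return A `gait_cycles` object: list of cycles, each with `start_frame`,
#'   `end_frame`, `duration_s`, per-limb `events`, and `complete` flag.
#' @export
segment_cycles <- function(events, frame_rate = attr(events, "frame_rate")) {
  stopifnot(inherits(events, "gait_events"))
  br <- events$BR$heel_strikes
  if (length(br) < 2L)
    stop("segmentation error: need at least 2 back-right heel strikes, got ",
         length(br))
  cycles <- lapply(seq_len(length(br) - 1L), function(k) {
    start <- br[k]; end <- br[k + 1L]
    ev <- lapply(events[LIMBS], function(e) list(
      heel_strikes = e$heel_strikes[e$heel_strikes >= start &
                                      e$heel_strikes < end],
      toe_offs = e$toe_offs[e$toe_offs >= start & e$toe_offs < end]))
    complete <- all(vapply(ev, function(e)
      length(e$heel_strikes) == 1L && length(e$toe_offs) == 1L, logical(1)))
    list(start_frame = start, end_frame = end,
         duration_s = (end - start) / frame_rate,
         events = ev, complete = complete)
  })
  structure(cycles, frame_rate = frame_rate, class = "gait_cycles")
}

#' @export
print.gait_cycles <- function(x, ...) {
  d <- vapply(x, `[[`, numeric(1), "duration_s")
  cat(sprintf("<gait_cycles> %d cycles, stride time %.3f +/- %.3f s, %d complete\n",
              length(x), mean(d), stats::sd(d),
              sum(vapply(x, `[[`, logical(1), "complete"))))
  invisible(x)
}
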