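#' Read a marker-trajectory export
#'
#' Reads the native text dialect: a metadata header of `key=value` lines
#' (at minimum `frame_rate` and `n_frames`; optionally `markers`,
#' `belt_speed`, `condition`, `subject_id`, `mass_kg`, `gait_pattern`)
#' followed by one whitespace- or comma-separated numeric row per frame
#' holding 25 x 3 coordinates in marker order (x, y, z per marker).
#' Missing samples are written as `NA` or `NaN` and become masked samples,
#' never zeros.
#'
#' @param path Path to the export file.
#' @param axis_map Axis mapping from the file's frame to the canonical
#'   frame (string or [axis_mapping()]); default identity.
#' @param belt_speed,condition Override the header values (useful when the
#'   header lacks them).
#' @return A [trial_recording()].
#' @export
read_trial <- function(path, axis_map = "xyz", belt_speed = NULL,
                       condition = NULL) {
  if (is.character(axis_map)) axis_map <- axis_mapping(axis_map)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  is_hdr <- grepl("^\\s*[A-Za-z_][A-Za-z0-9_]*\\s*=", lines)
  n_hdr <- if (any(!is_hdr)) which(!is_hdr)[1] - 1L else length(lines)
  hdr_lines <- lines[seq_len(n_hdr)]
  kv <- strsplit(sub("\\s*=\\s*", "=", trimws(hdr_lines)), "=", fixed = TRUE)
  header <- stats::setNames(vapply(kv, function(x)
    paste(x[-1], collapse = "="), ""), vapply(kv, `[[`, "", 1))
  need <- c("frame_rate", "n_frames")
  if (!all(need %in% names(header)))
    stop("malformed header: missing ", paste(setdiff(need, names(header)),
                                             collapse = ", "))
  frame_rate <- as.numeric(header["frame_rate"])
  n <- as.integer(header["n_frames"])
  if (!is.finite(frame_rate) || is.na(n))
    stop("malformed header: frame_rate/n_frames not numeric")
  markers <- canonical_markers()
  if ("markers" %in% names(header)) {
    labs <- trimws(strsplit(header["markers"], ",")[[1]])
    unknown <- setdiff(labs, markers)
    if (length(unknown))
      stop("labelling error: unknown marker label(s) ",
           paste(unknown, collapse = ", "))
    if (length(labs) != length(markers) || anyDuplicated(labs))
      stop("labelling error: header must list all 25 canonical markers once")
  } else labs <- markers
  body <- lines[-seq_len(n_hdr)]
  if (length(body) != n)
    stop("integrity error: header announces ", n, " frames but file has ",
         length(body), " data rows")
  num <- utils::read.table(text = body, sep = "", dec = ".",
                           na.strings = c("NA", "NaN", "nan"),
                           colClasses = "numeric",
                           comment.char = "")
  if (ncol(num) == 1L && any(grepl(",", body, fixed = TRUE)))
    num <- utils::read.table(text = body, sep = ",",
                             na.strings = c("NA", "NaN", "nan"),
                             colClasses = "numeric")
  num <- as.matrix(num)
  if (ncol(num) != 3L * length(labs))
    stop("integrity error: expected ", 3L * length(labs),
         " columns per frame, found ", ncol(num))
  pos <- array(NA_real_, c(n, 3, length(labs)),
               dimnames = list(NULL, c("x", "y", "z"), labs))
  for (i in seq_along(labs))
    pos[, , i] <- apply_axis_mapping(num[, (3 * i - 2):(3 * i), drop = FALSE],
                                     axis_map)
  bs <- if (!is.null(belt_speed)) belt_speed
        else if ("belt_speed" %in% names(header))
          as.numeric(header["belt_speed"]) else NA_real_
  cond <- if (!is.null(condition)) condition
          else if ("condition" %in% names(header)) header[["condition"]]
          else "reference"
  subject <- list()
  for (k in c("subject_id", "mass_kg", "gait_pattern"))
    if (k %in% names(header)) subject[[k]] <- header[[k]]
  trial_recording(pos, frame_rate, belt_speed = bs, condition = cond,
                  subject = subject)
}

#' Write a recording in the native export dialect
#'
#' @param rec A [trial_recording()].
#' @param path Output path.
#' @param digits Decimal places for coordinates (default 4; sub-micrometre
#'   at mm scale, so a write/read round trip preserves values to the file's
#'   stated precision).
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path, digits = 4) {
  stopifnot(inherits(rec, "trial_recording"))
  markers <- dimnames(rec$positions)[[3]]
  hdr <- c("# quadgait marker export",
           paste0("frame_rate=", format(rec$frame_rate, digits = 12)),
           paste0("n_frames=", n_frames(rec)),
           paste0("markers=", paste(markers, collapse = ",")),
           paste0("condition=", rec$condition))
  if (is.finite(rec$belt_speed))
    hdr <- c(hdr, paste0("belt_speed=", format(rec$belt_speed, digits = 12)))
  for (k in c("subject_id", "mass_kg", "gait_pattern"))
    if (!is.null(rec$subject[[k]]))
      hdr <- c(hdr, paste0(k, "=", rec$subject[[k]]))
  # interleave as x,y,z per marker
  flat <- do.call(cbind, lapply(seq_along(markers), function(i)
    rec$positions[, , i]))
  rows <- apply(round(flat, digits), 1, paste, collapse = " ")
  rows <- gsub("NA", "NaN", rows, fixed = TRUE)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a TRC (Track Row Column) marker file
#'
#' Minimal reader for the tab-separated TRC dialect common to motion-capture
#' tooling: line 3 holds `DataRate` etc., line 4 the marker names (one per
#' marker, followed by two empty cells), data rows start with frame number
#' and time.  Coordinates are assumed to be in mm unless the `Units` field
#' says `m`.
#'
#' @inheritParams read_trial
#' @return A [trial_recording()].
#' @export
read_trc <- function(path, axis_map = "xyz", belt_speed = NA_real_,
                     condition = "reference") {
  if (is.character(axis_map)) axis_map <- axis_mapping(axis_map)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6L) stop("malformed header: TRC file too short")
  meta_keys <- strsplit(lines[2], "\t")[[1]]
  meta_vals <- strsplit(lines[3], "\t")[[1]]
  meta <- stats::setNames(as.list(meta_vals[seq_along(meta_keys)]), meta_keys)
  frame_rate <- as.numeric(meta[["DataRate"]])
  if (!length(frame_rate) || !is.finite(frame_rate))
    stop("malformed header: DataRate missing")
  scale <- if (identical(tolower(meta[["Units"]] %||% "mm"), "m")) 1000 else 1
  name_row <- strsplit(lines[4], "\t")[[1]]
  labs <- name_row[-(1:2)]
  labs <- labs[nzchar(labs)]
  unknown <- setdiff(labs, canonical_markers())
  if (length(unknown))
    stop("labelling error: unknown marker label(s) ",
         paste(unknown, collapse = ", "))
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  num <- utils::read.table(text = body, sep = "\t",
                           na.strings = c("", "NA", "NaN"))
  num <- as.matrix(num[, -(1:2), drop = FALSE]) * scale
  if (ncol(num) < 3L * length(labs))
    stop("integrity error: fewer coordinate columns than markers")
  n <- nrow(num)
  pos <- array(NA_real_, c(n, 3, 25),
               dimnames = list(NULL, c("x", "y", "z"), canonical_markers()))
  for (i in seq_along(labs))
    pos[, , labs[i]] <- apply_axis_mapping(num[, (3 * i - 2):(3 * i),
                                               drop = FALSE], axis_map)
  trial_recording(pos, frame_rate, belt_speed = belt_speed,
                  condition = condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a per-cycle parameter table
#'
#' One row per gait cycle with the 53 named scalar parameters (see
#' [parameter_registry()]) plus cycle index, condition and anomaly-flag
#' metadata.  `read_parameters(write_parameters(x))` returns equal values.
#'
#' @param params Data frame as produced by [cycle_parameter_table()].
#' @param path Output (input) CSV path.
#' @return `path` invisibly (`write_parameters`); the table
#'   (`read_parameters`).
#' @export
write_parameters <- function(params, path) {
  if (!is.data.frame(params) || nrow(params) == 0L)
    stop("parameter table must have at least one cycle")
  missing_cols <- setdiff(parameter_registry(), names(params))
  if (length(missing_cols))
    stop("parameter table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(params, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
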