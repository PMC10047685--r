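#' Construct an overnight oximetry recording
#'
#' The canonical in-memory representation of an overnight SpO2 recording that
#' every analysis function in this package consumes: a uniformly sampled SpO2
#' series (percent), a per-sample validity mask, and a half-open sleep window
#' `[sleep_onset_index, sleep_offset_index)` bounding the samples that enter
#' index computation.
#'
#' Samples that are missing (`NA`) or outside the physical range \[0, 100\] are
#' flagged invalid automatically; values are never altered, only masked.
#'
#' @param spo2 Numeric vector of SpO2 values in percent. `NA` allowed.
#' @param sample_interval_s Seconds per sample (positive; pulse oximeters
#'   typically store one averaged value every 4 s).
#' @param valid Optional logical vector, `TRUE` where the signal is usable.
#'   Defaults to non-missing, in-range samples. Out-of-range or missing
#'   samples are forced invalid regardless.
#' @param sleep_onset_index,sleep_offset_index 1-based half-open sample window
#'   analyzed as sleep. Defaults to the full recording.
#' @param subject_id Opaque subject label.
#' @param visit One of `"pre"`, `"post"`, `"unknown"`.
#' @return An object of class `oximetry_recording`.
#' @seealso [read_recording()], [trim_to_sleep()], [quality_check()]
#' @export
#' @examples
#' rec <- oximetry_recording(c(97, 97, 96, 97), sample_interval_s = 4)
#' rec
oximetry_recording <- function(spo2, sample_interval_s = 4, valid = NULL,
                               sleep_onset_index = 1L,
                               sleep_offset_index = length(spo2) + 1L,
                               subject_id = NA_character_,
                               visit = c("unknown", "pre", "post")) {
  visit <- match.arg(visit)
  spo2 <- as.numeric(spo2)
  in_range <- !is.na(spo2) & spo2 >= 0 & spo2 <= 100
  if (is.null(valid)) valid <- in_range else valid <- as.logical(valid) & in_range
  rec <- structure(
    list(spo2 = spo2,
         valid = valid,
         sample_interval_s = as.numeric(sample_interval_s),
         sleep_onset_index = as.integer(sleep_onset_index),
         sleep_offset_index = as.integer(sleep_offset_index),
         subject_id = subject_id,
         visit = visit),
    class = "oximetry_recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "oximetry_recording"))
  n <- length(rec$spo2)
  if (length(rec$valid) != n)
    stop("valid mask and spo2 must have equal length", call. = FALSE)
  if (!is.finite(rec$sample_interval_s) || rec$sample_interval_s <= 0)
    stop("sample_interval_s must be positive", call. = FALSE)
  if (rec$sleep_onset_index < 1L || rec$sleep_onset_index >= rec$sleep_offset_index ||
      rec$sleep_offset_index > n + 1L)
    stop("sleep window indices out of range", call. = FALSE)
  bad <- rec$valid & (is.na(rec$spo2) | rec$spo2 < 0 | rec$spo2 > 100)
  if (any(bad))
    stop("valid samples must lie in [0, 100]", call. = FALSE)
  invisible(rec)
}

#' @export
print.oximetry_recording <- function(x, ...) {
  n <- length(x$spo2)
  win <- sleep_window(x)
  cat("<oximetry_recording>", "\n")
  cat(sprintf("  subject: %s  visit: %s\n", x$subject_id, x$visit))
  cat(sprintf("  %d samples @ %.3g s (%.2f h total)\n",
              n, x$sample_interval_s, n * x$sample_interval_s / 3600))
  cat(sprintf("  sleep window: samples %d..%d (%.2f h), %.2f%% invalid\n",
              x$sleep_onset_index, x$sleep_offset_index - 1L,
              length(win) * x$sample_interval_s / 3600,
              100 * mean(!x$valid[win])))
  v <- x$spo2[win][x$valid[win]]
  if (length(v))
    cat(sprintf("  SpO2 in window: mean %.1f%%, range %.0f-%.0f%%\n",
                mean(v), min(v), max(v)))
  invisible(x)
}

#' Sample indices of the analyzed sleep window
#' @param rec An [oximetry_recording()].
#' @return Integer vector of 1-based sample indices inside the sleep window.
#' @export
sleep_window <- function(rec) {
  seq.int(rec$sleep_onset_index, rec$sleep_offset_index - 1L)
}

#' Hours of valid signal inside the sleep window
#'
#' The denominator used for the oxygen desaturation indices: invalid samples
#' do not contribute analyzed time.
#' @param rec An [oximetry_recording()].
#' @return Hours of valid analyzed sleep.
#' @export
valid_hours <- function(rec) {
  win <- sleep_window(rec)
  sum(rec$valid[win]) * rec$sample_interval_s / 3600
}

#' @export
as.data.frame.oximetry_recording <- function(x, ...) {
  data.frame(t_s = (seq_along(x$spo2) - 1) * x$sample_interval_s,
             spo2 = x$spo2,
             quality = as.integer(x$valid))
}

#' Read an overnight SpO2 recording
#'
#' Reads a delimited-text (CSV) or European Data Format (EDF) oximetry
#' recording into an [oximetry_recording()]. CSV files must carry a header row
#' with a time column (seconds from recording start) and an SpO2 column in
#' percent; an optional 0/1 quality column marks device-rejected samples
#' (0 = artifact). For EDF the first signal whose label contains "SpO2"
#' (case-insensitive) is used, at the file's stated sampling rate.
#'
#' Missing, non-numeric or out-of-range (outside \[0, 100\]) SpO2 samples are
#' flagged invalid, never dropped or altered, so the series stays uniformly
#' spaced. Optionally, physiologically implausible jumps larger than
#' `max_jump_pct` percent between consecutive samples are also flagged.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`; default guesses from the file extension.
#' @param column_spec Named list mapping roles to CSV column names:
#'   `time`, `spo2`, and optionally `quality`.
#' @param sample_interval_s Override the sampling interval; by default it is
#'   inferred from the time column (CSV) or the EDF header.
#' @param time_tolerance_s Maximum deviation from uniform spacing before the
#'   file is rejected as non-uniform.
#' @param max_jump_pct Flag samples whose absolute change from the previous
#'   valid sample exceeds this (percent per sample). `Inf` (default) disables
#'   the rule; device-side artifact rejection normally covers this.
#' @return An [oximetry_recording()].
#' @export
read_recording <- function(path,
                           format = c("auto", "csv", "edf"),
                           column_spec = list(time = "t_s", spo2 = "spo2",
                                              quality = "quality"),
                           sample_interval_s = NULL,
                           time_tolerance_s = 0.01,
                           max_jump_pct = Inf) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  if (format == "edf") {
    sig <- read_edf_spo2(path)
    spo2 <- sig$spo2
    dt <- if (is.null(sample_interval_s)) sig$sample_interval_s else sample_interval_s
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c(column_spec$time, column_spec$spo2)
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("missing column(s) in '", path, "': ", paste(miss, collapse = ", "),
           call. = FALSE)
    t_s <- suppressWarnings(as.numeric(df[[column_spec$time]]))
    spo2 <- suppressWarnings(as.numeric(df[[column_spec$spo2]]))
    if (anyNA(t_s)) stop("non-numeric timestamp in '", path, "'", call. = FALSE)
    if (length(t_s) >= 2) {
      dts <- diff(t_s)
      dt <- if (is.null(sample_interval_s)) stats::median(dts) else sample_interval_s
      off <- which(abs(dts - dt) > time_tolerance_s)
      if (length(off))
        stop(sprintf("non-uniform sampling in '%s': row %d (interval %.4g s, expected %.4g s)",
                     path, off[1] + 1L, dts[off[1]], dt), call. = FALSE)
    } else {
      dt <- if (is.null(sample_interval_s)) 4 else sample_interval_s
    }
    if (!is.null(column_spec$quality) && column_spec$quality %in% names(df)) {
      q <- df[[column_spec$quality]]
      qvalid <- !(suppressWarnings(as.numeric(q)) %in% 0)
    } else qvalid <- rep(TRUE, length(spo2))
  }
  if (format == "edf") qvalid <- rep(TRUE, length(spo2))
  valid <- qvalid & !is.na(spo2) & spo2 >= 0 & spo2 <= 100
  if (is.finite(max_jump_pct)) {
    jump <- c(FALSE, abs(diff(spo2)) > max_jump_pct)
    jump[is.na(jump)] <- FALSE
    valid <- valid & !jump
  }
  oximetry_recording(spo2, sample_interval_s = dt, valid = valid)
}

#' Write a recording to the package CSV dialect
#'
#' Columns `t_s` (seconds from start), `spo2` (percent) and `quality`
#' (1 = usable, 0 = artifact). Re-reading with [read_recording()] reproduces
#' SpO2 values and the validity mask exactly.
#'
#' @param rec An [oximetry_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- as.data.frame(rec)
  df$spo2 <- ifelse(is.na(df$spo2), "", format(df$spo2, digits = 15, trim = TRUE,
                                               scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict the analyzed window to the reported sleep period
#'
#' Awake time at the beginning and end of an overnight recording (as noted on
#' the caregiver's observation sheet) is excluded from all index computation.
#' The window is half-open: a sample at time `t` is analyzed iff
#' `onset_s <= t < offset_s`.
#'
#' @param rec An [oximetry_recording()].
#' @param onset_s,offset_s Sleep onset and offset, seconds from recording
#'   start. `0 <= onset_s < offset_s <=` recording span.
#' @return The recording with the sleep window set.
#' @export
trim_to_sleep <- function(rec, onset_s, offset_s) {
  validate_recording(rec)
  span <- length(rec$spo2) * rec$sample_interval_s
  if (!is.finite(onset_s) || !is.finite(offset_s) ||
      onset_s < 0 || offset_s > span || onset_s >= offset_s)
    stop(sprintf("invalid sleep window [%.6g, %.6g) for a %.6g s recording",
                 onset_s, offset_s, span), call. = FALSE)
  t_s <- (seq_along(rec$spo2) - 1) * rec$sample_interval_s
  idx <- which(t_s >= onset_s & t_s < offset_s)
  if (!length(idx)) stop("sleep window contains no samples", call. = FALSE)
  rec$sleep_onset_index <- idx[1]
  rec$sleep_offset_index <- idx[length(idx)] + 1L
  validate_recording(rec)
  rec
}

#' Quality gate for an overnight recording
#'
#' A recording is analyzable when the sleep window is long enough (default at
#' least 6 h) and the artifact rate inside it is low enough (default below
#' 2.5% of samples). Both thresholds are configurable; recordings failing
#' either gate should be excluded from screening decisions.
#'
#' The check depends only on the validity mask and window length, never on
#' the SpO2 values themselves.
#'
#' @param rec An [oximetry_recording()].
#' @param min_duration_h Minimum analyzed sleep duration, hours.
#' @param max_artifact_pct Maximum percent of invalid samples in the window.
#' @return A list of class `nox_quality` with `duration_h`, `artifact_pct`,
#'   `passes`, and `reasons` (character vector, empty when passing).
#' @export
#' @examples
#' rec <- oximetry_recording(rep(97, 6 * 900))  # 6 h at 4 s
#' quality_check(rec)
quality_check <- function(rec, min_duration_h = 6, max_artifact_pct = 2.5) {
  validate_recording(rec)
  win <- sleep_window(rec)
  if (!length(win)) stop("empty sleep window", call. = FALSE)
  duration_h <- length(win) * rec$sample_interval_s / 3600
  artifact_pct <- 100 * mean(!rec$valid[win])
  reasons <- character()
  if (duration_h < min_duration_h) reasons <- c(reasons, "duration")
  if (artifact_pct >= max_artifact_pct) reasons <- c(reasons, "artifact")
  structure(list(duration_h = duration_h,
                 artifact_pct = artifact_pct,
                 passes = length(reasons) == 0L,
                 reasons = reasons),
            class = "nox_quality")
}

#' @export
print.nox_quality <- function(x, ...) {
  cat(sprintf("<nox_quality> %.2f h, %.2f%% artifact: %s\n",
              x$duration_h, x$artifact_pct,
              if (x$passes) "PASS" else paste("FAIL:", paste(x$reasons, collapse = ", "))))
  invisible(x)
}
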