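#' Cumulative saturation area (CSA)
#'
#' A distribution-based summary of an overnight SpO2 recording that needs no
#' event cutoffs. SpO2 values in the sleep window are binned (width 1%,
#' anchored at integers, so a value `v` falls in bin `floor(v)`); the
#' ascending cumulative relative frequency `F(s)` (in percent) is formed over
#' bins, and the CSA is the rectangle-rule area under the cumulative
#' frequency line from the lowest occupied bin to 100:
#' \deqn{CSA = \sum_{s = s_{min}}^{100} F(s).}
#' The index is dimensionless. Its analytic minimum is 100, attained exactly
#' when every valid sample equals 100%; it grows as saturation mass shifts to
#' lower bins, i.e. with a lower mean and/or a wider spread of SpO2.
#'
#' @param rec An [oximetry_recording()].
#' @param bin_width_pct Bin width in percent SpO2. The default of 1 matches
#'   the integer-percent resolution of pulse-oximeter output; other widths
#'   are supported (the area is scaled by the width) but are a deviation from
#'   the validated construction.
#' @return The CSA (dimensionless).
#' @export
#' @examples
#' compute_csa(oximetry_recording(rep(100, 100)))  # 100, the minimum
#' compute_csa(oximetry_recording(rep(c(100, 99), 50)))  # 150
compute_csa <- function(rec, bin_width_pct = 1) {
  validate_recording(rec)
  win <- sleep_window(rec)
  v <- rec$spo2[win][rec$valid[win]]
  if (!length(v)) stop("no valid samples in the sleep window", call. = FALSE)
  w <- bin_width_pct
  bins <- floor(v / w) * w
  grid <- seq(min(bins), 100, by = w)
  F_s <- 100 * vapply(grid, function(s) mean(bins <= s), numeric(1))
  sum(F_s) * w
}

#' Sample-entropy parameters
#'
#' @param m Embedding dimension (template length), a positive integer.
#' @param r_factor Matching tolerance as a multiple of the series SD.
#' @param r_floor Absolute lower bound on the tolerance, in percent SpO2.
#'   The default 0 keeps the tolerance purely SD-scaled; a small floor
#'   (e.g. 0.15) stabilizes near-constant signals.
#' @return A list of class `sse_params`.
#' @export
sse_params <- function(m = 2L, r_factor = 0.2, r_floor = 0) {
  if (!is.finite(m) || m < 1 || m != round(m))
    stop("m must be a positive integer", call. = FALSE)
  if (!is.finite(r_factor) || r_factor <= 0)
    stop("r_factor must be positive", call. = FALSE)
  structure(list(m = as.integer(m), r_factor = r_factor, r_floor = r_floor),
            class = "sse_params")
}

#' SpO2 sample entropy (SSE)
#'
#' Sample entropy (SampEn) of the SpO2 series: with `B` the number of pairs
#' of length-`m` templates agreeing within Chebyshev tolerance `r` and `A`
#' the number also agreeing at length `m + 1` (self-matches excluded),
#' \deqn{SSE = -\ln(A/B), \quad r = \max(r_{factor} \times SD, r_{floor}).}
#' A regular trace — few or shallow fluctuations from baseline — yields low
#' entropy; frequent desaturations raise it. SampEn is largely insensitive
#' to record length, which suits overnight recordings of varying duration.
#'
#' Invalid samples are dropped and the remaining valid series concatenated
#' (gaps are not modelled). Degenerate cases: a constant series (SD = 0)
#' returns 0; if no template pair matches at length `m + 1` (`A = 0`) the
#' value cannot be distinguished from infinity, so the finite upper bound
#' `-ln(1/(B+1))` is returned with attribute `upper_bounded = TRUE`, keeping
#' downstream ROC analysis well defined.
#'
#' @param rec An [oximetry_recording()].
#' @param params An [sse_params()].
#' @return The sample entropy (dimensionless, >= 0), possibly with attribute
#'   `upper_bounded`.
#' @export
#' @examples
#' compute_sse(oximetry_recording(rep(96, 50)))  # constant series -> 0
compute_sse <- function(rec, params = sse_params()) {
  validate_recording(rec)
  win <- sleep_window(rec)
  x <- rec$spo2[win][rec$valid[win]]
  m <- params$m
  if (length(x) < m + 2)
    stop("need at least m + 2 valid samples for sample entropy", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(0)
  r <- max(params$r_factor * s, params$r_floor)
  cnt <- sampen_counts(x, m, r)
  if (cnt$B == 0 || cnt$A == 0) {
    out <- -log(1 / (cnt$B + 1))
    attr(out, "upper_bounded") <- TRUE
    return(out)
  }
  -log(cnt$A / cnt$B)
}

#' Summarize one recording into its screening indices
#'
#' Runs the full single-recording pipeline: quality gate, baseline tracking,
#' desaturation detection at the 3% and 4% thresholds, ODI3/ODI4 (per hour of
#' valid analyzed sleep), cluster detection and McGill score (from 4%
#' events), mean and SD of SpO2 over valid sleep-window samples, CSA and SSE.
#'
#' @param rec An [oximetry_recording()].
#' @param baseline_cfg A [baseline_config()].
#' @param sse A [sse_params()].
#' @param min_duration_s Minimum desaturation duration, seconds.
#' @param max_gap_s Longest bridgeable invalid gap, seconds.
#' @param csa_bin_width_pct CSA bin width, percent.
#' @param min_duration_h,max_artifact_pct Quality-gate thresholds.
#' @param force Proceed (with a warning) when the quality gate fails.
#' @return A list of class `nox_summary`: `subject_id`, `visit`,
#'   `duration_h`, `artifact_pct`, `quality_pass`, `mean_spo2`, `sd_spo2`,
#'   `odi3`, `odi4`, `mos`, `csa`, `sse`, plus the event and cluster tables
#'   in attributes `events3`, `events4`, `clusters`.
#' @export
summarize_recording <- function(rec,
                                baseline_cfg = baseline_config(),
                                sse = sse_params(),
                                min_duration_s = 10,
                                max_gap_s = 30,
                                csa_bin_width_pct = 1,
                                min_duration_h = 6,
                                max_artifact_pct = 2.5,
                                force = FALSE) {
  qc <- quality_check(rec, min_duration_h, max_artifact_pct)
  if (!qc$passes) {
    if (!force)
      stop("recording fails quality gate (", paste(qc$reasons, collapse = ", "),
           "); use force = TRUE to analyze anyway", call. = FALSE)
    warning("analyzing recording that fails quality gate (",
            paste(qc$reasons, collapse = ", "), ")", call. = FALSE)
  }
  base <- track_baseline(rec, baseline_cfg)
  ev3 <- detect_desaturations(rec, base, 3, min_duration_s, max_gap_s)
  ev4 <- detect_desaturations(rec, base, 4, min_duration_s, max_gap_s)
  cl <- detect_clusters(ev4)
  mos <- assign_mos(ev4, cl)
  hrs <- valid_hours(rec)
  win <- sleep_window(rec)
  v <- rec$spo2[win][rec$valid[win]]
  out <- structure(list(
    subject_id = rec$subject_id,
    visit = rec$visit,
    duration_h = qc$duration_h,
    artifact_pct = qc$artifact_pct,
    quality_pass = qc$passes,
    mean_spo2 = mean(v),
    sd_spo2 = stats::sd(v),
    odi3 = compute_odi(ev3, hrs),
    odi4 = compute_odi(ev4, hrs),
    mos = mos$score,
    csa = compute_csa(rec, csa_bin_width_pct),
    sse = as.numeric(compute_sse(rec, sse))),
    class = "nox_summary")
  attr(out, "events3") <- ev3
  attr(out, "events4") <- ev4
  attr(out, "clusters") <- cl
  out
}

#' @export
print.nox_summary <- function(x, ...) {
  cat("<nox_summary>", x$subject_id, paste0("(", x$visit, ")"), "\n")
  cat(sprintf("  %.2f h analyzed, %.2f%% artifact (%s)\n", x$duration_h,
              x$artifact_pct, if (x$quality_pass) "pass" else "FAIL"))
  cat(sprintf("  SpO2 %.1f +/- %.2f %%; ODI3 %.2f/h; ODI4 %.2f/h; MOS %d\n",
              x$mean_spo2, x$sd_spo2, x$odi3, x$odi4, x$mos))
  cat(sprintf("  CSA %.1f; SSE %.3f\n", x$csa, x$sse))
  invisible(x)
}

#' One-row data.frame with the standard summary columns
#' @param x A `nox_summary`.
#' @param ... Unused.
#' @export
as.data.frame.nox_summary <- function(x, ...) {
  data.frame(subject_id = x$subject_id, visit = x$visit,
             spo2_mean = x$mean_spo2, spo2_sd = x$sd_spo2,
             odi3 = x$odi3, odi4 = x$odi4, mos = x$mos,
             csa = x$csa, sse = x$sse,
             duration_h = x$duration_h, artifact_pct = x$artifact_pct,
             quality_pass = x$quality_pass)
}
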