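#' Baseline-tracking configuration
#'
#' Desaturation events are drops *from baseline*, but overnight oximetry has
#' no annotated awake baseline, so one is tracked from the signal itself: the
#' rolling maximum (or a high percentile) of valid SpO2 over a trailing
#' window. A trailing maximum follows slow drifts while staying on the
#' stable/awake saturation level through transient dips shorter than the
#' window.
#'
#' @param method `"rolling_max"` (default) or `"rolling_percentile"`.
#' @param window_s Trailing window length in seconds (>= 30; default 120).
#' @param percentile Percentile used by `"rolling_percentile"`, in (50, 100].
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(method = c("rolling_max", "rolling_percentile"),
                            window_s = 120, percentile = 95) {
  method <- match.arg(method)
  if (!is.finite(window_s) || window_s < 30)
    stop("window_s must be at least 30 s", call. = FALSE)
  if (!is.finite(percentile) || percentile <= 50 || percentile > 100)
    stop("percentile must lie in (50, 100]", call. = FALSE)
  structure(list(method = method, window_s = window_s, percentile = percentile),
            class = "baseline_config")
}

#' Track the per-sample SpO2 baseline
#'
#' Computes, for every sample, the rolling maximum (or trailing percentile)
#' of valid SpO2 over the trailing window ending at that sample. Windows with
#' no valid sample carry the last defined baseline forward; leading undefined
#' samples take the first defined value. The result is clamped to \[0, 100\].
#'
#' @param rec An [oximetry_recording()].
#' @param cfg A [baseline_config()].
#' @return Numeric vector, one baseline value per sample.
#' @export
#' @examples
#' rec <- oximetry_recording(rep(97, 300))
#' all(track_baseline(rec) == 97)
track_baseline <- function(rec, cfg = baseline_config()) {
  validate_recording(rec)
  if (!any(rec$valid)) stop("all samples invalid; no baseline defined", call. = FALSE)
  x <- ifelse(rec$valid, rec$spo2, NA_real_)
  n <- length(x)
  w <- max(1L, as.integer(round(cfg$window_s / rec$sample_interval_s)))
  w <- min(w, n)
  if (cfg$method == "rolling_max") {
    xs <- ifelse(is.na(x), -Inf, x)
    # trailing max over w samples via the embedding trick; partial leading
    # windows handled by cummax
    full <- if (n >= w) {
      m <- stats::embed(xs, w)  # row i: xs[(i+w-1):i]
      do.call(pmax, as.data.frame(m))
    } else numeric(0)
    b <- c(cummax(xs[seq_len(min(w - 1L, n))]), full)
    b[!is.finite(b)] <- NA_real_
  } else {
    p <- cfg$percentile / 100
    b <- vapply(seq_len(n), function(i) {
      v <- x[max(1L, i - w + 1L):i]
      v <- v[!is.na(v)]
      if (!length(v)) NA_real_ else as.numeric(stats::quantile(v, p, names = FALSE))
    }, numeric(1))
  }
  # carry forward through all-invalid windows; back-fill the leading run
  if (anyNA(b)) {
    filled <- b
    last <- NA_real_
    for (i in seq_len(n)) {
      if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
    }
    first_def <- which(!is.na(filled))[1]
    if (first_def > 1) filled[seq_len(first_def - 1L)] <- filled[first_def]
    b <- filled
  }
  pmin(pmax(b, 0), 100)
}

#' Detect desaturation events
#'
#' A desaturation event is a maximal run of valid samples whose SpO2 lies at
#' or below `baseline - drop_threshold_pct`, lasting at least
#' `min_duration_s`. With discrete sampling the duration rule means at least
#' `ceiling(min_duration_s / sample_interval_s)` samples (>= 10 s at 4 s
#' resolution requires 3 samples, i.e. 12 s). Short invalid gaps inside a run
#' (at most `max_gap_s`) are bridged; longer gaps split events. Events end at
#' their last below-threshold sample and never overlap.
#'
#' @param rec An [oximetry_recording()].
#' @param baseline Per-sample baseline from [track_baseline()], aligned with
#'   the recording.
#' @param drop_threshold_pct Required drop from baseline, percent (3 for ODI3,
#'   4 for ODI4 and the McGill score).
#' @param min_duration_s Minimum event duration, seconds.
#' @param max_gap_s Longest invalid gap bridged inside an event, seconds.
#' @param min_separation_s Resaturation gap: below-threshold runs separated by
#'   fewer than this span of *valid* above-threshold samples are one event,
#'   since a 1-sample bounce above the threshold inside a desaturation is
#'   sensor noise, not a recovery (invalid samples evidence nothing and do
#'   not count toward the separation). Runs separated by at least this much
#'   recovered signal count as distinct events.
#' @return A data.frame of class `nox_events`, one row per event, with
#'   columns `start_index`, `end_index` (half-open sample indices),
#'   `start_s`, `end_s`, `baseline_spo2` (at onset), `nadir_spo2`,
#'   `depth` (onset baseline minus nadir) and `duration_s`. Ordered,
#'   non-overlapping.
#' @export
detect_desaturations <- function(rec, baseline, drop_threshold_pct,
                                 min_duration_s = 10, max_gap_s = 30,
                                 min_separation_s = 10) {
  validate_recording(rec)
  if (length(baseline) != length(rec$spo2))
    stop("baseline is not aligned with the recording", call. = FALSE)
  if (!is.finite(drop_threshold_pct) || drop_threshold_pct <= 0)
    stop("drop_threshold_pct must be positive", call. = FALSE)
  dt <- rec$sample_interval_s
  win <- sleep_window(rec)
  below <- rec$valid & (rec$spo2 <= baseline - drop_threshold_pct)
  gmax <- max(0L, as.integer(floor(max_gap_s / dt)))
  min_samples <- max(1L, as.integer(ceiling(min_duration_s / dt)))
  sep_n <- max(1L, as.integer(ceiling(min_separation_s / dt)))

  starts <- integer(0); ends <- integer(0)
  in_event <- FALSE; start <- 0L; last_below <- 0L; gap <- 0L
  for (i in win) {
    if (rec$valid[i]) {
      if (below[i]) {
        if (!in_event) { in_event <- TRUE; start <- i }
        last_below <- i
        gap <- 0L
      } else if (in_event) {
        starts <- c(starts, start); ends <- c(ends, last_below)
        in_event <- FALSE
      }
    } else if (in_event) {
      gap <- gap + 1L
      if (gap > gmax) {
        starts <- c(starts, start); ends <- c(ends, last_below)
        in_event <- FALSE; gap <- 0L
      }
    }
  }
  if (in_event) { starts <- c(starts, start); ends <- c(ends, last_below) }

  # resaturation rule: rejoin runs split by a sub-min_separation bounce
  # (never across an invalid stretch longer than max_gap_s)
  if (length(starts) > 1L) {
    ms <- starts[1]; me <- ends[1]
    out_s <- integer(0); out_e <- integer(0)
    for (k in 2:length(starts)) {
      gap_idx <- (me + 1L):(starts[k] - 1L)
      n_invalid <- sum(!rec$valid[gap_idx])
      n_above <- length(gap_idx) - n_invalid  # valid samples evidence recovery
      if (n_above < sep_n && n_invalid <= gmax) {
        me <- ends[k]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- starts[k]; me <- ends[k]
      }
    }
    starts <- c(out_s, ms); ends <- c(out_e, me)
  }

  keep <- (ends - starts + 1L) >= min_samples
  starts <- starts[keep]; ends <- ends[keep]
  nadir <- vapply(seq_along(starts), function(k) {
    idx <- starts[k]:ends[k]
    min(rec$spo2[idx][rec$valid[idx]])
  }, numeric(1))
  ev <- data.frame(
    start_index = starts,
    end_index = ends + 1L,
    start_s = (starts - 1L) * dt,
    end_s = ends * dt,
    baseline_spo2 = baseline[starts],
    nadir_spo2 = nadir,
    depth = baseline[starts] - nadir,
    duration_s = (ends - starts + 1L) * dt)
  class(ev) <- c("nox_events", "data.frame")
  attr(ev, "drop_threshold_pct") <- drop_threshold_pct
  ev
}

#' Oxygen desaturation index
#'
#' Qualifying desaturation events per hour of analyzed (valid) sleep.
#'
#' @param events A `nox_events` data.frame from [detect_desaturations()].
#' @param analyzed_hours Valid analyzed sleep time in hours, e.g. from
#'   [valid_hours()].
#' @return Events per hour.
#' @export
compute_odi <- function(events, analyzed_hours) {
  if (!is.finite(analyzed_hours) || analyzed_hours <= 0)
    stop("analyzed_hours must be positive", call. = FALSE)
  nrow(events) / analyzed_hours
}

#' Find clusters of desaturation events
#'
#' A desaturation cluster is at least `min_events` desaturations within a
#' 10-30 minute study period. Events are grouped greedily left to right:
#' starting from the earliest unassigned event, the group is extended while
#' the span from the first event's onset to the last event's end stays within
#' `window_max_s`; a maximal group with at least `min_events` events becomes a
#' cluster and its events are consumed, otherwise the scan advances one
#' event. Groups tighter than `window_min_s` still count (a denser burst of
#' events is at least as clinically significant); their reported window
#' duration is floored at `window_min_s`.
#'
#' @param events A `nox_events` data.frame, ordered and non-overlapping.
#' @param min_events Minimum events per cluster.
#' @param window_min_s,window_max_s Bounds of the cluster study period,
#'   seconds.
#' @return A data.frame of class `nox_clusters` with `start_index`,
#'   `end_index`, `start_s`, `end_s`, `event_count`, `window_duration_s`.
#' @export
detect_clusters <- function(events, min_events = 5,
                            window_min_s = 600, window_max_s = 1800) {
  out <- list()
  i <- 1L
  n <- nrow(events)
  while (i <= n) {
    j <- i
    while (j + 1L <= n &&
           events$end_s[j + 1L] - events$start_s[i] <= window_max_s) {
      j <- j + 1L
    }
    if (j - i + 1L >= min_events) {
      span <- events$end_s[j] - events$start_s[i]
      out[[length(out) + 1L]] <- data.frame(
        start_index = events$start_index[i],
        end_index = events$end_index[j],
        start_s = events$start_s[i],
        end_s = events$end_s[j],
        event_count = j - i + 1L,
        window_duration_s = max(span, window_min_s))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  cl <- if (length(out)) do.call(rbind, out) else
    data.frame(start_index = integer(0), end_index = integer(0),
               start_s = numeric(0), end_s = numeric(0),
               event_count = integer(0), window_duration_s = numeric(0))
  class(cl) <- c("nox_clusters", "data.frame")
  cl
}

#' Assign the McGill oximetry score
#'
#' Four-level severity score over events detected at the 4% drop threshold:
#' \describe{
#'   \item{1 (inconclusive)}{fewer than 3 clusters, or no qualifying nadir
#'     pattern below.}
#'   \item{2 (mild)}{>= 3 clusters, >= 3 events with nadir < 90% and none
#'     < 85%.}
#'   \item{3 (moderate)}{>= 3 clusters, >= 3 events with nadir < 85% and none
#'     < 80%.}
#'   \item{4 (severe)}{>= 3 clusters and >= 3 events with nadir < 80%.}
#' }
#' Nadir counts are taken over all detected 4% events in the record.
#'
#' @param events4 `nox_events` detected with `drop_threshold_pct = 4`.
#' @param clusters `nox_clusters` computed from `events4`.
#' @return A list of class `nox_mos`: `score` (1-4), `n_clusters`,
#'   `n_below_90`, `n_below_85`, `n_below_80`.
#' @export
assign_mos <- function(events4, clusters) {
  n_clusters <- nrow(clusters)
  nadir <- events4$nadir_spo2
  n90 <- sum(nadir < 90)
  n85 <- sum(nadir < 85)
  n80 <- sum(nadir < 80)
  score <- if (n_clusters >= 3 && n80 >= 3) 4L
  else if (n_clusters >= 3 && n85 >= 3 && n80 == 0) 3L
  else if (n_clusters >= 3 && n90 >= 3 && n85 == 0) 2L
  else 1L
  structure(list(score = score, n_clusters = n_clusters,
                 n_below_90 = n90, n_below_85 = n85, n_below_80 = n80),
            class = "nox_mos")
}

#' @export
print.nox_mos <- function(x, ...) {
  cat(sprintf("<nox_mos> score %d (%d clusters; nadirs <90/<85/<80: %d/%d/%d)\n",
              x$score, x$n_clusters, x$n_below_90, x$n_below_85, x$n_below_80))
  invisible(x)
}

#' Export detected events or clusters as CSV
#'
#' Events are written with columns
#' `start_s, end_s, baseline, nadir, depth, duration_s`; clusters with
#' `start_s, end_s, n_events`.
#'
#' @param x A `nox_events` or `nox_clusters` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(x, path) {
  df <- if (inherits(x, "nox_clusters"))
    data.frame(start_s = x$start_s, end_s = x$end_s, n_events = x$event_count)
  else
    data.frame(start_s = x$start_s, end_s = x$end_s, baseline = x$baseline_spo2,
               nadir = x$nadir_spo2, depth = x$depth, duration_s = x$duration_s)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
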