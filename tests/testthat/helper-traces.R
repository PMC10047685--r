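# Deterministic constructed traces: a flat signal at `baseline` with
# rectangular dips carved in. `dips` is a data.frame with columns
# start_s, duration_s, nadir.
make_trace <- function(duration_h = 6.5, baseline = 97, dips = NULL,
                       sample_interval_s = 4) {
  n <- as.integer(duration_h * 3600 / sample_interval_s)
  x <- rep(baseline, n)
  if (!is.null(dips)) {
    for (k in seq_len(nrow(dips))) {
      i0 <- as.integer(dips$start_s[k] / sample_interval_s) + 1L
      len <- as.integer(ceiling(dips$duration_s[k] / sample_interval_s))
      x[i0:(i0 + len - 1L)] <- dips$nadir[k]
    }
  }
  oximetry_recording(x, sample_interval_s = sample_interval_s)
}

# A burst of `n_events` dips starting at `start_s`, spaced `gap_s` apart.
dip_burst <- function(start_s, n_events, nadirs, duration_s = 20, gap_s = 60) {
  data.frame(start_s = start_s + (seq_len(n_events) - 1) * (duration_s + gap_s),
             duration_s = duration_s,
             nadir = rep_len(nadirs, n_events))
}

mos_trace <- function(kind = c("inconclusive", "mild", "severe")) {
  kind <- match.arg(kind)
  if (kind == "inconclusive") return(make_trace())
  nadirs <- if (kind == "mild") c(88, 92, 92, 92, 92) else c(78, 92, 92, 92, 92)
  # three bursts of 5 events (4% drops from a 97% baseline), ~50 min apart so
  # greedy grouping cannot merge them; one deep event per burst
  dips <- rbind(dip_burst(600, 5, nadirs),
                dip_burst(600 + 3000, 5, nadirs),
                dip_burst(600 + 6000, 5, nadirs))
  make_trace(dips = dips)
}

summarize_pair_frame <- function(cohort, ...) {
  df <- summarize_cohort(cohort, ...)
  df[order(df$visit, df$subject_id), ]
}
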