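#' Configuration for the synthetic overnight-SpO2 generator
#'
#' Defines the generative model behind [generate_recording()]: a slowly
#' drifting baseline plus quantized sensor noise, with desaturation events
#' carved in as trapezoidal dips (one ramp sample down, a full-depth plateau,
#' one ramp sample up) placed by a Poisson process. A configurable fraction
#' of events is concentrated inside periodic REM-like burst windows, which is
#' what produces desaturation clusters. A small fraction of samples is
#' flagged invalid to emulate device-side artifact rejection.
#'
#' Defaults emulate the pre-operative profile of children with
#' adenotonsillar obstruction as reported in overnight-oximetry cohorts:
#' 6-7.4 h recordings at 4 s resolution, baseline near 96.5%, about 17
#' qualifying 3% desaturations per hour, artifact rate well under 1%.
#'
#' @param duration_h Recording duration in hours; `NA` (default) draws
#'   uniformly from \[6, 7.4\].
#' @param sample_interval_s Seconds per sample.
#' @param baseline_spo2 Stable (awake-level) saturation, percent.
#' @param baseline_drift_sd Random-walk drift scale, percent per sqrt(hour).
#' @param noise_sd Sensor noise SD in percent, applied before integer
#'   quantization.
#' @param event_rate_per_h Ground-truth rate of qualifying 3% desaturations.
#' @param depth_min_pct,depth_scale_pct Event depth is
#'   `depth_min_pct + Exp(depth_scale_pct)` percent (shifted exponential).
#' @param plateau_min_s,plateau_scale_s Full-depth plateau duration is
#'   `plateau_min_s + Exp(plateau_scale_s)` seconds; the minimum of 12 s
#'   guarantees each event carries at least 3 below-threshold samples at 4 s
#'   resolution.
#' @param ramp_frac Ramp samples sit at this fraction of the full depth.
#' @param cluster_fraction Fraction of events targeted at burst windows.
#' @param rem_cycle_min Minutes between burst-window centers.
#' @param burst_width_min Burst-window width, minutes.
#' @param artifact_rate Fraction of samples flagged invalid.
#' @param quantize Round the signal to integer percent (device granularity).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(duration_h = NA_real_,
                              sample_interval_s = 4,
                              baseline_spo2 = 96.5,
                              baseline_drift_sd = 0.3,
                              noise_sd = 0.4,
                              event_rate_per_h = 17,
                              depth_min_pct = 3,
                              depth_scale_pct = 2.5,
                              plateau_min_s = 12,
                              plateau_scale_s = 10,
                              ramp_frac = 0.5,
                              cluster_fraction = 0.6,
                              rem_cycle_min = 90,
                              burst_width_min = 10,
                              artifact_rate = 0.004,
                              quantize = TRUE) {
  cfg <- list(duration_h = duration_h, sample_interval_s = sample_interval_s,
              baseline_spo2 = baseline_spo2, baseline_drift_sd = baseline_drift_sd,
              noise_sd = noise_sd, event_rate_per_h = event_rate_per_h,
              depth_min_pct = depth_min_pct, depth_scale_pct = depth_scale_pct,
              plateau_min_s = plateau_min_s, plateau_scale_s = plateau_scale_s,
              ramp_frac = ramp_frac, cluster_fraction = cluster_fraction,
              rem_cycle_min = rem_cycle_min, burst_width_min = burst_width_min,
              artifact_rate = artifact_rate, quantize = quantize)
  with(cfg, {
    stopifnot(sample_interval_s > 0, baseline_spo2 > 70, baseline_spo2 <= 100,
              baseline_drift_sd >= 0, noise_sd >= 0, event_rate_per_h >= 0,
              depth_min_pct >= 3, depth_scale_pct >= 0, plateau_min_s > 0,
              cluster_fraction >= 0, cluster_fraction <= 1,
              artifact_rate >= 0, artifact_rate < 1)
  })
  structure(cfg, class = "simulation_config")
}

#' Generate one synthetic overnight recording with ground truth
#'
#' Draws a recording from the generative model described in
#' [simulation_config()]. Identical `cfg` and `seed` reproduce the output
#' exactly. Events are placed without overlap (with a one-sample guard gap);
#' an event that cannot be placed inside a burst window after exhausting
#' retries falls back to uniform placement, and generation fails only when
#' the total event load cannot be placed at all.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param subject_id,visit Labels stamped on the recording.
#' @return A list with elements `recording` (an [oximetry_recording()]) and
#'   `truth`: a list with `events` (data.frame `start_s`, `end_s`, `depth`,
#'   `in_burst`), `true_rate_per_h`, `burst_windows` (data.frame `start_s`,
#'   `end_s`) and `duration_h`.
#' @export
#' @examples
#' g <- generate_recording(simulation_config(duration_h = 6, event_rate_per_h = 10),
#'                         seed = 1)
#' g$truth$true_rate_per_h
generate_recording <- function(cfg = simulation_config(), seed = NULL,
                               subject_id = NA_character_,
                               visit = c("unknown", "pre", "post")) {
  visit <- match.arg(visit)
  if (!is.null(seed)) set.seed(seed)
  dt <- cfg$sample_interval_s
  dur_h <- if (is.na(cfg$duration_h)) runif(1, 6, 7.4) else cfg$duration_h
  n <- as.integer(round(dur_h * 3600 / dt))
  span_s <- n * dt

  drift <- cumsum(rnorm(n, 0, cfg$baseline_drift_sd * sqrt(dt / 3600)))
  clean <- cfg$baseline_spo2 + drift

  # REM-like burst windows at regular cycle positions
  half_w <- cfg$burst_width_min * 60 / 2
  centers <- seq(cfg$rem_cycle_min * 60, span_s, by = cfg$rem_cycle_min * 60)
  bw <- data.frame(start_s = pmax(0, centers - half_w),
                   end_s = pmin(span_s, centers + half_w))
  bw <- bw[bw$end_s > bw$start_s, , drop = FALSE]

  k <- rpois(1, cfg$event_rate_per_h * dur_h)
  occupied <- logical(n)
  ev_start <- numeric(0); ev_end <- numeric(0); ev_depth <- numeric(0)
  ev_burst <- logical(0)
  depth_prof <- numeric(n)
  for (e in seq_len(k)) {
    depth <- cfg$depth_min_pct +
      if (cfg$depth_scale_pct > 0) rexp(1, 1 / cfg$depth_scale_pct) else 0
    plateau_n <- as.integer(ceiling(
      (cfg$plateau_min_s + if (cfg$plateau_scale_s > 0)
        rexp(1, 1 / cfg$plateau_scale_s) else 0) / dt))
    len <- plateau_n + 2L  # one ramp sample each side
    want_burst <- nrow(bw) > 0 && runif(1) < cfg$cluster_fraction
    placed <- FALSE
    place_at <- function(i0, burst) {
      idx <- i0:(i0 + len - 1L)
      occupied[idx] <<- TRUE
      depth_prof[idx] <<- c(cfg$ramp_frac * depth, rep(depth, plateau_n),
                            cfg$ramp_frac * depth)
      ev_start <<- c(ev_start, (i0 - 1L) * dt)
      ev_end <<- c(ev_end, (i0 + len - 1L) * dt)
      ev_depth <<- c(ev_depth, depth)
      ev_burst <<- c(ev_burst, burst)
    }
    for (mode in (if (want_burst) c("burst", "uniform") else "uniform")) {
      for (try in seq_len(200L)) {
        if (mode == "burst") {
          wsel <- bw[sample.int(nrow(bw), 1), ]
          t0 <- runif(1, wsel$start_s, max(wsel$start_s, wsel$end_s - len * dt))
        } else {
          t0 <- runif(1, 0, span_s - len * dt)
        }
        i0 <- as.integer(floor(t0 / dt)) + 1L
        idx_hi <- i0 + len - 1L
        # events are kept >= 3 samples (12 s) apart: resaturation between
        # distinct desaturations takes at least that long
        guard <- max(1L, i0 - 3L):min(n, idx_hi + 3L)
        if (idx_hi <= n && !any(occupied[guard])) {
          place_at(i0, mode == "burst")
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) {
      # dense recording: random probing failed, so scan the free gaps and
      # drop the event into one chosen at random (guard sample each side)
      runs <- rle(occupied)
      run_end <- cumsum(runs$lengths)
      run_start <- run_end - runs$lengths + 1L
      fit <- which(!runs$values & runs$lengths >= len + 6L)
      if (!length(fit))
        stop("event load exceeds recording capacity: could not place event ",
             e, " of ", k, call. = FALSE)
      r <- fit[sample.int(length(fit), 1)]
      i0 <- run_start[r] + 3L +
        sample.int(runs$lengths[r] - len - 5L, 1) - 1L
      place_at(i0, FALSE)
    }
  }

  x <- clean - depth_prof + rnorm(n, 0, cfg$noise_sd)
  if (cfg$quantize) x <- round(x)
  x <- pmin(pmax(x, 0), 100)
  invalid <- runif(n) < cfg$artifact_rate
  rec <- oximetry_recording(x, sample_interval_s = dt, valid = !invalid,
                            subject_id = subject_id, visit = visit)
  ord <- order(ev_start)
  truth <- list(events = data.frame(start_s = ev_start[ord],
                                    end_s = ev_end[ord],
                                    depth = ev_depth[ord],
                                    in_burst = ev_burst[ord]),
                true_rate_per_h = length(ev_start) / dur_h,
                burst_windows = bw,
                duration_h = dur_h)
  list(recording = rec, truth = truth)
}

#' Per-visit cohort profile for the paired-cohort generator
#'
#' Subject-level parameters are drawn per visit: the stable baseline is
#' normal, the 3% desaturation rate is log-normal (clamped to a plausible
#' range), artifact rate is uniform. `depth_scale_pct` and
#' `cluster_fraction` are shared across the visit's subjects.
#'
#' @param baseline_mean,baseline_sd Baseline SpO2 distribution, percent.
#' @param rate_meanlog,rate_sdlog Log-normal parameters of the event rate.
#' @param rate_min,rate_max Clamp on the drawn event rate, per hour.
#' @param depth_scale_pct Exponential scale of event depth beyond 3%.
#' @param cluster_fraction Fraction of events in burst windows.
#' @param artifact_min,artifact_max Uniform range of the artifact fraction.
#' @return A list of class `cohort_profile`.
#' @export
cohort_profile <- function(baseline_mean, baseline_sd,
                           rate_meanlog, rate_sdlog, rate_min, rate_max,
                           depth_scale_pct, cluster_fraction,
                           artifact_min = 0.001, artifact_max = 0.018) {
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 rate_min = rate_min, rate_max = rate_max,
                 depth_scale_pct = depth_scale_pct,
                 cluster_fraction = cluster_fraction,
                 artifact_min = artifact_min, artifact_max = artifact_max),
            class = "cohort_profile")
}

#' Default pre-operative (obstructed) cohort profile
#' @return A [cohort_profile()].
#' @export
profile_pre <- function() {
  cohort_profile(baseline_mean = 96.5, baseline_sd = 0.7,
                 rate_meanlog = log(15), rate_sdlog = 0.65,
                 rate_min = 3, rate_max = 55,
                 depth_scale_pct = 2.5, cluster_fraction = 0.6)
}

#' Default post-operative (resolved) cohort profile
#' @return A [cohort_profile()].
#' @export
profile_post <- function() {
  cohort_profile(baseline_mean = 98.2, baseline_sd = 0.4,
                 rate_meanlog = log(1.3), rate_sdlog = 0.6,
                 rate_min = 0.2, rate_max = 4.5,
                 depth_scale_pct = 0.7, cluster_fraction = 0.3)
}

#' Generate a paired pre/post synthetic cohort
#'
#' One pre- and one post-operative recording per subject. Pre/post
#' correlation is induced by a shared subject-level offset (SD 0.5%) on the
#' stable baseline of both visits, which makes paired comparisons
#' meaningfully paired.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param pre,post [cohort_profile()]s for the two visits.
#' @param subject_effect_sd SD of the shared per-subject baseline offset.
#' @return A list of class `nox_cohort`: `subjects` (ids), `pre` and `post`
#'   (lists of [generate_recording()] results, one per subject), `profiles`.
#' @export
generate_paired_cohort <- function(n_subjects = 45, seed = NULL,
                                   pre = profile_pre(), post = profile_post(),
                                   subject_effect_sd = 0.5) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%03d", seq_len(n_subjects))
  eff <- rnorm(n_subjects, 0, subject_effect_sd)
  draw <- function(prof, id, offset, visit) {
    base <- min(99.3, max(90, rnorm(1, prof$baseline_mean, prof$baseline_sd) + offset))
    rate <- min(prof$rate_max, max(prof$rate_min,
                                   rlnorm(1, prof$rate_meanlog, prof$rate_sdlog)))
    cfg <- simulation_config(baseline_spo2 = base,
                             event_rate_per_h = rate,
                             depth_scale_pct = prof$depth_scale_pct,
                             cluster_fraction = prof$cluster_fraction,
                             artifact_rate = runif(1, prof$artifact_min,
                                                   prof$artifact_max))
    g <- generate_recording(cfg, seed = NULL, subject_id = id, visit = visit)
    g$config <- cfg
    g
  }
  pre_l <- vector("list", n_subjects)
  post_l <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    pre_l[[i]] <- draw(pre, ids[i], eff[i], "pre")
    post_l[[i]] <- draw(post, ids[i], eff[i], "post")
  }
  structure(list(subjects = ids, pre = pre_l, post = post_l,
                 profiles = list(pre = pre, post = post)),
            class = "nox_cohort")
}

#' Summarize every recording in a cohort
#'
#' Applies [summarize_recording()] to each recording of a paired cohort and
#' stacks the results.
#'
#' @param cohort A `nox_cohort` from [generate_paired_cohort()].
#' @param ... Passed to [summarize_recording()].
#' @param force Analyze recordings that fail the quality gate (simulated
#'   cohorts occasionally draw a duration marginally under the gate).
#' @return A data.frame, one row per recording, with the columns of
#'   [as.data.frame.nox_summary()].
#' @export
summarize_cohort <- function(cohort, ..., force = TRUE) {
  rows <- lapply(c(cohort$pre, cohort$post), function(g) {
    as.data.frame(suppressWarnings(
      summarize_recording(g$recording, ..., force = force)))
  })
  do.call(rbind, rows)
}
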