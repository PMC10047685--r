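#' Full run configuration with package defaults
#'
#' All tunable analysis parameters in one nested list, serializable to YAML
#' or JSON and round-trippable via [write_run_config()] / [read_run_config()].
#' The `reference_cutoffs` entry ships cohort-derived screening cutoffs
#' (ODI3 > 3.6/h, ODI4 > 2.2/h, CSA > 293, SSE > 0.99) as a convenience for
#' reporting; they are labeled reference values, not validated thresholds
#' for new devices or populations.
#'
#' @return A nested list of class `nox_config`.
#' @export
nox_config <- function() {
  structure(list(
    baseline = list(method = "rolling_max", window_s = 120, percentile = 95),
    detection = list(odi3_threshold_pct = 3, odi4_threshold_pct = 4,
                     min_duration_s = 10, max_gap_s = 30),
    clusters = list(min_events = 5, window_min_s = 600, window_max_s = 1800),
    quality = list(min_duration_h = 6, max_artifact_pct = 2.5),
    sse = list(m = 2, r_factor = 0.2, r_floor = 0),
    csa = list(bin_width_pct = 1),
    roc = list(ci_method = "delong", boot_n = 2000),
    reference_cutoffs = list(odi3 = 3.6, odi4 = 2.2, csa = 293, sse = 0.99)),
    class = "nox_config")
}

#' Write a run configuration to YAML or JSON
#' @param config A [nox_config()]-shaped list.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(config), path)
  }
  invisible(path)
}

#' Read a run configuration, filling unset fields with defaults
#' @param path A YAML or JSON file written by [write_run_config()] (or a
#'   subset of its fields).
#' @return A `nox_config` list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  cfg <- nox_config()
  for (sec in intersect(names(raw), names(cfg)))
    for (key in intersect(names(raw[[sec]]), names(cfg[[sec]])))
      cfg[[sec]][[key]] <- raw[[sec]][[key]]
  cfg
}

config_from_nox <- function(config) {
  list(baseline_cfg = baseline_config(config$baseline$method,
                                      config$baseline$window_s,
                                      config$baseline$percentile),
       sse = sse_params(config$sse$m, config$sse$r_factor, config$sse$r_floor),
       min_duration_s = config$detection$min_duration_s,
       max_gap_s = config$detection$max_gap_s,
       csa_bin_width_pct = config$csa$bin_width_pct,
       min_duration_h = config$quality$min_duration_h,
       max_artifact_pct = config$quality$max_artifact_pct)
}

provenance_header <- function(config) {
  c(sprintf("# noxi %s", as.character(utils::packageVersion("noxi"))),
    sprintf("# config: %s",
            jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)))
}

#' Analyze one or more recordings into summary and event tables
#'
#' Runs the single-recording pipeline over a set of recording files.
#' Recordings failing the quality gate abort the run (so a screening
#' decision is never silently based on bad signal) unless `force = TRUE`, in
#' which case they are analyzed and flagged `quality_override` in the
#' summary. When `out_dir` is given, writes `summary.csv` plus per-recording
#' `<name>_events.csv` / `<name>_clusters.csv`, each stamped with the
#' package version and the resolved configuration.
#'
#' @param paths Recording file paths (CSV or EDF).
#' @param config A [nox_config()].
#' @param force Analyze recordings that fail the quality gate.
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `summary` (data.frame, one row per
#'   recording, including a `quality_override` column) and `details` (per
#'   recording, the `nox_summary` with event/cluster attributes).
#' @export
nox_analyze <- function(paths, config = nox_config(), force = FALSE,
                        out_dir = NULL) {
  args <- config_from_nox(config)
  details <- list()
  rows <- list()
  for (p in paths) {
    rec <- read_recording(p)
    qc <- quality_check(rec, args$min_duration_h, args$max_artifact_pct)
    if (!qc$passes && !force)
      stop("'", p, "' fails quality gate: ",
           paste(qc$reasons, collapse = ", "), call. = FALSE)
    s <- suppressWarnings(do.call(summarize_recording,
                                  c(list(rec = rec, force = TRUE), args)))
    s$subject_id <- if (is.na(s$subject_id))
      sub("\\.[^.]*$", "", basename(p)) else s$subject_id
    row <- as.data.frame(s)
    row$quality_override <- !qc$passes
    row$path <- p
    rows[[p]] <- row
    details[[p]] <- s
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- provenance_header(config)
    write_with_header <- function(df, path) {
      con <- file(path, "w")
      writeLines(hdr, con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    write_with_header(summary, file.path(out_dir, "summary.csv"))
    for (p in names(details)) {
      stem <- sub("\\.[^.]*$", "", basename(p))
      write_events_csv(attr(details[[p]], "events3"),
                       file.path(out_dir, paste0(stem, "_events.csv")))
      write_events_csv(attr(details[[p]], "clusters"),
                       file.path(out_dir, paste0(stem, "_clusters.csv")))
    }
  }
  invisible(list(summary = summary, details = details))
}

#' Paired-cohort evaluation: Wilcoxon, ROC/Youden, Spearman
#'
#' Takes a per-recording summary table with complete pre/post pairs and
#' produces, for each index (mean SpO2, SD SpO2, ODI3, ODI4, MOS, CSA, SSE):
#' the paired Wilcoxon signed-rank test of the pre/post change, and an ROC
#' analysis treating pre-operative recordings as the condition-positive
#' class and post-operative recordings as normal controls (ignoring the
#' pairing, as is conventional for this design). Also returns the Spearman
#' correlation matrix of the pre-visit indices.
#'
#' @param summary A data.frame as produced by [summarize_cohort()] or
#'   [nox_analyze()], with columns `subject_id`, `visit` (`"pre"`/`"post"`)
#'   and the index columns.
#' @param config A [nox_config()] (ROC options are read from it).
#' @param seed Seed applied before any bootstrap CI (ignored for DeLong).
#' @param out_dir Optional directory for `evaluation_roc.csv`,
#'   `evaluation_wilcoxon.csv` and `evaluation_spearman.csv`.
#' @return A list of class `nox_evaluation`: `wilcoxon` (data.frame),
#'   `roc` (data.frame with columns
#'   `parameter, auc, ci_low, ci_high, cutoff, se_pct, sp_pct`),
#'   `spearman` (matrix), `n_subjects`.
#' @export
nox_evaluate <- function(summary, config = nox_config(), seed = NULL,
                         out_dir = NULL) {
  pre <- summary[summary$visit == "pre", ]
  post <- summary[summary$visit == "post", ]
  missing_pre <- setdiff(post$subject_id, pre$subject_id)
  missing_post <- setdiff(pre$subject_id, post$subject_id)
  if (length(missing_pre) || length(missing_post))
    stop("incomplete pre/post pairs for subject(s): ",
         paste(unique(c(missing_pre, missing_post)), collapse = ", "),
         call. = FALSE)
  if (nrow(pre) < 2) stop("need at least 2 paired subjects", call. = FALSE)
  pre <- pre[order(pre$subject_id), ]
  post <- post[order(post$subject_id), ]

  idx <- c(spo2_mean = "less_is_positive", spo2_sd = "greater_is_positive",
           odi3 = "greater_is_positive", odi4 = "greater_is_positive",
           mos = "greater_is_positive", csa = "greater_is_positive",
           sse = "greater_is_positive")
  if (!is.null(seed)) set.seed(seed)
  wil <- list(); roc <- list()
  for (name in names(idx)) {
    w <- wilcoxon_paired(pre[[name]], post[[name]])
    wil[[name]] <- data.frame(parameter = name, statistic = w$statistic,
                              p_value = w$p_value, n_effective = w$n_effective)
    r <- roc_with_youden(c(pre[[name]], post[[name]]),
                         rep(c(TRUE, FALSE), c(nrow(pre), nrow(post))),
                         direction = idx[[name]],
                         ci_method = config$roc$ci_method,
                         boot_n = config$roc$boot_n)
    roc[[name]] <- data.frame(parameter = name, auc = r$auc,
                              ci_low = r$ci_low, ci_high = r$ci_high,
                              cutoff = r$cutoff, se_pct = r$sensitivity_pct,
                              sp_pct = r$specificity_pct)
  }
  sp <- if (nrow(pre) >= 3) spearman_matrix(pre[, names(idx)]) else {
    warning("fewer than 3 subjects: Spearman matrix not estimable",
            call. = FALSE)
    matrix(NA_real_, length(idx), length(idx),
           dimnames = list(names(idx), names(idx)))
  }
  out <- structure(list(wilcoxon = do.call(rbind, wil),
                        roc = do.call(rbind, roc),
                        spearman = sp,
                        n_subjects = nrow(pre)),
                   class = "nox_evaluation")
  rownames(out$wilcoxon) <- rownames(out$roc) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$roc, file.path(out_dir, "evaluation_roc.csv"),
                     row.names = FALSE)
    utils::write.csv(out$wilcoxon,
                     file.path(out_dir, "evaluation_wilcoxon.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(sp),
                     file.path(out_dir, "evaluation_spearman.csv"))
  }
  out
}

#' @export
print.nox_evaluation <- function(x, ...) {
  cat("<nox_evaluation>", x$n_subjects, "paired subjects\n")
  cat("Wilcoxon (pre vs post):\n")
  print(x$wilcoxon, row.names = FALSE)
  cat("ROC (pre = positive class):\n")
  print(x$roc, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulate a paired cohort to disk
#'
#' Writes one CSV recording per subject and visit in the package CSV
#' dialect, a ground-truth JSON next to each recording, and a manifest
#' (`manifest.csv`: `subject_id, visit, path, seed`). Re-running with the
#' same arguments reproduces the files byte for byte.
#'
#' @param n_subjects Number of subjects.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param pre,post [cohort_profile()]s.
#' @return Invisibly, the manifest data.frame.
#' @export
nox_simulate <- function(n_subjects = 45, out_dir, seed = 1,
                         pre = profile_pre(), post = profile_post()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_paired_cohort(n_subjects, seed = seed, pre = pre,
                                   post = post)
  rows <- list()
  for (visit in c("pre", "post")) {
    for (i in seq_along(cohort$subjects)) {
      g <- cohort[[visit]][[i]]
      stem <- paste0(cohort$subjects[i], "_", visit)
      path <- file.path(out_dir, paste0(stem, ".csv"))
      write_recording(g$recording, path)
      jsonlite::write_json(
        list(events = g$truth$events,
             true_rate_per_h = g$truth$true_rate_per_h,
             burst_windows = g$truth$burst_windows,
             duration_h = g$truth$duration_h),
        file.path(out_dir, paste0(stem, "_truth.json")),
        auto_unbox = TRUE, digits = NA)
      rows[[stem]] <- data.frame(subject_id = cohort$subjects[i],
                                 visit = visit, path = path, seed = seed)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
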