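#' Extract a metric value at a protocol timepoint
#'
#' Protocol metrics are recorded continuously but reported at discrete
#' timepoints.  Two extraction rules are provided:
#' \describe{
#'   \item{`window_ending_at` (default)}{the RMS value of the last complete
#'     window ending at or before `t` --- for a timepoint aligned to the
#'     window grid, exactly the window that closes at the timepoint.  A step
#'     occurring exactly at `t` therefore does not contaminate the extracted
#'     value.}
#'   \item{`mean_of_k_windows`}{the mean of the `k` complete windows ending
#'     at or before `t` (default `k = 2`).}
#' }
#'
#' @param series an `rms_series`.
#' @param t timepoint in seconds on the recording clock.
#' @param rule extraction rule (see above).
#' @param k number of windows for `mean_of_k_windows`.
#' @return extracted value.
#' @export
extract_at_timepoint <- function(series, t,
                                 rule = c("window_ending_at",
                                          "mean_of_k_windows"),
                                 k = 2L) {
  stopifnot(inherits(series, "rms_series"))
  rule <- match.arg(rule)
  w <- series$window_s
  starts <- series$window_start_s
  eps <- 1e-9
  if (rule == "window_ending_at") {
    cand <- which(starts + w <= t + eps)
    if (!length(cand)) stop("timepoint ", t, " s precedes the first complete window")
    series$values[max(cand)]
  } else {
    cand <- which(starts + w <= t + eps)
    if (!length(cand)) stop("timepoint ", t, " s precedes the first complete window")
    mean(series$values[tail(cand, k)])
  }
}

# Mean of an aux channel over (t - window_s, t].
.aux_at_timepoint <- function(ch, t, window_s, fs) {
  if (is.data.frame(ch)) {
    sel <- ch$time_s > t - window_s & ch$time_s <= t
    if (!any(sel)) return(NA_real_)
    mean(ch$value[sel])
  } else {
    idx <- which((seq_along(ch) - 1) / fs > t - window_s &
                   (seq_along(ch) - 1) / fs <= t)
    if (!length(idx)) return(NA_real_)
    mean(ch[idx])
  }
}

#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort from `sim`) or
#'   `"manifest"` (ingest recordings listed in a manifest file).
#' @param sim a [sim_config] (simulate mode).
#' @param manifest path to a manifest CSV or a `cohort_manifest`
#'   (manifest mode).
#' @param bandpass a [bandpass_spec].
#' @param window_s RMS window (default 30 s).
#' @param order pipeline order, `"norm_first"` or `"filter_first"`.
#' @param rule timepoint extraction rule (see [extract_at_timepoint()]).
#' @param threshold_frac fractional detection threshold for
#'   [detection_lead_time()] (applied to both series).
#' @param out_dir output directory, or `NULL` for in-memory results only.
#' @param seed overrides the simulator seed when not `NULL`.
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "manifest"),
                       sim = sim_config(), manifest = NULL,
                       bandpass = bandpass_spec(), window_s = 30,
                       order = c("norm_first", "filter_first"),
                       rule = c("window_ending_at", "mean_of_k_windows"),
                       threshold_frac = 0.03,
                       out_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  rule <- match.arg(rule)
  if (mode == "manifest" && is.null(manifest))
    stop("manifest mode requires a manifest")
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(mode = mode, sim = sim, manifest = manifest,
                 bandpass = bandpass, window_s = window_s, order = order,
                 rule = rule, threshold_frac = threshold_frac,
                 out_dir = out_dir),
            class = "run_config")
}

# Deterministic short fingerprint of a configuration (no external digest
# dependency; weighted byte checksum of the canonical serialization).
.fingerprint <- function(x) {
  x$out_dir <- NULL
  bytes <- as.integer(serialize(x, NULL, version = 2))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 97 + 1)) %% 2147483647)
}

# Map timeline labels to (block, phase, extraction time).
.report_timepoints <- function(tl, duration_s) {
  ph <- timeline_phases(tl, duration_s)
  tp <- NULL
  add <- function(block, phase, t_s)
    rbind(tp, data.frame(block = block, phase = phase, t_s = t_s))
  for (i in seq_len(nrow(ph))) {
    lab <- ph$label[i]
    if (lab == "baseline_start") tp <- add("pump_speed", "baseline", ph$end_s[i])
    else if (lab == "pump_medium") tp <- add("pump_speed", "medium", ph$end_s[i])
    else if (lab == "pump_high") tp <- add("pump_speed", "high", ph$end_s[i])
    else if (lab == "reversal_baseline") tp <- add("reversal", "baseline", ph$end_s[i])
    else if (lab %in% c("t15", "t30", "t60")) tp <- add("reversal", lab, ph$start_s[i])
  }
  tp
}

#' Run the full pipeline on a cohort
#'
#' Simulates (or ingests) a cohort, runs the vibration signal chain on every
#' subject, extracts all metrics at the protocol timepoints, builds the
#' per-block cohort summaries (pump-speed block and anticoagulation-reversal
#' block, each against its own baseline), and --- when the reversal phase
#' and a pressure channel are present --- the vibration-versus-pressure
#' detection lead times.  Deterministic given the configuration and seed.
#'
#' @param config a [run_config].
#' @return object of class `oxyvib_run`: list with `metrics` (tidy metric
#'   table: subject, metric, block, phase, value), `summary` (named list of
#'   `cohort_summary`, one per block), `leadtime` (data.frame, one row per
#'   subject, or `NULL`), `rms` (per-subject `rms_series`), `truth`
#'   (simulation ground truth, or `NULL`), `fingerprint` and `config`.
#'   With `config$out_dir` set, also writes `metrics.csv`, `summary.csv`,
#'   `summary.txt`, `leadtime.csv`, `ground_truth.txt` (simulate mode) and
#'   `run.log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fp <- .fingerprint(config)
  log_lines <- sprintf("[%s] run %s: mode=%s order=%s window=%gs",
                       format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), fp,
                       config$mode, config$order, config$window_s)

  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$sim)
    subjects <- lapply(cohort$subjects, function(s)
      list(recording = s$recording, timeline = s$timeline))
    truth <- cohort$truth
  } else {
    man <- if (inherits(config$manifest, "cohort_manifest")) config$manifest
    else read_manifest(config$manifest)
    subjects <- lapply(seq_len(man$n_subjects), function(i) {
      e <- man$entries[i, ]
      list(recording = read_recording(e$recording_path,
                                      subject_id = e$subject_id),
           timeline = read_timeline(e$timeline_path))
    })
    truth <- NULL
  }

  metrics <- NULL
  rms_list <- list()
  lead_rows <- NULL
  for (s in subjects) {
    rec <- s$recording
    rs <- process_recording(rec, config$bandpass, config$window_s,
                            config$order)
    rms_list[[rec$subject_id]] <- rs
    tp <- .report_timepoints(s$timeline, rec$duration_s)
    if (is.null(tp))
      stop("no recognized protocol timepoints for subject ", rec$subject_id)
    for (i in seq_len(nrow(tp))) {
      vals <- c(rms_oxy = extract_at_timepoint(rs, tp$t_s[i], config$rule))
      for (nm in names(rec$aux))
        vals[nm] <- .aux_at_timepoint(rec$aux[[nm]], tp$t_s[i],
                                      config$window_s, rec$sampling_rate_hz)
      metrics <- rbind(metrics,
                       data.frame(subject = rec$subject_id,
                                  metric = names(vals),
                                  block = tp$block[i], phase = tp$phase[i],
                                  value = unname(vals)))
    }
    rev_t <- event_time(s$timeline, "reversal")
    if (!is.na(rev_t) && "delta_p_oxy" %in% names(rec$aux)) {
      base_from <- event_time(s$timeline, "reversal_baseline")
      if (is.na(base_from)) base_from <- 0
      lt <- detection_lead_time(rs, rec$aux$delta_p_oxy, rev_t,
                                threshold_frac = config$threshold_frac,
                                baseline_from_s = base_from)
      lead_rows <- rbind(lead_rows,
                         data.frame(subject = rec$subject_id,
                                    t_rms_cross = lt$t_rms_cross,
                                    t_dp_cross = lt$t_dp_cross,
                                    lead_s = lt$lead_s,
                                    crossed_rms = lt$crossed_rms,
                                    crossed_dp = lt$crossed_dp))
    }
    log_lines <- c(log_lines,
                   sprintf("[%s] run %s: subject %s -> %d windows",
                           format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), fp,
                           rec$subject_id, rs$n_windows))
  }
  rownames(metrics) <- NULL

  summaries <- list()
  for (bl in unique(metrics$block)) {
    sub <- metrics[metrics$block == bl, c("subject", "metric", "phase", "value")]
    summaries[[bl]] <- summarize_cohort(sub, baseline = "baseline",
                                        phases = unique(sub$phase))
  }

  out <- structure(list(metrics = metrics, summary = summaries,
                        leadtime = lead_rows, rms = rms_list, truth = truth,
                        fingerprint = fp, config = config),
                   class = "oxyvib_run")
  if (!is.null(config$out_dir)) .write_run(out, config$out_dir, log_lines)
  out
}

.write_run <- function(run, dir, log_lines) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- run$fingerprint
  with_id <- function(df) { df$run_id <- fp; df }
  data.table::fwrite(with_id(run$metrics), file.path(dir, "metrics.csv"))
  all_sum <- do.call(rbind, lapply(names(run$summary), function(bl) {
    df <- as.data.frame(run$summary[[bl]]); df$block <- bl; df
  }))
  data.table::fwrite(with_id(all_sum), file.path(dir, "summary.csv"))
  txt <- unlist(lapply(names(run$summary), function(bl)
    c(sprintf("== %s block ==", bl), format_cohort_summary(run$summary[[bl]]), "")))
  writeLines(c(sprintf("run %s", fp), "", txt), file.path(dir, "summary.txt"))
  if (!is.null(run$leadtime))
    data.table::fwrite(with_id(run$leadtime), file.path(dir, "leadtime.csv"))
  if (!is.null(run$truth))
    yaml::write_yaml(c(list(run_id = fp), run$truth),
                     file.path(dir, "ground_truth.txt"))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.oxyvib_run <- function(x, ...) {
  cat(sprintf("<oxyvib_run %s: %d subjects, %d metric rows>\n",
              x$fingerprint, length(x$rms), nrow(x$metrics)))
  for (bl in names(x$summary)) {
    cat(sprintf("\n== %s block ==\n", bl))
    print(x$summary[[bl]])
  }
  if (!is.null(x$leadtime)) {
    cat("\nDetection lead (pressure crossing minus vibration crossing):\n")
    print(x$leadtime, row.names = FALSE)
  }
  invisible(x)
}
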