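#' Construct a protocol timeline
#'
#' A timeline is an ordered set of labeled events on the recording clock
#' (seconds from recording start, 0-based).  Consecutive events delimit
#' half-open phases `[event_i, event_{i+1})`; the last phase is open-ended
#' until the recording end.  Canonical labels for the two-phase protocol are
#' `baseline_start`, `pump_medium`, `pump_high`, `reversal`, `t15`, `t30`,
#' `t60`, `end`, but free-text labels are allowed.
#'
#' @param time_s numeric vector of event times (strictly increasing, >= 0).
#' @param label character vector of event labels, same length.
#' @return An object of class `protocol_timeline`.
#' @examples
#' tl <- protocol_timeline(c(0, 600, 1200), c("baseline_start", "pump_medium", "pump_high"))
#' timeline_phases(tl, duration_s = 1800)
#' @export
protocol_timeline <- function(time_s, label) {
  time_s <- as.numeric(time_s)
  label <- as.character(label)
  if (length(time_s) == 0L) stop("timeline must contain at least one event")
  if (length(time_s) != length(label))
    stop("time_s and label must have equal length")
  if (any(time_s < 0)) stop("event times must be >= 0")
  if (any(diff(time_s) <= 0)) stop("non-increasing event times")
  structure(list(time_s = time_s, label = label), class = "protocol_timeline")
}

#' @export
print.protocol_timeline <- function(x, ...) {
  cat("<protocol_timeline>\n")
  for (i in seq_along(x$time_s))
    cat(sprintf("  %8.1f s  %s\n", x$time_s[i], x$label[i]))
  invisible(x)
}

#' Phase intervals delimited by timeline events
#'
#' @param tl a [protocol_timeline].
#' @param duration_s recording duration closing the final phase.  All event
#'   times must lie within `[0, duration_s]`.
#' @return data.frame with columns `label`, `start_s`, `end_s`; intervals are
#'   half-open `[start_s, end_s)`.
#' @export
timeline_phases <- function(tl, duration_s) {
  stopifnot(inherits(tl, "protocol_timeline"))
  # small relative slack: durations re-derived from a file's inferred
  # sampling rate can be off by a few ulps
  if (any(tl$time_s > duration_s * (1 + 1e-9) + 1e-9))
    stop("event times exceed recording duration")
  data.frame(label = tl$label,
             start_s = tl$time_s,
             end_s = c(tl$time_s[-1], duration_s))
}

#' Time of a labeled event
#'
#' @param tl a [protocol_timeline].
#' @param label event label to look up (first match).
#' @return event time in seconds, or `NA_real_` if absent.
#' @export
event_time <- function(tl, label) {
  i <- match(label, tl$label)
  if (is.na(i)) NA_real_ else tl$time_s[i]
}

#' Read / write a protocol timeline CSV
#'
#' Two-column comma-separated text with header `time_s,label`.
#'
#' @param path CSV path.
#' @return [read_timeline()]: a [protocol_timeline]; [write_timeline()]:
#'   `path`, invisibly.
#' @export
read_timeline <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE)
  if (nrow(dt) == 0L) stop("empty timeline file")
  if (!all(c("time_s", "label") %in% names(dt)))
    stop("timeline file needs columns time_s, label")
  protocol_timeline(dt[["time_s"]], dt[["label"]])
}

#' @rdname read_timeline
#' @param tl a [protocol_timeline].
#' @export
write_timeline <- function(tl, path) {
  stopifnot(inherits(tl, "protocol_timeline"))
  .fwrite_lossless(data.table::data.table(time_s = tl$time_s,
                                          label = tl$label), path)
  invisible(path)
}

#' Construct / read / write a cohort manifest
#'
#' A manifest lists the per-subject recording and timeline files of a cohort.
#'
#' @param subject_id character vector of unique subject labels.
#' @param recording_path,timeline_path file paths, same length.
#' @return an object of class `cohort_manifest`.
#' @export
cohort_manifest <- function(subject_id, recording_path, timeline_path) {
  subject_id <- as.character(subject_id)
  if (length(subject_id) < 1L) stop("manifest needs at least one subject")
  if (anyDuplicated(subject_id)) stop("subject_ids must be unique")
  if (length(recording_path) != length(subject_id) ||
      length(timeline_path) != length(subject_id))
    stop("manifest columns must have equal length")
  structure(list(entries = data.frame(subject_id = subject_id,
                                      recording_path = as.character(recording_path),
                                      timeline_path = as.character(timeline_path)),
                 n_subjects = length(subject_id)),
            class = "cohort_manifest")
}

#' @rdname cohort_manifest
#' @param path manifest CSV path (columns `subject_id`, `recording_path`,
#'   `timeline_path`; relative paths resolved against the manifest directory).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE)
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  cohort_manifest(dt[["subject_id"]],
                  resolve(dt[["recording_path"]]),
                  resolve(dt[["timeline_path"]]))
}

#' @rdname cohort_manifest
#' @param manifest a `cohort_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  data.table::fwrite(data.table::as.data.table(manifest$entries), path, sep = ",")
  invisible(path)
}
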