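#' Construct a triaxial accelerometer recording
#'
#' A recording holds three orthogonal acceleration channels sampled uniformly
#' at `sampling_rate_hz`, plus optional auxiliary channels on the same clock.
#' Acceleration is in g (multiples of standard gravity).  Auxiliary channels
#' are either *full-rate* (a numeric vector the same length as the axes) or
#' *sparse* (a `data.frame` with columns `time_s`, `value` --- e.g. 1-Hz trend
#' channels exported by a patient monitor).
#'
#' @param sampling_rate_hz positive sampling rate in samples/s.  Must exceed
#'   twice the upper bandpass cutoff that will be used downstream (Nyquist).
#' @param gx,gy,gz numeric vectors of equal length (acceleration in g).
#' @param aux named list of auxiliary channels (full-rate numeric vectors or
#'   sparse `data.frame(time_s, value)`).  Canonical names include
#'   `delta_p_oxy` (mmHg), `ecmo_flow` (L/min), `heart_rate` (bpm),
#'   `map`, `cvp`, `mpap` (mmHg), `spo2` (%), `act_s` (s).
#' @param subject_id subject label.
#' @return An object of class `accel_recording` with derived field
#'   `duration_s = n_samples / sampling_rate_hz`.
#' @examples
#' rec <- accel_recording(1000, sin(1:100), cos(1:100), numeric(100))
#' rec$duration_s
#' @export
accel_recording <- function(sampling_rate_hz, gx, gy, gz,
                            aux = list(), subject_id = "subject") {
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive finite scalar")
  gx <- as.numeric(gx); gy <- as.numeric(gy); gz <- as.numeric(gz)
  n <- length(gx)
  if (n < 1L) stop("axes must contain at least one sample")
  if (length(gy) != n || length(gz) != n)
    stop("inconsistent channel lengths: gx, gy, gz must have identical length")
  if (length(aux)) {
    if (is.null(names(aux)) || any(!nzchar(names(aux))))
      stop("aux channels must be named")
    for (nm in names(aux)) {
      ch <- aux[[nm]]
      if (is.data.frame(ch)) {
        if (!all(c("time_s", "value") %in% names(ch)))
          stop("sparse aux channel '", nm, "' needs columns time_s, value")
      } else if (is.numeric(ch)) {
        if (length(ch) != n)
          stop("full-rate aux channel '", nm, "' must match axis length ",
               n, " (or be a sparse data.frame)")
      } else stop("aux channel '", nm, "' must be numeric or a data.frame")
    }
  }
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 gx = gx, gy = gy, gz = gz,
                 aux = aux,
                 subject_id = as.character(subject_id),
                 n_samples = n,
                 duration_s = n / sampling_rate_hz),
            class = "accel_recording")
}

#' @export
print.accel_recording <- function(x, ...) {
  cat(sprintf("<accel_recording '%s': %d samples @ %g Hz (%.1f s)>\n",
              x$subject_id, x$n_samples, x$sampling_rate_hz, x$duration_s))
  if (length(x$aux)) {
    kinds <- vapply(x$aux, function(ch)
      if (is.data.frame(ch)) sprintf("sparse[%d]", nrow(ch)) else "full-rate",
      character(1))
    cat("  aux:", paste(sprintf("%s (%s)", names(x$aux), kinds),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

# Lossless CSV writer: doubles rendered with 17 significant digits so a
# write/read round trip is the identity.
.fwrite_lossless <- function(dt, path) {
  for (cl in names(dt))
    if (is.double(dt[[cl]])) dt[[cl]] <- sprintf("%.17g", dt[[cl]])
  data.table::fwrite(dt, path, sep = ",", dec = ".", quote = FALSE)
}

# Column naming used in the on-disk CSV dialect, by canonical channel name.
.aux_col_names <- c(delta_p_oxy = "delta_p_oxy_mmHg", ecmo_flow = "ecmo_flow_lpm",
                    heart_rate = "heart_rate_bpm", map = "map_mmHg",
                    cvp = "cvp_mmHg", mpap = "mpap_mmHg", spo2 = "spo2_pct",
                    act_s = "act_s")

.aux_to_col <- function(nm) if (nm %in% names(.aux_col_names)) .aux_col_names[[nm]] else nm
.col_to_aux <- function(col) {
  hit <- names(.aux_col_names)[match(col, .aux_col_names)]
  if (is.na(hit)) col else hit
}

#' Read an accelerometer recording from CSV
#'
#' The on-disk dialect is comma-separated UTF-8 with one header row and a
#' period decimal separator.  Required columns: `time_s`, `gx_g`, `gy_g`,
#' `gz_g`; further columns are taken as full-rate auxiliary channels.  Sparse
#' auxiliary channels live in a sidecar file `<stem>_sparse.csv` with columns
#' `time_s`, `channel`, `value`, read automatically when present.
#'
#' @param path path to the recording CSV.
#' @param sampling_rate_hz optional explicit rate; if `NULL` the rate is
#'   inferred from the `time_s` column (total span divided by the number of
#'   intervals, after a uniformity check against the median interval).
#'   Sampling is required to be uniform: any interval deviating from the
#'   median by more than `irregular_tol` (relative) is an error, because the
#'   downstream DSP assumes a uniform grid.
#' @param subject_id subject label; defaults to the file stem.
#' @param irregular_tol relative tolerance on inter-sample intervals
#'   (default 0.01).
#' @return an [accel_recording].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, sampling_rate_hz = NULL, subject_id = NULL,
                           irregular_tol = 0.01) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                          data.table = TRUE)
  req <- c("time_s", "gx_g", "gy_g", "gz_g")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("missing required column: ", paste(miss, collapse = ", "))
  tt <- dt[["time_s"]]
  if (length(tt) >= 2L) {
    dts <- diff(tt)
    if (any(dts <= 0)) stop("non-monotone time column")
    med <- stats::median(dts)
    if (any(abs(dts - med) > irregular_tol * med))
      stop("irregular sampling: inter-sample intervals deviate from the ",
           "median by more than ", irregular_tol * 100, "%")
    # after the uniformity check, the full span gives the rate with far
    # better relative precision than any single interval
    fs <- if (is.null(sampling_rate_hz))
      (length(tt) - 1) / (tt[length(tt)] - tt[1]) else sampling_rate_hz
  } else {
    if (is.null(sampling_rate_hz))
      stop("cannot infer sampling rate from a single sample; ",
           "supply sampling_rate_hz")
    fs <- sampling_rate_hz
  }
  aux_cols <- setdiff(names(dt), req)
  aux <- stats::setNames(lapply(aux_cols, function(cl) as.numeric(dt[[cl]])),
                         vapply(aux_cols, .col_to_aux, character(1)))
  sparse_path <- .sparse_sidecar(path)
  if (file.exists(sparse_path)) {
    sp <- data.table::fread(sparse_path, sep = ",", dec = ".", header = TRUE)
    for (nm in unique(sp[["channel"]])) {
      sub <- sp[sp[["channel"]] == nm, ]
      aux[[.col_to_aux(nm)]] <- data.frame(time_s = sub[["time_s"]],
                                           value = sub[["value"]])
    }
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  accel_recording(fs, dt[["gx_g"]], dt[["gy_g"]], dt[["gz_g"]],
                  aux = aux, subject_id = subject_id)
}

.sparse_sidecar <- function(path)
  paste0(sub("\\.[^.]*$", "", path), "_sparse.csv")

#' Write an accelerometer recording to CSV
#'
#' Writes one row per sample with deterministic column order (`time_s`,
#' `gx_g`, `gy_g`, `gz_g`, then full-rate aux channels in their stored order)
#' at full double precision, so that a write/read round trip is the identity.
#' Sparse aux channels go to the `<stem>_sparse.csv` sidecar.
#'
#' @param rec an [accel_recording].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "accel_recording"))
  n <- rec$n_samples
  dt <- data.table::data.table(
    time_s = (seq_len(n) - 1L) / rec$sampling_rate_hz,
    gx_g = rec$gx, gy_g = rec$gy, gz_g = rec$gz)
  sparse <- list()
  for (nm in names(rec$aux)) {
    ch <- rec$aux[[nm]]
    if (is.data.frame(ch)) sparse[[nm]] <- ch
    else dt[[.aux_to_col(nm)]] <- ch
  }
  .fwrite_lossless(dt, path)
  if (length(sparse)) {
    sp <- data.table::rbindlist(lapply(names(sparse), function(nm)
      data.table::data.table(time_s = sparse[[nm]]$time_s,
                             channel = .aux_to_col(nm),
                             value = sparse[[nm]]$value)))
    .fwrite_lossless(sp, .sparse_sidecar(path))
  }
  invisible(path)
}
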