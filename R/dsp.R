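#' Bandpass specification
#'
#' Frequency-domain brick-wall bandpass: Fourier coefficients whose associated
#' frequency lies outside `[f_lo_hz, f_hi_hz]` are zeroed.  Defaults retain
#' 10--375 Hz, the band carrying pump harmonics and flow-related broadband
#' vibration while excluding DC/posture drift and the region near Nyquist.
#'
#' @param f_lo_hz lower cutoff in Hz (default 10; must be > 0, so the DC term
#'   is always removed).
#' @param f_hi_hz upper cutoff in Hz (default 375; must be below the Nyquist
#'   frequency of the signal it is applied to).
#' @param edge_inclusive if `TRUE` (default) a coefficient at exactly
#'   `f_lo_hz` or `f_hi_hz` is retained.
#' @return object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(f_lo_hz = 10, f_hi_hz = 375, edge_inclusive = TRUE) {
  if (!(f_lo_hz > 0 && f_hi_hz > f_lo_hz))
    stop("require 0 < f_lo_hz < f_hi_hz")
  structure(list(f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz,
                 edge_inclusive = isTRUE(edge_inclusive)),
            class = "bandpass_spec")
}

#' Omnidirectional acceleration norm
#'
#' Elementwise Euclidean norm \eqn{\sqrt{g_x^2 + g_y^2 + g_z^2}} of the three
#' axis signals: a single orientation-independent magnitude channel.
#'
#' @param gx,gy,gz equal-length numeric vectors (g units).
#' @return numeric vector of the same length, all values >= 0.
#' @export
vector_norm <- function(gx, gy, gz) {
  n <- length(gx)
  if (length(gy) != n || length(gz) != n)
    stop("length mismatch: gx, gy, gz must have identical length")
  sqrt(gx^2 + gy^2 + gz^2)
}

#' Frequency-domain brick-wall bandpass filter
#'
#' Transforms `x` with the FFT, zeroes every coefficient whose frequency
#' \eqn{|f|} lies outside the passband, and inverse-transforms with
#' conjugate-symmetric reconstruction so the output is purely real.  Bin `k`
#' (0-based, `k <= n/2`) is associated with frequency `k * fs / n`; mirrored
#' bins follow their conjugate partner, which keeps the mask symmetric.  With
#' `f_lo > 0` the DC bin is always removed, and the precondition
#' `f_hi < fs/2` guarantees the Nyquist bin is too.
#'
#' @param x real-valued sample vector (length >= 2).
#' @param fs sampling rate in Hz; must satisfy `fs/2 > spec$f_hi_hz`.
#' @param spec a [bandpass_spec].
#' @return real numeric vector, same length as `x`.
#' @examples
#' fs <- 1000; t <- (0:999) / fs
#' x <- sin(2 * pi * 50 * t) + sin(2 * pi * 5 * t)
#' y <- fft_bandpass(x, fs)           # 5 Hz component removed
#' max(abs(y - sin(2 * pi * 50 * t))) # ~1e-12
#' @export
fft_bandpass <- function(x, fs, spec = bandpass_spec()) {
  n <- length(x)
  if (n == 0L) stop("empty input")
  if (n < 2L) stop("input must have length >= 2")
  if (spec$f_hi_hz >= fs / 2)
    stop("f_hi_hz must be below the Nyquist frequency fs/2")
  # bin k (0-based, k <= n/2) carries frequency k*fs/n; the kept band is the
  # contiguous run klo..khi plus its conjugate mirror n-khi..n-klo
  lo <- spec$f_lo_hz * n / fs
  hi <- spec$f_hi_hz * n / fs
  eps <- 1e-6                              # bins are 1 apart: generous slack
  klo <- if (spec$edge_inclusive) ceiling(lo - eps) else floor(lo + eps) + 1
  khi <- if (spec$edge_inclusive) floor(hi + eps) else ceiling(hi - eps) - 1
  klo <- max(klo, 1L)                      # f_lo > 0: DC always zeroed
  X <- stats::fft(x)
  if (khi < klo) {
    X[] <- 0
  } else {
    X[seq_len(klo)] <- 0                               # k = 0 .. klo-1
    if (khi + 2L <= n - khi) X[(khi + 2L):(n - khi)] <- 0   # mid stop-band
    if (klo >= 2L) X[(n - klo + 2L):n] <- 0            # mirrored low band
  }
  y <- stats::fft(X, inverse = TRUE) / n
  # mask is conjugate-symmetric, so the imaginary residue is numerical only
  Re(y)
}

#' Root mean square over non-overlapping windows
#'
#' Partitions `x` into consecutive non-overlapping blocks of
#' `round(window_s * fs)` samples and emits \eqn{\sqrt{mean(x^2)}} per
#' complete block.  A trailing incomplete block is dropped (padding would
#' bias the RMS).  Timestamps are block start times on the recording clock.
#'
#' @param x sample vector.
#' @param fs sampling rate in Hz.
#' @param window_s window length in seconds (default 30; `window_s * fs`
#'   must round to >= 1 sample).
#' @return An `rms_series`: list with `values` (g), `window_start_s`,
#'   `window_s`, `n_windows`, and `truncated` (`TRUE` when the recording was
#'   shorter than one window, giving an empty series).
#' @export
windowed_rms <- function(x, fs, window_s = 30) {
  m <- as.integer(round(window_s * fs))
  if (m < 1L) stop("window_s * fs must round to at least one sample")
  nw <- length(x) %/% m
  vals <- if (nw > 0L) {
    xx <- x[seq_len(nw * m)]^2
    sqrt(colMeans(matrix(xx, nrow = m, ncol = nw)))
  } else numeric(0)
  structure(list(values = vals,
                 window_start_s = (seq_len(nw) - 1L) * window_s,
                 window_s = window_s,
                 n_windows = nw,
                 truncated = nw == 0L,
                 meta = list(fs = fs)),
            class = "rms_series")
}

#' @export
print.rms_series <- function(x, ...) {
  cat(sprintf("<rms_series: %d windows of %g s>\n", x$n_windows, x$window_s))
  if (x$n_windows > 0)
    cat(sprintf("  rms range %.4g - %.4g g\n", min(x$values), max(x$values)))
  if (!is.null(x$meta$order)) cat("  pipeline order:", x$meta$order, "\n")
  invisible(x)
}

#' @export
as.data.frame.rms_series <- function(x, ...) {
  data.frame(window_start_s = x$window_start_s, rms_g = x$values)
}

#' @export
plot.rms_series <- function(x, ..., xlab = "time (s)", ylab = "RMS (g)",
                            type = "s") {
  plot(x$window_start_s, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Write an RMS series as CSV with a sidecar metadata block
#'
#' @param rs an `rms_series`.
#' @param path destination CSV (columns `window_start_s`, `rms_g`); the filter
#'   and window parameters are echoed into `<stem>_meta.yaml`.
#' @export
write_rms_series <- function(rs, path) {
  stopifnot(inherits(rs, "rms_series"))
  .fwrite_lossless(data.table::as.data.table(as.data.frame(rs)), path)
  meta <- c(rs$meta, list(window_s = rs$window_s, n_windows = rs$n_windows,
                          truncated = rs$truncated))
  yaml::write_yaml(meta, paste0(sub("\\.[^.]*$", "", path), "_meta.yaml"))
  invisible(path)
}

#' Full vibration signal chain for one recording
#'
#' Runs the oxygenator vibration chain on a triaxial recording and returns the
#' per-window RMS series (the \eqn{RMS_{oxy}} metric when the accelerometer
#' sits on the oxygenator).  Two orderings are supported because the norm is
#' nonlinear and the order matters:
#'
#' \describe{
#'   \item{`norm_first` (default)}{omnidirectional norm, then bandpass of the
#'     norm, then windowed RMS.}
#'   \item{`filter_first`}{bandpass each axis, then norm, then windowed RMS.}
#' }
#'
#' The order used is recorded in the result's metadata.
#'
#' @param rec an [accel_recording].
#' @param spec a [bandpass_spec]; `rec$sampling_rate_hz` must exceed
#'   `2 * spec$f_hi_hz`.
#' @param window_s RMS window in seconds (default 30).
#' @param order `"norm_first"` or `"filter_first"`.
#' @return an `rms_series` (see [windowed_rms()]).
#' @export
process_recording <- function(rec, spec = bandpass_spec(), window_s = 30,
                              order = c("norm_first", "filter_first")) {
  stopifnot(inherits(rec, "accel_recording"))
  order <- match.arg(order)
  fs <- rec$sampling_rate_hz
  if (fs <= 2 * spec$f_hi_hz)
    stop("sampling rate must exceed twice the upper cutoff (Nyquist)")
  sig <- if (order == "norm_first") {
    fft_bandpass(vector_norm(rec$gx, rec$gy, rec$gz), fs, spec)
  } else {
    vector_norm(fft_bandpass(rec$gx, fs, spec),
                fft_bandpass(rec$gy, fs, spec),
                fft_bandpass(rec$gz, fs, spec))
  }
  rs <- windowed_rms(sig, fs, window_s)
  rs$meta <- list(fs = fs, order = order,
                  f_lo_hz = spec$f_lo_hz, f_hi_hz = spec$f_hi_hz,
                  edge_inclusive = spec$edge_inclusive,
                  subject_id = rec$subject_id)
  rs
}
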