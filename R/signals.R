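#' Uniformly sampled drive signal
#'
#' Container for the uniformly sampled time series handled by the workflow:
#' cumulative spike trains (CST), common synaptic input (CSI) and control
#' (CSC), effective neural drive (eND), current input and force traces.
#'
#' @param times numeric vector of sample times (s), uniformly spaced.
#' @param values numeric vector of samples, finite, same length as `times`.
#' @param role one of `"CST"`, `"eND"`, `"CSI"`, `"CSC"`, `"current"`,
#'   `"force"`, `"binary"`.
#' @return An object of class `drive_signal`.
#' @export
drive_signal <- function(times, values,
                         role = c("CST", "eND", "CSI", "CSC", "current",
                                  "force", "binary")) {
  role <- match.arg(role)
  stopifnot(is.numeric(times), is.numeric(values),
            length(times) == length(values))
  if (!all(is.finite(values))) stop("drive_signal values must be finite")
  if (length(times) > 2) {
    dts <- diff(times)
    if (max(dts) - min(dts) > 1e-9 * max(dts))
      stop("drive_signal time grid must be uniform")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 role = role),
            class = "drive_signal")
}

#' @export
print.drive_signal <- function(x, ...) {
  cat(sprintf("<drive_signal:%s> %d samples, t in [%.3f, %.3f] s, fs %.0f Hz\n",
              x$role, length(x$times), min(x$times), max(x$times),
              1 / signal_dt(x)))
  invisible(x)
}

#' Sampling interval of a signal
#' @param x a `drive_signal` or `rate_series`.
#' @return The grid spacing in seconds.
#' @export
signal_dt <- function(x) {
  if (length(x$times) < 2) return(NA_real_)
  (x$times[length(x$times)] - x$times[1]) / (length(x$times) - 1)
}

#' Discharge-rate series
#'
#' @param times uniform time grid (s).
#' @param values rate samples (Hz), non-negative.
#' @param kind `"IDF-impulse"` (impulses of reciprocal inter-spike interval
#'   at firing instants), `"FIDF"` (Hann-smoothed continuous rate) or
#'   `"trend"` (polynomial trendline).
#' @param empty logical flag marking a degenerate series (fewer than two
#'   discharges).
#' @return An object of class `rate_series`.
#' @export
rate_series <- function(times, values, kind = c("IDF-impulse", "FIDF", "trend"),
                        empty = FALSE) {
  kind <- match.arg(kind)
  stopifnot(length(times) == length(values))
  if (any(values < 0)) stop("rate_series values must be non-negative")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind, empty = isTRUE(empty)),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series:%s> %d samples%s, peak %.2f Hz\n", x$kind,
              length(x$times), if (x$empty) " (degenerate)" else "",
              if (length(x$values)) max(x$values) else NA_real_))
  invisible(x)
}

#' Zero-phase low-pass filter
#'
#' Fourth-order Butterworth applied forward-backward (`signal::filtfilt`)
#' with reflection padding at both ends, so the filter is zero-phase and a
#' constant input is returned unchanged (DC gain 1).
#'
#' @param x a [drive_signal()].
#' @param cutoff_hz cutoff frequency (Hz), strictly below Nyquist.
#' @param order filter order (default 4).
#' @return A [drive_signal()] on the same grid (role preserved unless
#'   overridden via `role`).
#' @param role optional role for the returned signal.
#' @export
lowpass <- function(x, cutoff_hz, order = 4, role = NULL) {
  stopifnot(inherits(x, "drive_signal"))
  fs <- 1 / signal_dt(x)
  if (!is.finite(fs)) stop("signal too short to filter")
  if (cutoff_hz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  v <- x$values
  n <- length(v)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / cutoff_hz)))
  vp <- c(rev(v[2:(pad + 1L)]), v, rev(v[(n - pad):(n - 1L)]))
  m <- mean(vp) # filter the deviation so DC passes exactly
  yf <- signal::filtfilt(bf, vp - m) + m
  y <- yf[(pad + 1L):(pad + n)]
  drive_signal(x$times, y, role = if (is.null(role)) x$role else role)
}

#' Normalize a signal to unit peak
#'
#' @param x a [drive_signal()].
#' @return The signal divided by its maximum absolute value (unchanged when
#'   identically zero).
#' @export
normalize_peak <- function(x) {
  stopifnot(inherits(x, "drive_signal"))
  m <- max(abs(x$values))
  if (m == 0) return(x)
  drive_signal(x$times, x$values / m, role = x$role)
}

restrict_overlap <- function(a, b) {
  lo <- max(min(a$times), min(b$times))
  hi <- min(max(a$times), max(b$times))
  if (hi <= lo) stop("signals have no common time support")
  ia <- a$times >= lo - 1e-12 & a$times <= hi + 1e-12
  ib <- b$times >= lo - 1e-12 & b$times <= hi + 1e-12
  va <- a$values[ia]; vb <- b$values[ib]
  n <- min(length(va), length(vb))
  list(a = va[seq_len(n)], b = vb[seq_len(n)])
}

#' Agreement metrics between two signals
#'
#' Computes the validation metrics used throughout the workflow: the
#' root-mean-square error normalized by the range of the reference `b`
#' (`nrmse`, %), the coefficient of determination `r2` (squared Pearson
#' correlation of `a` against `b`), and the maximum absolute error
#' normalized by the range of `b` (`nme`, %).  Signals are restricted to
#' their common time support.
#'
#' @param a,b `drive_signal` or `rate_series` objects on compatible grids;
#'   `b` is the reference whose range normalizes the errors.
#' @return A list of class `validation_metrics` with fields `nrmse`, `r2`,
#'   `nme` and (reserved, `NA`) `dft1`.
#' @examples
#' s <- drive_signal(seq(0, 1, by = 0.01), sin(seq(0, 1, by = 0.01)), "force")
#' compare_signals(s, s) # 0, 1, 0
#' @export
compare_signals <- function(a, b) {
  ov <- restrict_overlap(a, b)
  va <- ov$a; vb <- ov$b
  rng <- diff(range(vb))
  if (rng == 0) stop("reference signal has zero range")
  if (identical(va, vb))
    return(validation_metrics(0, 1, 0))
  err <- va - vb
  nrmse <- sqrt(mean(err^2)) / rng * 100
  nme <- max(abs(err)) / rng * 100
  r2 <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) 0
        else stats::cor(va, vb)^2
  validation_metrics(nrmse, r2, nme)
}

#' Validation-metric container
#'
#' @param nrmse normalized RMS error (% of reference range), non-negative.
#' @param r2 coefficient of determination, at most 1.
#' @param nme normalized maximum error (%).
#' @param dft1 signed recruitment-time error (s), when applicable.
#' @return A list of class `validation_metrics`.
#' @export
validation_metrics <- function(nrmse, r2, nme = NA_real_, dft1 = NA_real_) {
  stopifnot(nrmse >= 0, r2 <= 1 + 1e-12)
  structure(list(nrmse = nrmse, r2 = min(r2, 1), nme = nme, dft1 = dft1),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat(sprintf("<validation_metrics> nRMSE %.2f%%, r2 %.3f%s%s\n",
              x$nrmse, x$r2,
              if (is.na(x$nme)) "" else sprintf(", nME %.2f%%", x$nme),
              if (is.na(x$dft1)) "" else sprintf(", dft1 %+.3f s", x$dft1)))
  invisible(x)
}
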