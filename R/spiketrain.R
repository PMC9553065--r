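#' Motoneuron spike train
#'
#' Discharge times of one motoneuron (MN), with the force level at which it
#' was recruited when that was recorded.
#'
#' @param firing_times strictly increasing vector of discharge times (s),
#'   all non-negative.
#' @param mn_id integer label of the MN.
#' @param recruitment_threshold force recruitment threshold in %MVC
#'   (optional; must lie in `(0, 100]` when present).
#' @param sampling_rate grid used for binarization (Hz).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(firing_times, mn_id = 1L,
                        recruitment_threshold = NA_real_,
                        sampling_rate = 2048) {
  firing_times <- as.numeric(firing_times)
  if (length(firing_times) && any(firing_times < 0))
    stop("firing times must be non-negative")
  if (length(firing_times) > 1 && any(diff(firing_times) <= 0))
    stop("firing times must be strictly increasing")
  if (!is.na(recruitment_threshold) &&
      (recruitment_threshold <= 0 || recruitment_threshold > 100))
    stop("recruitment_threshold must lie in (0, 100] %MVC")
  structure(list(mn_id = as.integer(mn_id), firing_times = firing_times,
                 recruitment_threshold = recruitment_threshold,
                 sampling_rate = sampling_rate),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> MN %d: %d discharges%s%s\n", x$mn_id,
              length(x$firing_times),
              if (length(x$firing_times))
                sprintf(" in [%.3f, %.3f] s", min(x$firing_times),
                        max(x$firing_times)) else "",
              if (is.na(x$recruitment_threshold)) ""
              else sprintf(", Fth %.2f %%MVC", x$recruitment_threshold)))
  invisible(x)
}

#' Number of discharges
#' @param train a [spike_train()].
#' @return Integer count of discharges.
#' @export
n_discharges <- function(train) length(train$firing_times)

#' Binary spike train on the protocol grid
#'
#' Places a 1 at the grid sample nearest each firing time and 0 elsewhere,
#' so the sum of the samples equals the number of discharges.
#'
#' @param train a [spike_train()].
#' @param protocol a [contraction_protocol()] whose window must contain all
#'   firing times.
#' @param merge_coincident two firings mapping to the same grid sample are
#'   physiologically impossible for one MN at 2048 Hz and raise an error by
#'   default; set `TRUE` to merge them into a single sample with a warning.
#' @return A [drive_signal()] with `role = "binary"`, values in `{0, 1}`.
#' @export
binarize <- function(train, protocol, merge_coincident = FALSE) {
  stopifnot(inherits(train, "spike_train"),
            inherits(protocol, "contraction_protocol"))
  times <- protocol_grid(protocol)
  v <- numeric(length(times))
  ft <- train$firing_times
  if (length(ft)) {
    if (any(ft < protocol$t_tr[1] - 1e-9) || any(ft > protocol$t_tr[6] + 1e-9))
      stop(sprintf("MN %d has firing times outside the protocol window [%g, %g] s",
                   train$mn_id, protocol$t_tr[1], protocol$t_tr[6]))
    idx <- round((ft - protocol$t_tr[1]) * protocol$sampling_rate) + 1L
    idx <- pmin(pmax(idx, 1L), length(times))
    if (anyDuplicated(idx)) {
      if (!merge_coincident)
        stop(sprintf("MN %d: two discharges fall on the same grid sample; %s",
                     train$mn_id,
                     "use merge_coincident = TRUE to merge them"))
      warning(sprintf("MN %d: coincident discharges merged into one sample",
                      train$mn_id))
      idx <- unique(idx)
    }
    v[idx] <- 1
  }
  drive_signal(times, v, role = "binary")
}

#' Instantaneous discharge frequency (IDF) impulse train
#'
#' At the grid sample nearest each firing time `ft_k` (except the last), the
#' series takes the value `1/(ft_{k+1} - ft_k)` (Hz); it is zero elsewhere.
#'
#' @param train a [spike_train()] with at least two discharges; with fewer,
#'   an empty series flagged `empty = TRUE` is returned.
#' @param protocol a [contraction_protocol()].
#' @return A [rate_series()] of kind `"IDF-impulse"`.
#' @export
instantaneous_discharge_frequency <- function(train, protocol) {
  stopifnot(inherits(train, "spike_train"),
            inherits(protocol, "contraction_protocol"))
  times <- protocol_grid(protocol)
  ft <- train$firing_times
  if (length(ft) < 2)
    return(rate_series(times, numeric(length(times)), kind = "IDF-impulse",
                       empty = TRUE))
  v <- numeric(length(times))
  idx <- round((ft - protocol$t_tr[1]) * protocol$sampling_rate) + 1L
  idx <- pmin(pmax(idx, 1L), length(times))
  rates <- 1 / diff(ft)
  v[idx[-length(idx)]] <- rates
  rate_series(times, v, kind = "IDF-impulse")
}

hann_window <- function(n) {
  if (n < 2) stop("Hann window needs at least 2 samples")
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

centered_convolve <- function(x, w) {
  # zero-phase convolution, output on the input grid (centered window)
  n <- length(x); L <- length(w)
  half <- (L - 1L) %/% 2L
  y <- stats::convolve(c(x, numeric(L)), rev(w), type = "open")
  y[(half + 1L):(half + n)]
}

# centered convolution of a sparse impulse train (impulses amp at idx) with
# window w; fast path for IDF smoothing where only firing instants are
# nonzero
sparse_centered_convolve <- function(n, idx, amp, w) {
  L <- length(w); half <- (L - 1L) %/% 2L
  out <- numeric(n)
  for (k in seq_along(idx)) {
    lo <- idx[k] - half; hi <- idx[k] + half
    wlo <- 1L + max(0L, 1L - lo); whi <- L - max(0L, hi - n)
    olo <- max(1L, lo); ohi <- min(n, hi)
    out[olo:ohi] <- out[olo:ohi] + amp[k] * w[wlo:whi]
  }
  out
}

#' Smoothed (filtered) instantaneous discharge frequency
#'
#' Smooths an IDF impulse train with a centered Hann window of the given
#' duration (default 400 ms).  The smoothing is a kernel-weighted moving
#' average over the firing instants,
#' `FIDF(t) = sum_k IDF_k w(t - ft_k) / sum_k w(t - ft_k)`,
#' so the output lives on the discharge-rate scale: a train firing at a
#' constant rate maps to that rate in the window interior.  Outside the
#' half-window neighbourhood of the discharges the FIDF is zero.
#'
#' @param idf a [rate_series()] of kind `"IDF-impulse"`.
#' @param window_s Hann window duration (s), at least two grid steps.
#' @return A [rate_series()] of kind `"FIDF"` on the same grid.
#' @export
filtered_idf <- function(idf, window_s = 0.400) {
  stopifnot(inherits(idf, "rate_series"), idf$kind == "IDF-impulse")
  dt <- signal_dt(idf)
  L <- round(window_s / dt) + 1L
  if (L %% 2L == 0L) L <- L + 1L
  if (window_s < 2 * dt) stop("window shorter than two grid steps")
  w <- hann_window(L)
  nz <- which(idf$values > 0)
  num <- sparse_centered_convolve(length(idf$values), nz, idf$values[nz], w)
  den <- sparse_centered_convolve(length(idf$values), nz,
                                  rep(1, length(nz)), w)
  v <- ifelse(den > 1e-12, num / den, 0)
  v[v < 0] <- 0
  rate_series(idf$times, v, kind = "FIDF", empty = idf$empty)
}

#' Polynomial discharge-rate trendline
#'
#' Least-squares polynomial (default order 6) fitted to the `(time, IDF)`
#' pairs at the firing instants only, evaluated on the grid spanning the
#' firing period.  With fewer than `order + 1` firing instants the order is
#' reduced with a warning.
#'
#' @param idf a [rate_series()] of kind `"IDF-impulse"`.
#' @param order polynomial order (default 6).
#' @return A [rate_series()] of kind `"trend"` over the firing span.
#' @export
polynomial_trend <- function(idf, order = 6) {
  stopifnot(inherits(idf, "rate_series"), idf$kind == "IDF-impulse")
  nz <- which(idf$values > 0)
  if (length(nz) < 2) stop("too few discharges for a trendline")
  if (length(nz) < order + 1) {
    order <- length(nz) - 1L
    warning(sprintf("trend order reduced to %d (only %d IDF points)",
                    order, length(nz)))
  }
  x <- idf$times[nz]; y <- idf$values[nz]
  fit <- stats::lm(y ~ stats::poly(x, degree = order))
  grid <- idf$times >= min(x) & idf$times <= max(x)
  pred <- stats::predict(fit, newdata = data.frame(x = idf$times[grid]))
  pred[pred < 0] <- 0
  rate_series(idf$times[grid], pred, kind = "trend")
}

#' Cumulative spike train (CST)
#'
#' Per-sample sum of the binarized spike trains; the total over time equals
#' the total number of discharges.
#'
#' @param trains list of [spike_train()] objects (at least one).
#' @param protocol a [contraction_protocol()].
#' @param merge_coincident passed to [binarize()].
#' @return A [drive_signal()] with `role = "CST"` and integer values.
#' @export
cumulative_spike_train <- function(trains, protocol, merge_coincident = FALSE) {
  if (!length(trains)) stop("at least one spike train is required")
  times <- protocol_grid(protocol)
  acc <- numeric(length(times))
  for (tr in trains)
    acc <- acc + binarize(tr, protocol, merge_coincident)$values
  drive_signal(times, acc, role = "CST")
}
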