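#' Trapezoidal contraction protocol
#'
#' Describes a trapezoidal isometric contraction: zero force on
#' `[t_tr0, t_tr1]`, a linear ramp up on `[t_tr1, t_tr2]`, a plateau at
#' `plateau_mvc` on `[t_tr2, t_tr3]`, a linear ramp down on `[t_tr3, t_tr4]`
#' and zero force on `[t_tr4, t_tr5]`.  All derived signals live on the
#' uniform grid `seq(t_tr0, t_tr5, by = 1/sampling_rate)`.
#'
#' @param t_tr numeric vector of six non-decreasing times (s),
#'   `t_tr0 .. t_tr5`.
#' @param plateau_mvc plateau force level in %MVC, in `(0, 100]`.
#' @param sampling_rate sampling rate of the recording grid (Hz).
#' @return An object of class `contraction_protocol`.
#' @examples
#' contraction_protocol(c(0, 2.2, 10.6, 20.5, 30, 30), 35)
#' @export
contraction_protocol <- function(t_tr, plateau_mvc, sampling_rate = 2048) {
  stopifnot(is.numeric(t_tr), length(t_tr) == 6, all(is.finite(t_tr)))
  if (any(diff(t_tr) < 0)) stop("protocol times t_tr0..t_tr5 must be non-decreasing")
  if (!is.numeric(plateau_mvc) || plateau_mvc <= 0 || plateau_mvc > 100)
    stop("plateau_mvc must lie in (0, 100]")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(
    list(t_tr = as.numeric(t_tr), plateau_mvc = plateau_mvc,
         sampling_rate = sampling_rate),
    class = "contraction_protocol")
}

#' @export
print.contraction_protocol <- function(x, ...) {
  cat(sprintf(
    "<contraction_protocol> plateau %.1f %%MVC, fs %.0f Hz\n  t_tr = [%s] s\n",
    x$plateau_mvc, x$sampling_rate, paste(format(x$t_tr), collapse = ", ")))
  invisible(x)
}

#' Time grid of a protocol
#'
#' @param protocol a [contraction_protocol()].
#' @return Numeric vector of sample times from `t_tr0` to `t_tr5`.
#' @export
protocol_grid <- function(protocol) {
  stopifnot(inherits(protocol, "contraction_protocol"))
  dt <- 1 / protocol$sampling_rate
  n <- floor((protocol$t_tr[6] - protocol$t_tr[1]) / dt) + 1L
  protocol$t_tr[1] + (seq_len(n) - 1L) * dt
}

#' Normalized trapezoid waveform of a protocol
#'
#' Returns the ramp-plateau-ramp wave of the protocol on its sampling grid,
#' normalized to peak 1 (the plateau).
#'
#' @param protocol a [contraction_protocol()].
#' @return A [drive_signal()] with `role = "force"` and peak value 1.
#' @export
trapezoid_wave <- function(protocol) {
  tt <- protocol$t_tr
  times <- protocol_grid(protocol)
  v <- numeric(length(times))
  up <- times >= tt[2] & times < tt[3]
  if (tt[3] > tt[2]) v[up] <- (times[up] - tt[2]) / (tt[3] - tt[2])
  v[times >= tt[3] & times <= tt[4]] <- 1
  dn <- times > tt[4] & times < tt[5]
  if (tt[5] > tt[4]) v[dn] <- (tt[5] - times[dn]) / (tt[5] - tt[4])
  drive_signal(times, v, role = "force")
}
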