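#' Default resistance scale constant
#'
#' The resistance-size power law `R = k_R / S^2.43` needs an anchor.  The
#' default anchors the law at the midpoint of the classic cat motoneuron
#' ranges of surface area (`[0.15, 0.36] mm^2`) and input resistance
#' (`[0.5, 4.1] MOhm`): `k_R = R_ref * S_ref^2.43` with
#' `(S_ref, R_ref) = (2.5e-7 m^2, 2.0e6 Ohm)`.
#'
#' @return The constant `k_R` (Ohm m^(2*2.43)).
#' @export
default_kr <- function() 2.0e6 * (2.5e-7)^2.43

#' Leaky integrate-and-fire parameters from motoneuron size
#'
#' Derives the electrophysiological parameters of a single-compartment LIF
#' motoneuron from its membrane surface area `S`:
#' input resistance `R = k_R / S^2.43`, capacitance `C = C_m S`,
#' time constant `tau = R C`, and rheobase `I^th = dV_th / R` (Ohm's law).
#'
#' @param size_s membrane surface area (m^2), sanity-bounded to
#'   `(5e-8, 1e-6)`.
#' @param ip inert period (s): post-spike interval during which the
#'   membrane is held at rest; sets the maximum firing rate `1/IP`.
#' @param kr resistance scale constant (default [default_kr()]).
#' @param cm specific membrane capacitance (F/m^2, default `1.3e-2`, i.e.
#'   1.3 uF/cm^2).
#' @param dvth voltage threshold above rest (V, default 0.027).
#' @return An object of class `lif_parameters`.
#' @export
lif_params_from_size <- function(size_s, ip = 0.04, kr = default_kr(),
                                 cm = 1.3e-2, dvth = 0.027) {
  if (size_s <= 5e-8 || size_s >= 1e-6)
    stop("size_s outside the physiological range (5e-8, 1e-6) m^2")
  stopifnot(ip > 0, kr > 0, cm > 0, dvth > 0)
  r <- kr / size_s^2.43
  cc <- cm * size_s
  structure(list(size_s = size_s, resistance_r = r, capacitance_c = cc,
                 tau = r * cc, dvth = dvth, rheobase = dvth / r,
                 ip = ip, cm = cm, kr = kr),
            class = "lif_parameters")
}

#' @export
print.lif_parameters <- function(x, ...) {
  cat(sprintf(paste0(
    "<lif_parameters> S %.3g mm^2, R %.3g MOhm, C %.3g nF, tau %.2f ms\n",
    "  rheobase %.3g nA, dVth %.0f mV, IP %.1f ms\n"),
    x$size_s * 1e6, x$resistance_r / 1e6, x$capacitance_c * 1e9,
    x$tau * 1e3, x$rheobase * 1e9, x$dvth * 1e3, x$ip * 1e3))
  invisible(x)
}

#' Derecruitment-phase parameter variant
#'
#' During derecruitment the current-voltage hysteresis (persistent inward
#' currents) makes motoneurons stop firing at a lower current threshold
#' than at recruitment.  Phenomenologically this is an apparent increase of
#' the input resistance to `R^d = R / k_th` (so the derecruitment rheobase
#' is `k_th * I^th < I^th`) and of the specific capacitance to `C_m^d`.
#'
#' @param params a [lif_parameters()].
#' @param kth_ratio derecruitment-to-recruitment threshold ratio
#'   `k_th^dth` in `(0, 1)`.
#' @param cmd derecruitment specific capacitance (F/m^2), at least `cm`.
#' @param switch_time time from which the variant applies (s), normally
#'   `t_tr3`.
#' @return An object of class `derecruitment_params`.
#' @export
derecruitment_variant <- function(params, kth_ratio, cmd = params$cm,
                                  switch_time = NA_real_) {
  stopifnot(inherits(params, "lif_parameters"))
  if (kth_ratio <= 0 || kth_ratio >= 1)
    stop("kth_ratio must lie strictly inside (0, 1)")
  if (cmd < params$cm) stop("cmd must be at least cm")
  structure(list(kth_ratio = kth_ratio,
                 rd = params$resistance_r / kth_ratio,
                 cmd = cmd, switch_time = switch_time),
            class = "derecruitment_params")
}

#' Steady-state firing rate of a LIF motoneuron
#'
#' Closed form for constant supra-threshold current:
#' \deqn{FF(I) = 1 / (IP - R C \ln(1 - \Delta V_{th} / (R I)))}
#' which tends to `1/IP` as `I >> I^th`.
#'
#' @param params a [lif_parameters()].
#' @param i_const constant current (A), strictly above the rheobase.
#' @return Firing rate (Hz).
#' @export
steady_state_rate <- function(params, i_const) {
  stopifnot(inherits(params, "lif_parameters"))
  if (i_const <= params$rheobase)
    stop("current must exceed the rheobase")
  1 / (params$ip - params$resistance_r * params$capacitance_c *
         log(1 - params$dvth / (params$resistance_r * i_const)))
}

current_vector <- function(current) {
  if (inherits(current, "current_input")) current$signal
  else if (inherits(current, "drive_signal")) current
  else stop("current must be a current_input or drive_signal")
}

#' Simulate a LIF motoneuron
#'
#' Integrates the discrete recurrence
#' `Vm[n] = exp(-dt/tau) Vm[n-1] + (R dt / tau) I[n]`
#' (forward Euler-type scheme; `scheme = "exact"` uses the exponential
#' integrator coefficient `R (1 - exp(-dt/tau))` as a correctness
#' cross-check).  A spike is recorded at the grid sample where
#' `Vm >= dVth`; the membrane is then reset and held at rest for the inert
#' period `IP + o`, where `o ~ N(0, IP/10)` truncated at `-IP` (omitted
#' when `ip_noise = FALSE`).  When a [derecruitment_variant()] is given,
#' `R` and `C_m` switch to their derecruitment values from `switch_time`
#' on.
#'
#' @param params a [lif_parameters()].
#' @param current a `current_input` or `drive_signal` (ampere).
#' @param dt integration step (s), at most 0.001; defaults to the current
#'   grid spacing.  A mismatched grid is resampled with a warning.
#' @param seed integer seed for the inert-period noise.
#' @param derecruit optional [derecruitment_variant()].
#' @param ip_noise randomize the inert period at each firing (default
#'   TRUE).
#' @param mn_id label for the returned train.
#' @param scheme `"forward"` (default) or `"exact"`.
#' @return A [spike_train()] of the simulated discharges.
#' @export
lif_simulate <- function(params, current, dt = NULL, seed = 1,
                         derecruit = NULL, ip_noise = TRUE, mn_id = 1L,
                         scheme = c("forward", "exact")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(params, "lif_parameters"))
  sig <- current_vector(current)
  grid_dt <- signal_dt(sig)
  if (is.null(dt)) dt <- grid_dt
  if (dt > 0.001 + 1e-12) stop("dt must be at most 0.001 s")
  vals <- sig$values
  t0 <- sig$times[1]
  if (abs(dt - grid_dt) > 1e-12) {
    warning("current grid mismatched with dt; resampling by interpolation")
    n <- floor((sig$times[length(sig$times)] - t0) / dt) + 1L
    tt <- t0 + (seq_len(n) - 1L) * dt
    vals <- stats::approx(sig$times, sig$values, xout = tt, rule = 2)$y
  }
  switch_idx <- -1L; rd <- params$resistance_r; cd <- params$capacitance_c
  if (!is.null(derecruit)) {
    stopifnot(inherits(derecruit, "derecruitment_params"))
    if (is.na(derecruit$switch_time))
      stop("derecruitment variant needs a switch_time")
    switch_idx <- as.integer(round((derecruit$switch_time - t0) / dt))
    rd <- derecruit$rd
    cd <- derecruit$cmd * params$size_s
  }
  idx <- .lif_step_cpp(vals, dt, params$resistance_r, params$capacitance_c,
                       params$dvth, params$ip, switch_idx, rd, cd,
                       isTRUE(ip_noise), params$ip / 10, as.numeric(seed),
                       scheme == "exact")
  spike_train(t0 + idx * dt, mn_id = mn_id,
              sampling_rate = 1 / dt)
}
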