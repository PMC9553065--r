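#' Specification of a reconstructed motoneuron pool
#'
#' Bundles the property distributions and seeds needed to simulate the
#' complete pool of `n_pool` LIF motoneurons.  Per-MN seeds are derived
#' from the master seed by a counter scheme (`master_seed + j`), so adding
#' motoneurons does not perturb existing ones.
#'
#' @param n_pool pool size `N`.
#' @param size_dist a [size_distribution()].
#' @param ip_dist an `ip_distribution` from [fit_ip_distribution()].
#' @param kth_ratio derecruitment threshold ratio in `(0, 1)`, or `NA` to
#'   disable the derecruitment variant.
#' @param cmd derecruitment specific capacitance (F/m^2).
#' @param master_seed master RNG seed.
#' @param kr,cm,dvth LIF constants, see [lif_params_from_size()].
#' @return An object of class `pool_spec`.
#' @export
pool_spec <- function(n_pool, size_dist, ip_dist, kth_ratio = NA_real_,
                      cmd = NA_real_, master_seed = 1, kr = default_kr(),
                      cm = 1.3e-2, dvth = 0.027) {
  stopifnot(inherits(size_dist, "size_distribution"),
            inherits(ip_dist, "ip_distribution"))
  structure(list(n_pool = as.integer(n_pool), size_dist = size_dist,
                 ip_dist = ip_dist, kth_ratio = kth_ratio, cmd = cmd,
                 master_seed = master_seed, kr = kr, cm = cm, dvth = dvth),
            class = "pool_spec")
}

#' @export
print.pool_spec <- function(x, ...) {
  cat(sprintf("<pool_spec> N = %d, master seed %d%s\n", x$n_pool,
              x$master_seed,
              if (is.na(x$kth_ratio)) ""
              else sprintf(", derecruitment kth %.2f, Cmd %.1f uF/cm^2",
                           x$kth_ratio, x$cmd * 100)))
  invisible(x)
}

#' Simulate the complete motoneuron pool
#'
#' Runs one LIF model per pool location `j`, parameterized by `S(j)` and
#' `IP(j)`, all receiving the same current input; the derecruitment
#' variant (when specified) is active from `t_tr3` on.  Deterministic
#' under a fixed master seed.
#'
#' @param spec a [pool_spec()].
#' @param current a `current_input` or `drive_signal` (ampere).
#' @param protocol a [contraction_protocol()].
#' @param ip_noise randomize inert periods (default TRUE).
#' @return An object of class `pool_result`: list with `trains` (length
#'   `N`), `cst`, `end_n` (0-4 Hz effective neural drive, raw) and
#'   `end_n_norm`.
#' @export
simulate_pool <- function(spec, current, protocol, ip_noise = TRUE) {
  stopifnot(inherits(spec, "pool_spec"))
  sizes <- evaluate_size(spec$size_dist, seq_len(spec$n_pool))
  ips <- evaluate_ip(spec$ip_dist, seq_len(spec$n_pool))
  trains <- vector("list", spec$n_pool)
  for (j in seq_len(spec$n_pool)) {
    p <- lif_params_from_size(sizes[j], ip = ips[j], kr = spec$kr,
                              cm = spec$cm, dvth = spec$dvth)
    d <- if (!is.na(spec$kth_ratio))
      derecruitment_variant(p, spec$kth_ratio,
                            cmd = if (is.na(spec$cmd)) spec$cm else spec$cmd,
                            switch_time = protocol$t_tr[4])
    trains[[j]] <- lif_simulate(p, current, seed = spec$master_seed + j,
                                derecruit = d, ip_noise = ip_noise,
                                mn_id = j)
    trains[[j]]$sampling_rate <- protocol$sampling_rate
  }
  firing <- Filter(n_discharges, trains)
  cst <- if (length(firing)) cumulative_spike_train(firing, protocol)
         else drive_signal(protocol_grid(protocol),
                           numeric(length(protocol_grid(protocol))), "CST")
  endn <- effective_neural_drive_cst(cst)
  structure(list(trains = trains, cst = cst, end_n = endn$raw,
                 end_n_norm = endn$norm, spec = spec),
            class = "pool_result")
}

#' @export
print.pool_result <- function(x, ...) {
  nf <- sum(vapply(x$trains, n_discharges, integer(1)) > 0)
  cat(sprintf("<pool_result> %d MNs simulated, %d firing, %d discharges total\n",
              length(x$trains), nf, sum(x$cst$values)))
  invisible(x)
}

effective_neural_drive_cst <- function(cst, cutoff_hz = 4) {
  if (all(cst$values == 0)) {
    raw <- drive_signal(cst$times, cst$values, role = "eND")
    return(list(raw = raw, norm = raw))
  }
  raw <- lowpass(cst, cutoff_hz, role = "eND")
  raw$values[raw$values < 0] <- 0
  list(raw = raw, norm = normalize_peak(raw))
}

#' Effective neural drive to the muscle
#'
#' Low-pass filters (default 0-4 Hz) the cumulative spike train of a set
#' of motoneurons; the normalized drive is what tracks the normalized
#' force in isometric contraction.
#'
#' @param trains list of [spike_train()]s (empty trains allowed).
#' @param protocol a [contraction_protocol()].
#' @param cutoff_hz low-pass cutoff (Hz, default 4).
#' @return A list with `raw` and `norm` [drive_signal()]s (role `"eND"`).
#' @export
effective_neural_drive <- function(trains, protocol, cutoff_hz = 4) {
  firing <- Filter(n_discharges, trains)
  if (!length(firing)) {
    z <- drive_signal(protocol_grid(protocol),
                      numeric(length(protocol_grid(protocol))), "eND")
    return(list(raw = z, norm = z))
  }
  effective_neural_drive_cst(cumulative_spike_train(firing, protocol),
                             cutoff_hz)
}

#' Validate a neural drive against a force trace
#'
#' Compares the peak-normalized drive with the peak-normalized force.
#'
#' @param end a [drive_signal()] effective neural drive.
#' @param force a [drive_signal()] force trace.
#' @return A [validation_metrics()].
#' @export
validate_against_force <- function(end, force) {
  compare_signals(normalize_peak(end), normalize_peak(force))
}
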