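#' Run the complete workflow from a configuration
#'
#' Orchestrates the four steps end-to-end from a single configuration: it
#' reads the spike-train, threshold and force files, reconstructs the
#' pool, and writes the pool map, current input, effective neural drive,
#' simulated pool trains and a `metrics.json` summary into the output
#' directory.  Every defaulted modelling decision (filter family, window,
#' pool size, seeds) is echoed in a structured log at run start.
#'
#' @param config either a path to a YAML file or a named list with keys:
#'   `trains`, `thresholds`, `force` (CSV paths; `force` optional),
#'   `muscle` (`"TA"` or `"GM"`), `n_pool`, `out_dir`, and the optional
#'   keys `sampling_rate_hz`, `master_seed`, `coherence_n_perm`,
#'   `coherence_seed`, `i_min_a`, `delta_i`, `rheobase_exponent`,
#'   `delta_s`, `protocol_t_tr`, `plateau_mvc`, `ip_anchor_points`
#'   (list of `[N_i, IP_i]`).
#' @return The `pool_reconstruction`, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- c("trains", "thresholds", "n_pool", "out_dir", "protocol_t_tr",
            "plateau_mvc")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing required keys: ", paste(miss, collapse = ", "))
  fs <- config$sampling_rate_hz %||% 2048
  seed <- config$master_seed %||% 1
  protocol <- contraction_protocol(unlist(config$protocol_t_tr),
                                   config$plateau_mvc, fs)
  message(sprintf(
    paste0("monpool run: N = %d, fs = %g Hz, master seed = %d\n",
           "  defaults: 4th-order zero-phase Butterworth (10/4 Hz bands), ",
           "400 ms Hann smoothing,\n  dVth = 27 mV, Cm = 1.3 uF/cm^2, ",
           "delta_S = %.1f, delta_I = %.1f, delta_F = 120"),
    config$n_pool, fs, seed, config$delta_s %||% 2.4,
    config$delta_i %||% 9.1))
  trains <- read_spike_trains(config$trains, sampling_rate = fs)
  trains <- attach_thresholds(trains, read_thresholds(config$thresholds))
  force <- if (!is.null(config$force)) read_force(config$force)
  rheo <- rheobase_distribution(config$n_pool,
                                i_min = config$i_min_a %||% 3.9e-9,
                                delta_i = config$delta_i %||% 9.1,
                                exponent = config$rheobase_exponent %||% 1.18)
  anchors <- NULL
  if (!is.null(config$ip_anchor_points))
    anchors <- do.call(rbind, lapply(config$ip_anchor_points, function(p)
      data.frame(N_i = p[[1]], IP_i = p[[2]])))
  rec <- reconstruct_pool(
    trains, force, protocol, n_pool = config$n_pool, rheo = rheo,
    delta_s = config$delta_s %||% 2.4, master_seed = seed,
    coherence_n_perm = config$coherence_n_perm %||% 20,
    coherence_seed = config$coherence_seed %||% 1,
    ip_anchor_points = anchors)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  utils::write.csv(as.data.frame(rec$pool_map), out("map.csv"),
                   row.names = FALSE, quote = FALSE)
  write_signal(rec$current$signal, out("current.csv"))
  write_signal(rec$pool$end_n_norm, out("end.csv"), value_col = "end_norm")
  write_spike_trains(Filter(n_discharges, rec$pool$trains),
                     out("pool_trains.csv"))
  utils::write.csv(rec$per_mn, out("calibration.csv"), row.names = FALSE,
                   quote = FALSE)
  metrics <- list(
    n_pool = config$n_pool, n_identified = length(trains),
    coherence = if (!is.null(rec$coherence))
      rec$coherence[c("half_sample_mean", "extrapolated_full",
                      "csc_force_r2", "csc_force_nrmse",
                      "representative")],
    ip_dist = list(a = rec$ip_dist$a, b = rec$ip_dist$b),
    size_dist = list(s_min = rec$size_dist$s_min, c = rec$size_dist$c,
                     delta_s = rec$size_dist$delta_s),
    kth_ratio = rec$kth_ratio, cmd_uf_cm2 = rec$cmd * 100,
    per_mn = rec$per_mn,
    end_validation = if (!is.null(rec$metrics)) list(
      end_n = rec$metrics$end_n[c("nrmse", "r2")],
      end_nr = rec$metrics$end_nr[c("nrmse", "r2")]))
  jsonlite::write_json(metrics, out("metrics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(rec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
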