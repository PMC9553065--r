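order_by_threshold <- function(trains) {
  th <- vapply(trains, function(tr) tr$recruitment_threshold, numeric(1))
  if (any(is.na(th)))
    stop("every identified train needs a recruitment_threshold")
  trains[order(th)]
}

#' Reconstruct the complete motoneuron pool from identified spike trains
#'
#' Runs the four-step workflow: (1) map the identified motor units onto
#' the pool through the muscle threshold distribution; (2) estimate the
#' common synaptic input from the cumulative spike train and rescale it
#' into a current drive anchored on the rheobase distribution; (3) extract
#' inert periods from discharge-rate saturation, calibrate each identified
#' motoneuron's size against its smoothed discharge rate, and fit the
#' pool-wide `IP(j)` and `S(j)` distributions plus the derecruitment
#' parameters; (4) simulate the complete pool of `n_pool` LIF models and
#' compute the effective neural drive.
#'
#' @param trains list of identified [spike_train()]s with recorded
#'   `recruitment_threshold`s.
#' @param force a [drive_signal()] force trace (used for the
#'   representativeness check and final validation; may be `NULL`).
#' @param protocol a [contraction_protocol()].
#' @param n_pool pool size `N` (400 for TA, 550 for GM).
#' @param fth_dist a [threshold_distribution()]; defaults to the built-in
#'   TA distribution (also used for GM).
#' @param rheo a [rheobase_distribution()]; defaults to the published cat
#'   distribution.
#' @param delta_s size fold range for `S(j)` (default 2.4).
#' @param bounds size calibration bracket (m^2).
#' @param master_seed master seed for the pool simulation.
#' @param run_coherence run the coherence representativeness check
#'   (requires `force`).
#' @param coherence_n_perm,coherence_seed permutation settings for the
#'   check.
#' @param fit_derecruit fit `k_th^dth` and run the `C_m^d` grid search
#'   (set `FALSE` to skip the derecruitment variant entirely).
#' @param cmd fixed `C_m^d` (F/m^2) to skip the grid search; `NULL`
#'   calibrates it.
#' @param ip_anchor_points optional data.frame of auxiliary `(N_i, IP_i)`
#'   anchor rows appended to the saturating pairs (the remedy when too few
#'   motoneurons saturate).
#' @param kr,cm,dvth LIF constants, see [lif_params_from_size()].
#' @return A list of class `pool_reconstruction` (pool map, current input,
#'   per-MN calibration table, fitted distributions, simulated pool,
#'   validation metrics).
#' @export
reconstruct_pool <- function(trains, force, protocol, n_pool = 400,
                             fth_dist = NULL, rheo = NULL, delta_s = 2.4,
                             bounds = c(1.0e-7, 5.0e-7), master_seed = 1,
                             run_coherence = !is.null(force),
                             coherence_n_perm = 20, coherence_seed = 1,
                             fit_derecruit = TRUE, cmd = NULL,
                             ip_anchor_points = NULL, kr = default_kr(),
                             cm = 1.3e-2, dvth = 0.027) {
  if (is.null(fth_dist)) fth_dist <- ta_threshold_distribution(n_pool)
  if (is.null(rheo)) rheo <- rheobase_distribution(n_pool)
  stopifnot(fth_dist$n_pool == n_pool, rheo$n_pool == n_pool)
  trains <- order_by_threshold(trains)
  nr <- length(trains)
  if (nr < 2) stop("at least two identified spike trains are required")

  # -- step 1: mapping ------------------------------------------------
  th <- vapply(trains, function(tr) tr$recruitment_threshold, numeric(1))
  pmap <- map_to_pool(th, fth_dist)

  # -- step 2: common current input -----------------------------------
  ci <- estimate_common_input(trains, protocol)
  coh <- NULL
  if (run_coherence && !is.null(force) && nr >= 4) {
    coh <- coherence_representativeness(trains, force, protocol,
                                        n_perm = coherence_n_perm,
                                        seed = coherence_seed)
    if (!coh$representative)
      warning(paste("identified sample failed the representativeness check;",
                    "proceeding, but the common-input estimate may be biased"))
  }
  current <- build_current_input(ci$csi, pmap, rheo, trains)

  # -- step 3: inert periods, size calibration, distributions ---------
  sat <- logical(nr); ip_own <- rep(NA_real_, nr)
  for (i in seq_len(nr)) {
    idf <- instantaneous_discharge_frequency(trains[[i]], protocol)
    tr_ok <- !idf$empty && sum(idf$values > 0) >= 3
    if (!tr_ok) next
    trend <- tryCatch(suppressWarnings(polynomial_trend(idf)),
                      error = function(e) NULL)
    if (is.null(trend)) next
    det <- tryCatch(detect_saturation(trend, protocol),
                    error = function(e) list(saturating = FALSE, ip = NA))
    sat[i] <- det$saturating
    ip_own[i] <- det$ip
  }
  ip_pairs <- data.frame(N_i = pmap$N_i[sat], IP_i = ip_own[sat])
  if (!is.null(ip_anchor_points))
    ip_pairs <- rbind(ip_pairs,
                      ip_anchor_points[, c("N_i", "IP_i"), drop = FALSE])
  if (nrow(ip_pairs) < 2)
    stop(paste("fewer than two saturating MNs: supply ip_anchor_points",
               "to anchor the IP distribution"))
  ip_dist <- fit_ip_distribution(ip_pairs)
  ips <- ifelse(sat, ip_own, evaluate_ip(ip_dist, pmap$N_i))

  calib <- vector("list", nr)
  for (i in seq_len(nr)) {
    fid <- filtered_idf(instantaneous_discharge_frequency(trains[[i]],
                                                          protocol))
    calib[i] <- list(tryCatch(
      suppressWarnings(
        calibrate_size(fid, ips[i], current, protocol, bounds = bounds,
                       target_train = trains[[i]], kr = kr, cm = cm,
                       dvth = dvth)),
      error = function(e) NULL))
  }
  ok <- !vapply(calib, is.null, logical(1))
  if (sum(ok) < 2) stop("size calibration failed for all but one MN")
  per_mn <- data.frame(
    i = seq_len(nr), N_i = pmap$N_i, Fth = th, saturating = sat, IP_i = ips,
    S_i = vapply(calib, function(x) if (is.null(x)) NA_real_ else x$size_s,
                 numeric(1)),
    J = vapply(calib, function(x) if (is.null(x)) NA_real_ else x$objective,
               numeric(1)),
    dft1 = vapply(calib, function(x) if (is.null(x)) NA_real_
                  else x$metrics$dft1, numeric(1)),
    nrmse = vapply(calib, function(x) if (is.null(x)) NA_real_
                   else x$metrics$nrmse, numeric(1)),
    r2 = vapply(calib, function(x) if (is.null(x)) NA_real_
                else x$metrics$r2, numeric(1)))
  size_dist <- fit_size_distribution(
    data.frame(N_i = pmap$N_i[ok], S_i = per_mn$S_i[ok]),
    delta_s = delta_s, n_pool = n_pool)

  kth <- NA_real_; cmd_fit <- NA_real_
  if (fit_derecruit) {
    kth <- suppressWarnings(fit_derecruitment(trains, current))
    if (is.null(cmd)) {
      cg <- suppressWarnings(
        calibrate_cmd(per_mn$S_i[ok], per_mn$IP_i[ok], trains[ok], current,
                      protocol, kth, kr = kr, cm = cm, dvth = dvth))
      cmd_fit <- cg$cmd
    } else cmd_fit <- cmd
  }

  # -- step 4: full-pool simulation -----------------------------------
  spec <- pool_spec(n_pool, size_dist, ip_dist, kth_ratio = kth,
                    cmd = cmd_fit, master_seed = master_seed, kr = kr,
                    cm = cm, dvth = dvth)
  pool <- simulate_pool(spec, current, protocol)
  end_nr <- effective_neural_drive(trains, protocol)
  metrics <- NULL
  if (!is.null(force))
    metrics <- list(
      end_n = validate_against_force(pool$end_n, force),
      end_nr = validate_against_force(end_nr$raw, force))

  structure(list(trains = trains, protocol = protocol, pool_map = pmap,
                 fth_dist = fth_dist, rheo = rheo, common_input = ci,
                 coherence = coh, current = current, per_mn = per_mn,
                 ip_dist = ip_dist, size_dist = size_dist,
                 kth_ratio = kth, cmd = cmd_fit, pool = pool,
                 end_nr = end_nr, metrics = metrics),
            class = "pool_reconstruction")
}

#' @export
print.pool_reconstruction <- function(x, ...) {
  cat(sprintf("<pool_reconstruction> %d identified MNs -> pool of %d\n",
              nrow(x$per_mn), x$pool$spec$n_pool))
  print(x$ip_dist); print(x$size_dist)
  if (!is.null(x$metrics)) {
    cat("  eND_N  vs force: "); print(x$metrics$end_n)
    cat("  eND_Nr vs force: "); print(x$metrics$end_nr)
  }
  invisible(x)
}

#' Leave-one-out validation of the reconstruction
#'
#' For each identified motoneuron `i`, repeats the common-input estimation
#' and the step-3 fits without train `i`, then predicts MN `i` with a LIF
#' model parameterized by `S(N_i)` and `IP(N_i)` read off the refitted
#' distributions, and scores the prediction against the held-out
#' experimental train (`dft1`, and nRMSE / r2 of the smoothed discharge
#' rates over the full protocol window).
#'
#' @param trains identified [spike_train()]s with thresholds.
#' @param protocol a [contraction_protocol()].
#' @param n_pool pool size.
#' @param fth_dist,rheo,delta_s,bounds,kr,cm,dvth as in
#'   [reconstruct_pool()].
#' @param kth_ratio,cmd derecruitment parameters reused across iterations
#'   (fit them on the full sample first, or leave `NA` to disable).
#' @param ip_anchor_points optional auxiliary IP anchors, as in
#'   [reconstruct_pool()].
#' @return A data.frame with one row per motoneuron: `i`, `N_i`, `dft1`,
#'   `nrmse`, `r2`.
#' @export
leave_one_out <- function(trains, protocol, n_pool = 400, fth_dist = NULL,
                          rheo = NULL, delta_s = 2.4,
                          bounds = c(1.0e-7, 5.0e-7), kth_ratio = NA_real_,
                          cmd = NA_real_, ip_anchor_points = NULL,
                          kr = default_kr(), cm = 1.3e-2, dvth = 0.027) {
  if (length(trains) < 3) stop("leave-one-out needs at least three MNs")
  if (is.null(fth_dist)) fth_dist <- ta_threshold_distribution(n_pool)
  if (is.null(rheo)) rheo <- rheobase_distribution(n_pool)
  trains <- order_by_threshold(trains)
  nr <- length(trains)
  th <- vapply(trains, function(tr) tr$recruitment_threshold, numeric(1))
  pmap_full <- map_to_pool(th, fth_dist)
  out <- vector("list", nr)
  for (i in seq_len(nr)) {
    rest <- trains[-i]
    rec <- tryCatch(
      reconstruct_pool(rest, force = NULL, protocol, n_pool = n_pool,
                       fth_dist = fth_dist, rheo = rheo, delta_s = delta_s,
                       bounds = bounds, run_coherence = FALSE,
                       fit_derecruit = !is.na(kth_ratio), cmd = cmd,
                       ip_anchor_points = ip_anchor_points, kr = kr,
                       cm = cm, dvth = dvth),
      error = function(e) NULL)
    if (is.null(rec)) next
    ni <- pmap_full$N_i[i]
    p <- lif_params_from_size(
      min(max(evaluate_size(rec$size_dist, ni), 5.01e-8), 9.99e-7),
      ip = evaluate_ip(rec$ip_dist, ni), kr = kr, cm = cm, dvth = dvth)
    d <- if (!is.na(rec$kth_ratio))
      derecruitment_variant(p, rec$kth_ratio,
                            cmd = if (is.na(rec$cmd)) cm else rec$cmd,
                            switch_time = protocol$t_tr[4])
    sim <- simulated_fidf(p, rec$current, protocol, derecruit = d)
    fid_exp <- filtered_idf(instantaneous_discharge_frequency(trains[[i]],
                                                              protocol))
    m <- compare_signals(sim$fidf, fid_exp)
    ft1_sim <- if (n_discharges(sim$train)) sim$train$firing_times[1]
               else NA_real_
    out[[i]] <- data.frame(i = i, N_i = ni,
                           dft1 = ft1_sim - trains[[i]]$firing_times[1],
                           nrmse = m$nrmse, r2 = m$r2)
  }
  do.call(rbind, out)
}

#' Sensitivity of the reconstruction to the assumed pool size
#'
#' Reruns the full pipeline for each candidate `N` and reports the
#' normalized effective-neural-drive validation metrics against the force
#' trace.
#'
#' @param trains,force,protocol as in [reconstruct_pool()].
#' @param n_values candidate pool sizes.
#' @param ... forwarded to [reconstruct_pool()].
#' @return A data.frame with columns `n_pool`, `nrmse`, `r2`.
#' @export
sensitivity_to_n <- function(trains, force, protocol,
                             n_values = c(length(trains), 100, 200, 300, 400),
                             ...) {
  rows <- lapply(n_values, function(n) {
    rec <- reconstruct_pool(trains, force, protocol, n_pool = n,
                            run_coherence = FALSE, ...)
    data.frame(n_pool = n, nrmse = rec$metrics$end_n$nrmse,
               r2 = rec$metrics$end_n$r2)
  })
  do.call(rbind, rows)
}
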