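#' Detect discharge-rate saturation and extract the inert period
#'
#' A motoneuron 'saturates' when its polynomial discharge-rate trendline
#' exceeds, somewhere during the force ramp `[t_tr1, t_tr2 - 1 s]`, 90% of
#' the mean trendline level `M` on the plateau `[t_tr2, t_tr3]`.  For a
#' saturating motoneuron the inert period is read off the trendline as
#' `IP = 1 / max(trend)`, which caps its maximum firing rate at
#' `max(trend)`.
#'
#' @param idf_trend a [rate_series()] of kind `"trend"` (from
#'   [polynomial_trend()]).
#' @param protocol a [contraction_protocol()].
#' @return A list with `saturating` (logical) and `ip` (s, `NA` when not
#'   saturating).
#' @export
detect_saturation <- function(idf_trend, protocol) {
  stopifnot(inherits(idf_trend, "rate_series"), idf_trend$kind == "trend")
  tt <- protocol$t_tr
  plateau <- idf_trend$times >= tt[3] & idf_trend$times <= tt[4]
  if (!any(plateau)) stop("trendline does not cover the force plateau")
  m <- mean(idf_trend$values[plateau])
  ramp <- idf_trend$times >= tt[2] & idf_trend$times <= tt[3] - 1
  sat <- any(ramp) && any(idf_trend$values[ramp] > 0.9 * m)
  list(saturating = sat,
       ip = if (sat) 1 / max(idf_trend$values) else NA_real_)
}

#' Inert-period distribution over the pool
#'
#' Power trendline `IP(j) = a j^b` least-squares fitted in log-log space
#' to the `(N_i, IP_i)` pairs of the saturating motoneurons; inert periods
#' of non-saturating motoneurons are predicted from it.
#'
#' @param pairs data.frame with columns `N_i` (pool location) and `IP_i`
#'   (s); at least two rows.
#' @return An object of class `ip_distribution` with fields `a`, `b`,
#'   `pairs`.
#' @export
fit_ip_distribution <- function(pairs) {
  stopifnot(all(c("N_i", "IP_i") %in% names(pairs)))
  if (nrow(pairs) < 2)
    stop(paste("at least two saturating MNs are required; append auxiliary",
               "anchor (N_i, IP_i) points for sparse samples"))
  fit <- stats::lm(log(IP_i) ~ log(N_i), data = pairs)
  structure(list(a = exp(stats::coef(fit)[[1]]), b = stats::coef(fit)[[2]],
                 pairs = pairs),
            class = "ip_distribution")
}

#' @export
print.ip_distribution <- function(x, ...) {
  cat(sprintf("<ip_distribution> IP(j) = %.3g * j^%.3g s (fit on %d MNs); 1/IP(1) = %.1f Hz\n",
              x$a, x$b, nrow(x$pairs), 1 / evaluate_ip(x, 1)))
  invisible(x)
}

#' Evaluate an inert-period distribution
#' @param dist an `ip_distribution`.
#' @param j pool index or vector.
#' @return Inert period(s) in seconds.
#' @export
evaluate_ip <- function(dist, j) {
  stopifnot(inherits(dist, "ip_distribution"))
  dist$a * j^dist$b
}

#' Size distribution over the pool
#'
#' Power-family distribution of motoneuron surface areas,
#' \deqn{S(j) = S_{min} \, \Delta_S^{(j/N)^{c}}}
#' with the fold range `delta_s` fixed (default 2.4).
#'
#' @param s_min surface area of the first unit (m^2).
#' @param c shape exponent.
#' @param delta_s size fold range (default 2.4).
#' @param n_pool pool size `N`.
#' @return An object of class `size_distribution`.
#' @export
size_distribution <- function(s_min, c, delta_s = 2.4, n_pool = 400) {
  stopifnot(s_min > 0, delta_s > 1, n_pool >= 2)
  structure(list(s_min = s_min, c = c, delta_s = delta_s,
                 n_pool = as.integer(n_pool)),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> S(j) = %.3g * %.2f^((j/%d)^%.3g) m^2, range [%.2f, %.2f] e-7 m^2\n",
              x$s_min, x$delta_s, x$n_pool, x$c,
              1e7 * evaluate_size(x, 1), 1e7 * evaluate_size(x, x$n_pool)))
  invisible(x)
}

#' Evaluate a size distribution
#' @param dist a [size_distribution()].
#' @param j pool index or vector, in `[1, n_pool]`.
#' @return Surface area(s) in m^2.
#' @export
evaluate_size <- function(dist, j) {
  stopifnot(inherits(dist, "size_distribution"))
  if (any(j < 1 - 1e-9 | j > dist$n_pool + 1e-9))
    stop("pool index out of [1, n_pool]")
  dist$s_min * dist$delta_s^((j / dist$n_pool)^dist$c)
}

#' Fit the pool size distribution to calibrated sizes
#'
#' Least-squares fit of `(s_min, c)` on the log scale with the fold range
#' `delta_s` held fixed.
#'
#' @param pairs data.frame with columns `N_i` and `S_i` (m^2); at least
#'   two rows.
#' @param delta_s fixed size fold range (default 2.4).
#' @param n_pool pool size `N`.
#' @return A [size_distribution()].
#' @export
fit_size_distribution <- function(pairs, delta_s = 2.4, n_pool = 400) {
  stopifnot(all(c("N_i", "S_i") %in% names(pairs)))
  if (nrow(pairs) < 2) stop("at least two (N_i, S_i) pairs are required")
  df <- data.frame(r = pairs$N_i / n_pool, y = log(pairs$S_i))
  fit <- minpack.lm::nlsLM(
    y ~ log(smin) + (r^cc) * log(delta_s),
    data = df, start = list(smin = exp(min(df$y)), cc = 1.5),
    lower = c(1e-9, 0.05), upper = c(1e-5, 20),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  size_distribution(cf[["smin"]], cf[["cc"]], delta_s = delta_s,
                    n_pool = n_pool)
}

simulated_fidf <- function(params, current, protocol, seed = 1,
                           derecruit = NULL, ip_noise = FALSE) {
  tr <- lif_simulate(params, current, seed = seed, derecruit = derecruit,
                     ip_noise = ip_noise)
  tr$sampling_rate <- protocol$sampling_rate
  idf <- instantaneous_discharge_frequency(tr, protocol)
  list(train = tr, fidf = filtered_idf(idf))
}

#' Calibrate the motoneuron size against its smoothed discharge rate
#'
#' Finds the size `S_i` minimizing the root-mean-square difference between
#' the LIF-predicted and the target (experimental) smoothed discharge
#' rates over `[t_tr0, (t_tr2 + t_tr3)/2]` (recruitment ramp and first
#' half of the plateau), by bounded scalar minimization.  Inert-period
#' noise is disabled so the objective is deterministic.
#'
#' @param target_fidf a [rate_series()] of kind `"FIDF"`: the target
#'   smoothed discharge rate.
#' @param ip inert period of this motoneuron (s).
#' @param current a `current_input`.
#' @param protocol a [contraction_protocol()].
#' @param bounds physiological size bracket (m^2), default
#'   `c(1.0e-7, 5.0e-7)`.
#' @param target_train optional [spike_train()] used for the
#'   recruitment-time error `dft1`; otherwise the onset of the target FIDF
#'   support is used.
#' @param kr,cm,dvth LIF constants, see [lif_params_from_size()].
#' @return A list with `size_s`, `objective` (RMS in Hz), and `metrics`
#'   (a [validation_metrics()] computed on `[t_tr0, t_tr3]`).
#' @export
calibrate_size <- function(target_fidf, ip, current, protocol,
                           bounds = c(1.0e-7, 5.0e-7), target_train = NULL,
                           kr = default_kr(), cm = 1.3e-2, dvth = 0.027) {
  stopifnot(inherits(target_fidf, "rate_series"))
  tt <- protocol$t_tr
  w_hi <- (tt[3] + tt[4]) / 2
  win <- target_fidf$times >= tt[1] & target_fidf$times <= w_hi
  target <- target_fidf$values[win]
  if (all(target == 0))
    stop(paste("target MN has no discharges in the calibration window",
               "(recruited after the current peak); its size cannot be",
               "calibrated"))
  penalty <- sqrt(mean(target^2)) * 10 + 1
  objective <- function(s) {
    p <- lif_params_from_size(s, ip = ip, kr = kr, cm = cm, dvth = dvth)
    sim <- simulated_fidf(p, current, protocol)
    if (n_discharges(sim$train) < 2) return(penalty)
    sqrt(mean((sim$fidf$values[win] - target)^2))
  }
  # a spike-less optimum at the most excitable end means the target MN is
  # never recruited by this current
  if (objective(bounds[1]) >= penalty && objective(bounds[2]) >= penalty)
    stop("no candidate size produces discharges under this current input")
  opt <- stats::optimize(objective, interval = bounds, tol = 1e-10)
  s_hat <- opt$minimum
  if (min(abs(s_hat - bounds)) < 1e-3 * diff(bounds))
    warning("size optimum at a calibration bound; possible model misfit")
  p <- lif_params_from_size(s_hat, ip = ip, kr = kr, cm = cm, dvth = dvth)
  sim <- simulated_fidf(p, current, protocol)
  mwin <- target_fidf$times >= tt[1] & target_fidf$times <= tt[4]
  a <- rate_series(target_fidf$times[mwin], sim$fidf$values[mwin], "FIDF")
  b <- rate_series(target_fidf$times[mwin], target_fidf$values[mwin], "FIDF")
  m <- compare_signals(a, b)
  ft1_exp <- if (!is.null(target_train) && length(target_train$firing_times))
    target_train$firing_times[1]
  else if (any(target > 0)) target_fidf$times[win][which(target > 0)[1]]
  else NA_real_
  ft1_sim <- if (n_discharges(sim$train)) sim$train$firing_times[1] else NA_real_
  m$dft1 <- ft1_sim - ft1_exp
  list(size_s = s_hat, objective = opt$objective, metrics = m)
}

#' Fit the derecruitment threshold ratio
#'
#' For each identified motoneuron the current at its first discharge
#' (recruitment) and at its last discharge (derecruitment) are read off
#' the common current input; the ratio `k_th^dth` is the zero-intercept
#' least-squares slope of derecruitment on recruitment current.  Values at
#' or above 1 are clipped just below 1 with a warning.
#'
#' @param trains list of identified [spike_train()]s.
#' @param current a `current_input`.
#' @return The fitted `k_th^dth` in `(0, 1)`.
#' @export
fit_derecruitment <- function(trains, current) {
  sig <- current_vector(current)
  at <- function(t) sig$values[which.min(abs(sig$times - t))]
  rec <- der <- numeric(0)
  for (tr in trains) {
    if (length(tr$firing_times) < 2) next
    rec <- c(rec, at(tr$firing_times[1]))
    der <- c(der, at(tr$firing_times[length(tr$firing_times)]))
  }
  if (!length(rec)) stop("no train with at least two discharges")
  k <- sum(rec * der) / sum(rec^2)
  if (k >= 1) {
    warning("fitted derecruitment ratio >= 1; clipped below 1")
    k <- 1 - 1e-6
  }
  k
}

#' Calibrate the derecruitment specific capacitance
#'
#' Grid search over `C_m^d` in `[cm, cmd_max]` at `grid_step` increments:
#' each candidate re-simulates the calibrated motoneurons with the
#' derecruitment variant active from `t_tr3` and scores the smoothed
#' discharge rates over the derecruitment window `[t_tr3, t_tr5]` with
#' \deqn{J(C_m) = (\overline{nRMSE} + 100 (1 - \overline{r^2})) / 2}
#' (equal-weight combination on a 0-100 scale).  The minimizing candidate
#' is returned; a boundary minimum triggers a warning.
#'
#' @param sizes calibrated sizes `S_i` (m^2), one per train.
#' @param ips inert periods (s), one per train.
#' @param trains identified [spike_train()]s (targets).
#' @param current a `current_input`.
#' @param protocol a [contraction_protocol()].
#' @param kth_ratio fitted derecruitment threshold ratio.
#' @param grid_step grid increment (F/m^2), default `0.1e-2` (0.1
#'   uF/cm^2).
#' @param cmd_max upper bound (F/m^2), default `3.0e-2`.
#' @param kr,cm,dvth LIF constants.
#' @return A list with `cmd` (F/m^2), `grid`, `score` (J per grid value).
#' @export
calibrate_cmd <- function(sizes, ips, trains, current, protocol, kth_ratio,
                          grid_step = 0.1e-2, cmd_max = 3.0e-2,
                          kr = default_kr(), cm = 1.3e-2, dvth = 0.027) {
  tt <- protocol$t_tr
  if (tt[6] <= tt[4]) stop("empty derecruitment window")
  grid <- seq(cm, cmd_max, by = grid_step)
  win <- NULL
  targets <- vector("list", length(trains))
  for (i in seq_along(trains)) {
    fid <- filtered_idf(instantaneous_discharge_frequency(trains[[i]],
                                                          protocol))
    if (is.null(win)) win <- fid$times >= tt[4] & fid$times <= tt[6]
    targets[[i]] <- fid$values[win]
  }
  score <- vapply(grid, function(cmd) {
    nr <- r2 <- numeric(0)
    for (i in seq_along(trains)) {
      p <- lif_params_from_size(sizes[i], ip = ips[i], kr = kr, cm = cm,
                                dvth = dvth)
      d <- derecruitment_variant(p, kth_ratio, cmd = cmd,
                                 switch_time = tt[4])
      sim <- simulated_fidf(p, current, protocol, derecruit = d)
      tgt <- targets[[i]]
      if (diff(range(tgt)) == 0) next
      sv <- sim$fidf$values[win]
      nr <- c(nr, sqrt(mean((sv - tgt)^2)) / diff(range(tgt)) * 100)
      r2 <- c(r2, if (stats::sd(sv) == 0) 0 else stats::cor(sv, tgt)^2)
    }
    (mean(nr) + 100 * (1 - mean(r2))) / 2
  }, numeric(1))
  best <- which.min(score)
  if (best == 1L || best == length(grid))
    warning("C_m^d score has no interior minimum; returning the boundary")
  list(cmd = grid[best], grid = grid, score = score)
}
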