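#' Synthetic fixture specification
#'
#' Defines a ground-truth motoneuron pool and contraction from which
#' synthetic spike trains and a biased identified subsample can be drawn,
#' emulating the statistical structure of trapezoidal HDEMG datasets:
#' a size-principle-ordered pool, a trapezoid common drive, and an
#' identification bias toward high-threshold units.
#'
#' @param n_pool pool size `N`.
#' @param protocol a [contraction_protocol()].
#' @param fth_dist a [threshold_distribution()] (truth).
#' @param size_dist a [size_distribution()] (truth).
#' @param ip_a,ip_b truth inert-period power-law coefficients
#'   (`IP(j) = a j^b`, seconds).
#' @param kth_ratio,cmd truth derecruitment parameters.
#' @param n_identified number of identified motoneurons `N_r`.
#' @param bias identification-bias exponent `beta >= 0`: motoneuron `j`
#'   is sampled with probability proportional to `(j/N)^beta` (0 =
#'   uniform; larger = stronger enrichment of high-threshold units).
#' @param threshold_jitter Gaussian jitter (s.d., %MVC) added to the
#'   recorded thresholds (default 0).
#' @param drive_noise_cv coefficient of variation of the band-limited
#'   (0-10 Hz) Gaussian fluctuations superimposed on the common drive
#'   (default 0.10), emulating the physiological common synaptic
#'   fluctuations that make cumulative spike trains of sub-populations
#'   coherent in the 1-10 Hz band.
#' @param master_seed master seed for the truth simulation.
#' @param kr,cm,dvth LIF constants.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_pool, protocol, fth_dist, size_dist, ip_a, ip_b,
                         kth_ratio = 0.9, cmd = 2.0e-2, n_identified = 32,
                         bias = 2, threshold_jitter = 0,
                         drive_noise_cv = 0.10, master_seed = 1,
                         kr = default_kr(), cm = 1.3e-2, dvth = 0.027) {
  stopifnot(n_identified <= n_pool, drive_noise_cv >= 0)
  ip_dist <- structure(list(a = ip_a, b = ip_b,
                            pairs = data.frame(N_i = integer(0),
                                               IP_i = numeric(0))),
                       class = "ip_distribution")
  structure(list(n_pool = as.integer(n_pool), protocol = protocol,
                 fth_dist = fth_dist, size_dist = size_dist,
                 ip_dist = ip_dist, kth_ratio = kth_ratio, cmd = cmd,
                 n_identified = as.integer(n_identified), bias = bias,
                 threshold_jitter = threshold_jitter,
                 drive_noise_cv = drive_noise_cv,
                 master_seed = master_seed, kr = kr, cm = cm, dvth = dvth),
            class = "fixture_spec")
}

#' Reference fixtures emulating the source datasets
#'
#' Returns a [fixture_spec()] whose protocol timing, plateau level and
#' `N_r` follow the corresponding source dataset, with truth distributions
#' set to the published threshold, size and inert-period fits:
#' `"DTA35-like"` (TA, 35 %MVC, `N_r = 32`), `"HTA35-like"` (TA, 35 %MVC,
#' `N_r = 21`), `"HTA50-like"` (TA, 50 %MVC, `N_r = 14`), `"HGM30-like"`
#' (GM, 30 %MVC, `N = 550`, `N_r = 27`).
#'
#' @param name fixture name.
#' @param n_identified override `N_r`.
#' @param bias identification-bias exponent (default 2).
#' @param master_seed master seed.
#' @param ... forwarded to [fixture_spec()].
#' @return A [fixture_spec()].
#' @export
make_reference_fixture <- function(name = c("DTA35-like", "HTA35-like",
                                            "HTA50-like", "HGM30-like"),
                                   n_identified = NULL, bias = 2,
                                   master_seed = 1, ...) {
  if (!is.character(name) || !name[1] %in% c("DTA35-like", "HTA35-like",
                                             "HTA50-like", "HGM30-like"))
    stop(paste("unknown fixture; available: DTA35-like, HTA35-like,",
               "HTA50-like, HGM30-like"))
  name <- match.arg(name)
  row <- switch(name,
    "DTA35-like" = list(mvc = 35, t = c(0, 2.2, 10.6, 20.5, 30, 30),
                        nr = 32, n = 400, ip_a = 0.04, ip_b = 0.06),
    "HTA35-like" = list(mvc = 35, t = c(0, 2.1, 10.5, 20.5, 30, 33),
                        nr = 21, n = 400, ip_a = 0.04, ip_b = 0.05),
    "HTA50-like" = list(mvc = 50, t = c(0, 1.6, 12, 21.8, 34.5, 35),
                        nr = 14, n = 400, ip_a = 0.04, ip_b = 0.06),
    "HGM30-like" = list(mvc = 30, t = c(0, 3.1, 9.1, 28, 33.5, 107),
                        nr = 27, n = 550, ip_a = 0.03, ip_b = 0.20))
  proto <- contraction_protocol(row$t, row$mvc)
  fixture_spec(
    n_pool = row$n, protocol = proto,
    fth_dist = ta_threshold_distribution(row$n),
    size_dist = size_distribution(1.49e-7, 1.47, delta_s = 2.4,
                                  n_pool = row$n),
    ip_a = row$ip_a, ip_b = row$ip_b,
    n_identified = if (is.null(n_identified)) row$nr else n_identified,
    bias = bias, master_seed = master_seed, ...)
}

#' Generate the ground truth of a fixture
#'
#' Builds the trapezoid-shaped common current drive, scaled so that the
#' fraction of the pool recruited on the plateau matches the threshold
#' distribution at the plateau %MVC (the plateau current sits between the
#' rheobases of the last recruited and the first non-recruited
#' motoneuron), then simulates the complete truth pool.
#'
#' @param spec a [fixture_spec()].
#' @return A list of class `fixture_truth` with `spec`, `current`
#'   (a `drive_signal`, ampere), `pool` (a `pool_result`), `drive_norm`
#'   (the normalized trapezoid used as force proxy) and `j_plateau` (the
#'   last recruited truth index).
#' @export
generate_truth <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_pool
  fthv <- evaluate_fth(spec$fth_dist, seq_len(n))
  j_star <- max(1L, sum(fthv <= spec$protocol$plateau_mvc))
  ith <- function(j)
    spec$dvth / (spec$kr / evaluate_size(spec$size_dist, j)^2.43)
  i_plateau <- if (j_star < n) (ith(j_star) + ith(j_star + 1)) / 2
               else ith(n) * 1.02
  wave <- trapezoid_wave(spec$protocol)
  v <- wave$values * i_plateau
  if (spec$drive_noise_cv > 0) {
    set.seed(spec$master_seed)
    z <- stats::rnorm(length(v))
    zf <- lowpass(drive_signal(wave$times, z, "current"), 10)$values
    zf <- zf / stats::sd(zf)
    v <- pmax(v * (1 + spec$drive_noise_cv * zf), 0)
  }
  current <- drive_signal(wave$times, v, role = "current")
  pspec <- pool_spec(n, spec$size_dist, spec$ip_dist,
                     kth_ratio = spec$kth_ratio, cmd = spec$cmd,
                     master_seed = spec$master_seed, kr = spec$kr,
                     cm = spec$cm, dvth = spec$dvth)
  pool <- simulate_pool(pspec, current, spec$protocol)
  structure(list(spec = spec, current = current, pool = pool,
                 drive_norm = normalize_peak(wave), j_plateau = j_star),
            class = "fixture_truth")
}

#' Draw a biased identified subsample from a fixture truth
#'
#' Samples `n_identified` firing motoneurons without replacement with
#' probability proportional to `(j/N)^bias`, mimicking the bias of HDEMG
#' decomposition toward large high-threshold units, records their
#' thresholds from the truth distribution (with optional jitter) and
#' returns them as an identified dataset together with the force proxy
#' (the normalized ground-truth drive).
#'
#' @param truth a `fixture_truth` from [generate_truth()].
#' @param n_identified number of identified units (default from the
#'   spec).
#' @param bias bias exponent (default from the spec).
#' @param seed sampling seed (default `master_seed + 1000`).
#' @return A list of class `fixture_dataset` with `trains` (identified
#'   [spike_train()]s, thresholds attached, ordered by threshold),
#'   `force` (force-proxy `drive_signal`), `protocol`, `true_idx` (truth
#'   pool indices of the sample).
#' @export
sample_identified <- function(truth, n_identified = NULL, bias = NULL,
                              seed = NULL) {
  stopifnot(inherits(truth, "fixture_truth"))
  spec <- truth$spec
  if (is.null(n_identified)) n_identified <- spec$n_identified
  if (is.null(bias)) bias <- spec$bias
  if (is.null(seed)) seed <- spec$master_seed + 1000
  # eligible units are recruited during the ramp or plateau, as HDEMG
  # decomposition identifies them; units first firing in the derecruitment
  # phase are artefacts of the threshold hysteresis and are never identified
  firing <- which(vapply(truth$pool$trains, function(tr)
    n_discharges(tr) >= 2 && tr$firing_times[1] < spec$protocol$t_tr[4],
    logical(1)))
  if (n_identified > length(firing))
    stop("fewer firing MNs than requested identified sample size")
  set.seed(seed)
  prob <- (firing / spec$n_pool)^bias
  idx <- sort(sample(firing, n_identified, prob = prob))
  fthv <- evaluate_fth(spec$fth_dist, idx)
  if (spec$threshold_jitter > 0) {
    fthv <- fthv + stats::rnorm(length(idx), 0, spec$threshold_jitter)
    fthv <- pmin(pmax(fthv, 0.01), 100)
  }
  trains <- vector("list", n_identified)
  for (k in seq_along(idx)) {
    tr <- truth$pool$trains[[idx[k]]]
    tr$mn_id <- k
    tr$recruitment_threshold <- fthv[k]
    trains[[k]] <- tr
  }
  structure(list(trains = trains, force = truth$drive_norm,
                 protocol = spec$protocol, true_idx = idx),
            class = "fixture_dataset")
}
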