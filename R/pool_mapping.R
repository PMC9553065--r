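#' Force recruitment-threshold distribution over a motoneuron pool
#'
#' Linear-exponential distribution of motor-unit force recruitment
#' thresholds across a pool of `n_pool` units ranked by increasing
#' threshold:
#' \deqn{F^{th}(j) = k_1 (k_2 \, j/N + \Delta_F^{(j/N)^{k_3}})}
#' with fold range `delta_f` between the last and first recruited units.
#'
#' @param k1 scale (%MVC).
#' @param k2 linear coefficient (unitless).
#' @param k3 exponent (unitless).
#' @param delta_f threshold fold range (`> 1`).
#' @param n_pool pool size `N`.
#' @return An object of class `threshold_distribution`.
#' @seealso [ta_threshold_distribution()] for the built-in tibialis
#'   anterior coefficients.
#' @export
threshold_distribution <- function(k1, k2, k3, delta_f = 120, n_pool = 400) {
  stopifnot(delta_f > 1, n_pool >= 2, k1 > 0)
  d <- structure(list(k1 = k1, k2 = k2, k3 = k3, delta_f = delta_f,
                      n_pool = as.integer(n_pool)),
                 class = "threshold_distribution")
  v <- evaluate_fth(d, seq_len(n_pool))
  if (any(diff(v) <= 0) || any(v <= 0))
    stop("threshold distribution must be positive and strictly increasing")
  d
}

#' @export
print.threshold_distribution <- function(x, ...) {
  cat(sprintf(
    "<threshold_distribution> Fth(j) = %.3g*(%.4g*j/N + %g^((j/N)^%.3g)), N = %d\n",
    x$k1, x$k2, x$delta_f, x$k3, x$n_pool))
  invisible(x)
}

#' Evaluate a threshold distribution
#'
#' @param dist a [threshold_distribution()].
#' @param j pool index (or vector), in `[1, n_pool]` (continuous values are
#'   allowed for root finding).
#' @return Force recruitment threshold(s) in %MVC.
#' @export
evaluate_fth <- function(dist, j) {
  stopifnot(inherits(dist, "threshold_distribution"))
  if (any(j < 1 - 1e-9 | j > dist$n_pool + 1e-9))
    stop("pool index out of [1, n_pool]")
  r <- j / dist$n_pool
  dist$k1 * (dist$k2 * r + dist$delta_f^(r^dist$k3))
}

#' Built-in tibialis anterior threshold distribution
#'
#' The published coefficients for the human tibialis anterior (TA):
#' `k1 = 0.50`, `k2 = 58.12`, `k3 = 1.83`, fold range 120.  The same
#' distribution is reused for the gastrocnemius medialis (GM), for which no
#' muscle-specific literature distribution is available.
#'
#' @param n_pool pool size (default 400 for TA; use 550 for GM).
#' @return A [threshold_distribution()].
#' @export
ta_threshold_distribution <- function(n_pool = 400) {
  threshold_distribution(0.50, 58.12, 1.83, delta_f = 120, n_pool = n_pool)
}

#' Built-in TA threshold step data
#'
#' Fraction of the motor-unit pool whose recruitment threshold falls in
#' each 10 %MVC bin.  The shipped table is a synthetic reconstruction
#' computed from the fitted TA threshold distribution (the literature
#' scatter data underlying the original partition are not machine-readable);
#' it reproduces the same step function that the distribution was fitted to.
#'
#' @return A data.frame with columns `bin_low`, `bin_high`, `fraction`.
#' @export
ta_fth_bins <- function() {
  path <- system.file("extdata", "ta_fth_bins_synthetic.csv",
                      package = "monpool", mustWork = TRUE)
  utils::read.csv(path)
}

#' Fit a threshold distribution to binned step data
#'
#' Builds the step function mapping each pool index `j` to the midpoint of
#' its 10 %MVC threshold bin, appends the boundary conditions
#' `F^th(1) = fth_first` and `F^th(N) = delta_f * fth_first` as heavily
#' weighted points (weight 100 per point), and least-squares fits the
#' linear-exponential form by Levenberg-Marquardt.
#'
#' @param step_distribution data.frame with columns `bin_low`, `bin_high`
#'   (in %MVC) and `fraction` (fractions summing to 1).
#' @param n_pool pool size `N`.
#' @param delta_f threshold fold range.
#' @param fth_first threshold of the first recruited unit (%MVC).
#' @param fth_last threshold of the last unit; defaults to
#'   `delta_f * fth_first` (the fold-range relation).
#' @param boundary_weight weight of each boundary point relative to a bin
#'   point.
#' @return A [threshold_distribution()].
#' @export
fit_threshold_distribution <- function(step_distribution, n_pool = 400,
                                       delta_f = 120, fth_first = 0.75,
                                       fth_last = delta_f * fth_first,
                                       boundary_weight = 100) {
  sd <- step_distribution
  stopifnot(all(c("bin_low", "bin_high", "fraction") %in% names(sd)))
  if (abs(sum(sd$fraction) - 1) > 1e-6)
    stop("bin fractions must sum to 1")
  if (nrow(sd) < 2) stop("at least two threshold bins are required")
  # step function: pool index j -> midpoint of its threshold bin
  counts <- round(sd$fraction * n_pool)
  counts[length(counts)] <- n_pool - sum(counts[-length(counts)])
  mid <- (sd$bin_low + sd$bin_high) / 2
  j <- seq_len(n_pool)
  target <- rep(mid, counts)
  jj <- c(j, 1, n_pool)
  yy <- c(target, fth_first, fth_last)
  wt <- c(rep(1, n_pool), boundary_weight, boundary_weight)
  r <- jj / n_pool
  fit <- minpack.lm::nlsLM(
    yy ~ k1 * (k2 * r + delta_f^(r^k3)),
    start = list(k1 = 0.5, k2 = 50, k3 = 1.5),
    weights = wt,
    lower = c(1e-4, 0, 0.2), upper = c(50, 500, 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  threshold_distribution(cf[["k1"]], cf[["k2"]], cf[["k3"]],
                         delta_f = delta_f, n_pool = n_pool)
}

#' Map identified motor units onto the complete pool
#'
#' Solves `F^th(N_i) = F_i^th` for each recorded threshold by monotone root
#' finding on the continuous index, then rounds to the nearest integer pool
#' location.  Thresholds below `F^th(1)` clamp to location 1 with a
#' warning; thresholds above `F^th(N)` are an error.  Ties and ordering
#' collisions are resolved by assigning consecutive increasing locations so
#' the map stays injective and order-preserving.
#'
#' @param thresholds numeric vector of recorded thresholds `F_i^th` (%MVC),
#'   sorted ascending (enforced).
#' @param dist a [threshold_distribution()].
#' @return A data.frame of class `pool_map` with columns `i` and `N_i`.
#' @export
map_to_pool <- function(thresholds, dist) {
  stopifnot(inherits(dist, "threshold_distribution"))
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  n <- dist$n_pool
  f1 <- evaluate_fth(dist, 1); fn <- evaluate_fth(dist, n)
  ni <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    fth <- thresholds[k]
    if (fth > fn)
      stop(sprintf("MN %d threshold %.2f %%MVC exceeds Fth(N) = %.2f %%MVC",
                   k, fth, fn))
    if (fth <= f1) {
      if (fth < f1 * (1 - 1e-9))
        warning(sprintf("MN %d threshold below Fth(1); clamped to location 1",
                        k))
      ni[k] <- 1
    } else {
      ni[k] <- stats::uniroot(function(x) evaluate_fth(dist, x) - fth,
                              c(1, n), tol = 1e-6)$root
    }
  }
  ni <- round(ni)
  for (k in seq_along(ni)[-1])           # enforce strictly increasing
    if (ni[k] <= ni[k - 1]) ni[k] <- ni[k - 1] + 1
  if (any(ni > n))
    stop("tie-breaking pushed a location beyond the pool size")
  structure(data.frame(i = seq_along(ni), N_i = as.integer(ni)),
            class = c("pool_map", "data.frame"))
}
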