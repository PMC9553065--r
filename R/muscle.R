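#' Distribution of motor-unit maximal tetanic forces
#'
#' Exponential (Fuglevand-style) distribution of maximal isometric tetanic
#' forces across the pool, `f(j) = f(1) * fold_range^((j-1)/(N-1))`,
#' normalized so the forces sum to 1 muscle-maximum unit.
#'
#' @param n_pool pool size.
#' @param fold_range ratio `f(N)/f(1)` (default 100).
#' @return Numeric vector of length `n_pool` summing to 1, strictly
#'   increasing for `fold_range > 1`.
#' @export
mu_force_distribution <- function(n_pool, fold_range = 100) {
  stopifnot(n_pool >= 1, fold_range >= 1)
  if (n_pool == 1) return(1)
  f <- fold_range^((seq_len(n_pool) - 1) / (n_pool - 1))
  f / sum(f)
}

#' Excitation-contraction coupling parameters
#'
#' Constants of the two-stage first-order activation model (all modelling
#' choices of this package, not literature values): free-calcium decay
#' time constant `tau_c`; calcium-troponin binding and unbinding rates
#' `k_b`, `k_u`; and the half-activation level `b50` of the saturating
#' (Hill, exponent 2) output nonlinearity.  The defaults give a twitch
#' rise time of roughly 50 ms and tetanic fusion near 100 Hz.
#'
#' @param tau_c calcium decay time constant (s).
#' @param k_b troponin binding rate (1/s).
#' @param k_u troponin unbinding rate (1/s).
#' @param b50 half-activation calcium-troponin level (normalized).
#' @return A list of class `activation_params`.
#' @export
activation_params <- function(tau_c = 0.02, k_b = 30, k_u = 15, b50 = 0.4) {
  stopifnot(tau_c > 0, k_b > 0, k_u > 0, b50 > 0)
  structure(list(tau_c = tau_c, k_b = k_b, k_u = k_u, b50 = b50),
            class = "activation_params")
}

#' Excitation-contraction coupling: spike train to active state
#'
#' Two first-order stages: each discharge injects a unit impulse into the
#' normalized free-calcium concentration `c(t)`, which decays with time
#' constant `tau_c`; the calcium-troponin concentration `b(t)` follows
#' `db/dt = k_b c - k_u b`; the active state is the saturating Hill
#' nonlinearity `a = b^2 / (b^2 + b50^2)`, bounded in `[0, 1)`.
#'
#' @param train a [spike_train()].
#' @param params an [activation_params()].
#' @param protocol a [contraction_protocol()] giving the simulation
#'   window.
#' @param dt integration step (s), at most 0.001.
#' @return A list of class `activation_trace` with `times`, `calcium`,
#'   `caltrop`, `a`.
#' @export
activation_dynamics <- function(train, params = activation_params(),
                                protocol, dt = 1e-3) {
  stopifnot(inherits(train, "spike_train"),
            inherits(params, "activation_params"))
  if (dt > 0.001 + 1e-12) stop("dt must be at most 0.001 s")
  t0 <- protocol$t_tr[1]
  n <- floor((protocol$t_tr[6] - t0) / dt) + 1L
  times <- t0 + (seq_len(n) - 1L) * dt
  imp <- numeric(n)
  if (length(train$firing_times)) {
    idx <- round((train$firing_times - t0) / dt) + 1L
    idx <- idx[idx >= 1L & idx <= n]
    for (i in idx) imp[i] <- imp[i] + 1
  }
  decay <- exp(-dt / params$tau_c)
  cal <- as.numeric(stats::filter(imp, decay, method = "recursive"))
  # forward-Euler first-order binding stage
  b <- as.numeric(stats::filter(dt * params$k_b * cal,
                                1 - dt * params$k_u, method = "recursive"))
  a <- b^2 / (b^2 + params$b50^2)
  structure(list(times = times, calcium = cal, caltrop = b, a = a),
            class = "activation_trace")
}

#' Steady-state active state under periodic stimulation
#'
#' Closed form of the stage ODE means under a periodic impulse train of
#' the given rate: mean calcium `c = rate * tau_c`, mean calcium-troponin
#' `b = k_b c / k_u`, active state `a = b^2/(b^2 + b50^2)`.  Used as the
#' analytic oracle for tetanic-fusion behaviour.
#'
#' @param rate discharge rate (Hz).
#' @param params an [activation_params()].
#' @return The asymptotic active state in `[0, 1)`.
#' @export
activation_steady_state <- function(rate, params = activation_params()) {
  b <- params$k_b * rate * params$tau_c / params$k_u
  b^2 / (b^2 + params$b50^2)
}

#' Simulate the whole-muscle force from motor-unit spike trains
#'
#' Each motor unit converts its spike train into an active state through
#' [activation_dynamics()] and produces
#' `f_j(t) = fiso_max(j) * a_j(t)` (force-length factor 1 at optimal
#' length, no force-velocity or passive terms); the whole-muscle force is
#' the linear summation `F(t) = sum_j f_j(t)`.
#'
#' @param trains list of [spike_train()]s (one motor unit each).
#' @param fiso_max vector of maximal tetanic forces, one per train (see
#'   [mu_force_distribution()]).
#' @param protocol a [contraction_protocol()].
#' @param params an [activation_params()].
#' @param dt integration step (s).
#' @return A [drive_signal()] with `role = "force"`.
#' @export
simulate_muscle <- function(trains, fiso_max, protocol,
                            params = activation_params(), dt = 1e-3) {
  stopifnot(length(trains) == length(fiso_max))
  acc <- NULL
  for (k in seq_along(trains)) {
    tr <- activation_dynamics(trains[[k]], params, protocol, dt = dt)
    contrib <- fiso_max[k] * tr$a
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  t0 <- protocol$t_tr[1]
  n <- floor((protocol$t_tr[6] - t0) / dt) + 1L
  if (is.null(acc)) acc <- numeric(n)
  drive_signal(t0 + (seq_len(n) - 1L) * dt, acc, role = "force")
}
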