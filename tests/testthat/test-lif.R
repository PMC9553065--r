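test_that("size-derived parameters obey the power laws and Ohm anchor", {
  p1 <- lif_params_from_size(2e-7, ip = 0.03)
  p2 <- lif_params_from_size(4e-7, ip = 0.03)
  expect_equal(p2$capacitance_c / p1$capacitance_c, 2, tolerance = 1e-12)
  expect_equal(p1$resistance_r / p2$resistance_r, 2^2.43, tolerance = 1e-12)
  for (p in list(p1, p2)) {
    expect_equal(p$rheobase * p$resistance_r, 0.027, tolerance = 1e-12)
    expect_equal(p$tau, p$resistance_r * p$capacitance_c, tolerance = 1e-12)
  }
  expect_error(lif_params_from_size(1e-8), "range")
  # published size distribution tops out near 0.36 mm^2
  sN <- evaluate_size(size_distribution(1.49e-7, 1.47), 400)
  expect_equal(signif(sN * 1e6, 2), 0.36)
})

test_that("default resistance anchor sits mid-range with the right span", {
  r_of <- function(s) default_kr() / s^2.43
  # anchored at 2 MOhm for the mid-range 0.25 mm^2 motoneuron
  expect_equal(r_of(2.5e-7), 2.0e6, tolerance = 1e-12)
  # the classic surface-area span maps to an ~8.4-fold resistance span
  expect_equal(r_of(0.15e-6) / r_of(0.36e-6), (0.36 / 0.15)^2.43,
               tolerance = 1e-9)
  expect_equal((0.36 / 0.15)^2.43, 8.4, tolerance = 0.01)
})

test_that("steady-state rate formula has the right limits", {
  p <- lif_params_from_size(2.5e-7, ip = 0.02)
  expect_error(steady_state_rate(p, p$rheobase * 0.9), "exceed")
  # near rheobase the log diverges: the rate falls monotonically to zero
  r <- vapply(c(1e-9, 1e-4, 1e-2, 0.5), function(eps)
    steady_state_rate(p, p$rheobase * (1 + eps)), numeric(1))
  expect_true(all(diff(r) > 0))
  expect_lt(r[1], 0.3 * r[4])
  # far above rheobase the rate saturates at 1/IP
  expect_equal(steady_state_rate(p, p$rheobase * 1e4), 1 / 0.02,
               tolerance = 0.01)
})

test_that("simulated interspike intervals match the closed form", {
  proto <- contraction_protocol(c(0, 0, 0, 8, 8, 8), 35)
  p <- lif_params_from_size(2.5e-7, ip = 0.03)
  cur <- constant_current(proto, 2 * p$rheobase)
  tr <- lif_simulate(p, cur, ip_noise = FALSE)
  isi <- diff(tr$firing_times)
  expect_lt(abs(mean(isi) - 1 / steady_state_rate(p, 2 * p$rheobase)),
            2 / 2048)
  # subthreshold current: silent
  sub <- lif_simulate(p, constant_current(proto, 0.5 * p$rheobase),
                      ip_noise = FALSE)
  expect_equal(n_discharges(sub), 0)
})

test_that("simulation is deterministic and IP noise has zero mean", {
  proto <- contraction_protocol(c(0, 0, 0, 20, 20, 20), 35)
  p <- lif_params_from_size(2e-7, ip = 0.025)
  cur <- constant_current(proto, 5 * p$rheobase)
  a <- lif_simulate(p, cur, seed = 9)
  b <- lif_simulate(p, cur, seed = 9)
  expect_identical(a$firing_times, b$firing_times)
  d <- lif_simulate(p, cur, seed = 10)
  expect_false(identical(a$firing_times, d$firing_times))
  # at I >> Ith the mean ISI equals IP up to Monte-Carlo and charge time
  isi <- diff(lif_simulate(p, constant_current(proto, 30 * p$rheobase),
                           seed = 3)$firing_times)
  charge <- -p$tau * log(1 - p$dvth / (p$resistance_r * 30 * p$rheobase))
  expect_lt(abs(mean(isi) - (p$ip + charge)),
            3 * p$ip / 10 / sqrt(length(isi)) + 2 / 2048)
})

test_that("forward scheme tracks the exact integrator within 1%", {
  proto <- contraction_protocol(c(0, 0, 0, 5, 5, 5), 35,
                                sampling_rate = 1e4) # dt = 1e-4 s
  p <- lif_params_from_size(2.5e-7, ip = 0.03) # tau ~ 6.5 ms >= 5 ms
  cur <- constant_current(proto, 1.5 * p$rheobase)
  a <- lif_simulate(p, cur, ip_noise = FALSE, scheme = "forward")
  b <- lif_simulate(p, cur, ip_noise = FALSE, scheme = "exact")
  ra <- 1 / mean(diff(a$firing_times))
  rb <- 1 / mean(diff(b$firing_times))
  expect_lt(abs(ra - rb) / rb, 0.01)
})

test_that("derecruitment variant lowers the threshold as specified", {
  p <- lif_params_from_size(2.5e-7, ip = 0.03)
  d <- derecruitment_variant(p, 0.9, cmd = 2e-2, switch_time = 5)
  expect_equal(d$rd, p$resistance_r / 0.9, tolerance = 1e-12)
  expect_equal(p$dvth / d$rd, 0.9 * p$rheobase, tolerance = 1e-12)
  expect_error(derecruitment_variant(p, 1), "strictly inside")
  expect_error(derecruitment_variant(p, 0.9, cmd = 1e-3), "at least")
  # a current between the two thresholds sustains firing only after the
  # switch
  proto <- contraction_protocol(c(0, 0, 0, 10, 10, 10), 35)
  cur <- constant_current(proto, 0.95 * p$rheobase)
  base <- lif_simulate(p, cur, ip_noise = FALSE)
  expect_equal(n_discharges(base), 0)
  hyst <- lif_simulate(p, cur, ip_noise = FALSE,
                       derecruit = derecruitment_variant(p, 0.9,
                                                         switch_time = 5))
  expect_gt(n_discharges(hyst), 0)
  expect_true(all(hyst$firing_times >= 5))
})

test_that("recruitment order follows size for a rising ramp", {
  proto <- contraction_protocol(c(0, 0.5, 8, 9, 9.5, 10), 35)
  wave <- trapezoid_wave(proto)
  sizes <- seq(1.5e-7, 3.5e-7, length.out = 8)
  i_top <- 0.027 / (default_kr() / max(sizes)^2.43) * 1.2
  cur <- drive_signal(wave$times, wave$values * i_top, "current")
  first <- vapply(sizes, function(s) {
    tr <- lif_simulate(lif_params_from_size(s, ip = 0.03), cur,
                       ip_noise = FALSE)
    if (n_discharges(tr)) tr$firing_times[1] else Inf
  }, numeric(1))
  expect_true(all(diff(first) >= 0))
})
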