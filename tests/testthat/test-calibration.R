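test_that("saturation detection follows the plateau-relative rule", {
  proto <- short_protocol()
  g <- seq(0.5, 8.5, by = 1 / 64)
  # constant trend: saturating, IP the reciprocal rate
  const <- rate_series(g, rep(12, length(g)), "trend")
  det <- detect_saturation(const, proto)
  expect_true(det$saturating)
  expect_equal(det$ip, 1 / 12, tolerance = 1e-12)
  # linear ramp reaching the plateau mean only at t_tr2: not saturating
  ramp_val <- approx(c(0.5, 3, 8.5), c(0, 10, 10), xout = g)$y
  # keep the pre-plateau values below 0.9 * plateau mean before t_tr2 - 1 s
  ramp_val[g < 2] <- ramp_val[g < 2] * 0.5
  ramp <- rate_series(g, ramp_val, "trend")
  det2 <- detect_saturation(ramp, proto)
  expect_false(det2$saturating)
  # saturating mid-ramp with plateau max 25 Hz: IP = 40 ms
  sat_val <- approx(c(0.5, 1.5, 8.5), c(0, 25, 25), xout = g)$y
  det3 <- detect_saturation(rate_series(g, sat_val, "trend"), proto)
  expect_true(det3$saturating)
  expect_equal(det3$ip, 0.04, tolerance = 1e-9)
})

test_that("IP distribution fit recovers exact generating coefficients", {
  j <- c(10, 40, 90, 160, 250, 330)
  pairs <- data.frame(N_i = j, IP_i = 0.03 * j^0.2)
  fit <- fit_ip_distribution(pairs)
  expect_equal(fit$a, 0.03, tolerance = 1e-4)
  expect_equal(fit$b, 0.2, tolerance = 1e-4)
  # published DTA35-style fit implies 25 Hz for the first motoneuron
  lit <- structure(list(a = 0.04, b = 0.05, pairs = pairs),
                   class = "ip_distribution")
  expect_equal(1 / evaluate_ip(lit, 1), 25)
  expect_error(fit_ip_distribution(pairs[1, ]), "anchor")
})

test_that("size distribution fit recovers exact generating coefficients", {
  truth <- size_distribution(1.49e-7, 1.47, n_pool = 400)
  j <- c(9, 60, 120, 180, 250, 313)
  pairs <- data.frame(N_i = j, S_i = evaluate_size(truth, j))
  fit <- fit_size_distribution(pairs, n_pool = 400)
  expect_equal(fit$s_min, 1.49e-7, tolerance = 1e-4)
  expect_equal(fit$c, 1.47, tolerance = 1e-4)
  # non-monotone pairs still give a monotone functional form
  pairs2 <- pairs; pairs2$S_i[3] <- pairs2$S_i[3] * 1.3
  fit2 <- fit_size_distribution(pairs2, n_pool = 400)
  expect_true(all(diff(evaluate_size(fit2, 1:400)) > 0))
})

test_that("size calibration recovers a known generating size", {
  proto <- short_protocol()
  wave <- trapezoid_wave(proto)
  s_star <- 2.5e-7
  p_star <- lif_params_from_size(s_star, ip = 0.04)
  cur <- structure(list(signal = drive_signal(wave$times,
                                              wave$values * 2.2 *
                                                p_star$rheobase,
                                              "current"),
                        gain = 1, onset_time = 0),
                   class = "current_input")
  target <- simulated_fidf(p_star, cur, proto)
  res <- calibrate_size(target$fidf, ip = 0.04, cur, proto,
                        target_train = target$train)
  expect_lt(abs(res$size_s - s_star) / s_star, 0.02)
  expect_lt(abs(res$metrics$dft1), 0.05)
  expect_gt(res$metrics$r2, 0.99)
  # minimizer property: J at the optimum is below J at +/- 10% probes
  expect_lt(res$objective,
            calibrate_size(target$fidf, 0.04, cur, proto,
                           bounds = c(s_star * 1.1, s_star * 1.2))$objective)
  # a target silent in the calibration window cannot be calibrated
  empty <- rate_series(target$fidf$times, 0 * target$fidf$values, "FIDF")
  expect_error(calibrate_size(empty, 0.04, cur, proto), "calibration window")
})

test_that("derecruitment ratio is recovered from constructed currents", {
  proto <- short_protocol()
  g <- protocol_grid(proto)
  # triangular current: each unit is recruited at I and derecruited at 0.9 I
  rise <- approx(c(0, 5, 10), c(0, 10e-9, 0), xout = g)$y
  cur <- structure(list(signal = drive_signal(g, rise, "current")),
                   class = "current_input")
  trains <- lapply(seq(2e-9, 8e-9, length.out = 8), function(i_rec) {
    t_on <- 5 * i_rec / 10e-9
    t_off <- 10 - 5 * (0.9 * i_rec) / 10e-9
    spike_train(c(t_on, seq(t_on + 0.05, t_off, by = 0.05)))
  })
  k <- fit_derecruitment(trains, cur)
  expect_lt(abs(k - 0.9) / 0.9, 0.02)
  # identical recruitment and derecruitment currents: k clipped at 1
  sym <- lapply(seq(2e-9, 8e-9, length.out = 5), function(i_rec) {
    t_on <- 5 * i_rec / 10e-9
    spike_train(c(t_on, seq(t_on + 0.05, 10 - t_on, by = 0.05)))
  })
  expect_warning(k2 <- fit_derecruitment(sym, cur), "clipped")
  expect_lt(k2, 1)
})

test_that("Cmd grid search recovers the generating capacitance", {
  # matched-current recovery on a handful of pool units
  truth <- dta35_truth()
  fx <- truth$spec
  idx <- round(seq(130, 330, length.out = 6))
  sizes <- evaluate_size(fx$size_dist, idx)
  ips <- evaluate_ip(fx$ip_dist, idx)
  trains <- lapply(seq_along(idx), function(k) {
    p <- lif_params_from_size(sizes[k], ip = ips[k])
    d <- derecruitment_variant(p, 0.9, cmd = 2.0e-2,
                               switch_time = fx$protocol$t_tr[4])
    s <- lif_simulate(p, truth$current, seed = 200 + k, derecruit = d)
    s$sampling_rate <- fx$protocol$sampling_rate
    s
  })
  cur <- structure(list(signal = truth$current), class = "current_input")
  cc <- calibrate_cmd(sizes, ips, trains, cur, fx$protocol,
                      kth_ratio = 0.9)
  expect_lt(abs(cc$cmd - 2.0e-2), 0.1e-2 + 1e-9) # within one grid step
})
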