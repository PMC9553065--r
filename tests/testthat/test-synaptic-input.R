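test_that("rheobase distribution matches the published span", {
  rh <- rheobase_distribution(400)
  expect_equal(signif(evaluate_rheobase(rh, 400) * 1e9, 3), 35.5)
  expect_equal(evaluate_rheobase(rh, 1), 3.9e-9, tolerance = 1e-3)
  v <- evaluate_rheobase(rh, 1:400)
  expect_true(all(diff(v) > 0))
  expect_error(evaluate_rheobase(rh, 0.5), "out of")
})

test_that("common-input estimate recovers a trapezoid drive shape", {
  proto <- short_protocol()
  truth <- trapezoid_wave(proto)
  set.seed(2)
  # twenty regularly firing units recruited along the ramp
  trains <- lapply(1:20, function(k) {
    on <- 1 + 2 * (k / 20)
    off <- 9 - 1.5 * (k / 20)
    periodic_train(8 + 6 * runif(1), on + runif(1, 0, 0.1), off,
                   mn_id = k)
  })
  ci <- estimate_common_input(trains, proto)
  m <- compare_signals(ci$csc_norm, normalize_peak(truth))
  expect_gt(m$r2, 0.9)
  expect_error(estimate_common_input(list(), proto), "at least two")
})

test_that("coherence is high for duplicated halves and low without common drive", {
  proto <- contraction_protocol(c(0, 0, 0, 12, 12, 12), 35)
  set.seed(7)
  # renewal trains with a 40 ms refractory floor (no grid collisions)
  renewal <- function(n) {
    ft <- cumsum(0.04 + stats::rexp(n, 30)) + 0.2
    ft[ft < 11.8]
  }
  base <- lapply(1:6, function(k) spike_train(renewal(150), mn_id = k))
  dup <- c(base, lapply(base, function(tr) {
    tr$mn_id <- tr$mn_id + 6L
    tr$firing_times <- tr$firing_times + 2e-3 # avoid exact coincidence
    tr
  }))
  force <- trapezoid_wave(contraction_protocol(c(0, 1, 4, 9, 11, 12), 35))
  # two identical half-populations: coherence of their CSTs is ~1
  c1 <- cumulative_spike_train(base, proto)
  c2 <- cumulative_spike_train(dup[7:12], proto)
  co12 <- welch_coherence(c1$values, c2$values, 2048)
  expect_gt(mean(co12$coherence[co12$freq >= 1 & co12$freq <= 10]), 0.9)
  co_dup <- coherence_representativeness(dup, force, proto, n_perm = 5,
                                         seed = 1)
  # independent renewal trains: near the estimator bias floor
  indep <- lapply(1:12, function(k) spike_train(renewal(150), mn_id = k))
  co_ind <- coherence_representativeness(indep, force, proto, n_perm = 5,
                                         seed = 1)
  expect_lt(co_ind$half_sample_mean, 0.2)
  expect_false(co_ind$representative)
  expect_gt(co_dup$half_sample_mean, co_ind$half_sample_mean)
})

test_that("current input honours both rheobase anchors", {
  proto <- short_protocol()
  set.seed(3)
  trains <- lapply(1:6, function(k)
    periodic_train(10, 1 + 0.8 * k, 8.5, mn_id = k,
                   fth = evaluate_fth(ta_threshold_distribution(400),
                                      30 + 50 * k)))
  pm <- map_to_pool(vapply(trains, function(x) x$recruitment_threshold,
                           numeric(1)),
                    ta_threshold_distribution(400))
  rh <- rheobase_distribution(400)
  ci <- estimate_common_input(trains, proto)
  cur <- build_current_input(ci$csi, pm, rh, trains)
  at <- function(t) cur$signal$values[which.min(abs(cur$signal$times - t))]
  i1 <- evaluate_rheobase(rh, pm$N_i[1])
  iN <- evaluate_rheobase(rh, pm$N_i[6])
  expect_lt(abs(at(trains[[1]]$firing_times[1]) - i1) / i1, 1e-3)
  expect_lt(abs(at(trains[[6]]$firing_times[1]) - iN) / iN, 1e-3)
  # zero before onset, positive gain for increasing CSI
  expect_true(all(cur$signal$values[cur$signal$times <
                                      cur$onset_time] == 0))
  expect_gt(cur$gain, 0)
})

test_that("degenerate CSI spread is rejected with guidance", {
  proto <- short_protocol()
  tr1 <- periodic_train(10, 2, 8, mn_id = 1, fth = 5)
  tr2 <- tr1; tr2$mn_id <- 2L; tr2$recruitment_threshold <- 5.1
  tr2$firing_times <- tr2$firing_times + 1e-3
  pm <- structure(data.frame(i = 1:2, N_i = c(10L, 11L)),
                  class = c("pool_map", "data.frame"))
  csi <- drive_signal(protocol_grid(proto),
                      rep(1, length(protocol_grid(proto))), "CSI")
  expect_error(build_current_input(csi, pm, rheobase_distribution(400),
                                   list(tr1, tr2)),
               "better-spread")
})
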