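test_that("spike_train validates its invariants", {
  expect_error(spike_train(c(1, 0.5)), "strictly increasing")
  expect_error(spike_train(c(-1, 2)), "non-negative")
  expect_error(spike_train(1:3, recruitment_threshold = 150), "MVC")
  tr <- spike_train(c(1, 2, 3), mn_id = 5, recruitment_threshold = 12)
  expect_s3_class(tr, "spike_train")
  expect_equal(n_discharges(tr), 3)
})

test_that("binarize conserves discharge count and rejects bad input", {
  proto <- short_protocol()
  expect_equal(sum(binarize(spike_train(numeric(0)), proto)$values), 0)
  b <- binarize(spike_train(c(1.0, 2.0)), proto)
  expect_equal(sum(b$values), 2)
  expect_equal(b$values[round(1.0 * 2048) + 1], 1)
  expect_error(binarize(spike_train(c(1, 11)), proto), "outside the protocol")
  # two firings within one grid step collide on a sample
  dt <- 1 / 2048
  clash <- spike_train(c(1.0, 1.0 + dt / 4))
  expect_error(binarize(clash, proto), "same grid sample")
  expect_warning(b2 <- binarize(clash, proto, merge_coincident = TRUE),
                 "merged")
  expect_equal(sum(b2$values), 1)
})

test_that("IDF places reciprocal-interval impulses at firing instants", {
  proto <- short_protocol()
  idf <- instantaneous_discharge_frequency(spike_train(c(1.0, 1.1, 1.3)),
                                           proto)
  nz <- which(idf$values > 0)
  expect_equal(length(nz), 2)
  expect_equal(idf$values[nz], c(10, 5), tolerance = 1e-9)
  expect_equal(idf$times[nz], c(1.0, 1.1), tolerance = 1e-3)
  # uniform train: all impulses at the common rate
  u <- instantaneous_discharge_frequency(periodic_train(10, 1, 5), proto)
  expect_true(all(abs(u$values[u$values > 0] - 10) < 1e-9))
  # single spike: degenerate flagged series
  s <- instantaneous_discharge_frequency(spike_train(2), proto)
  expect_true(s$empty)
  expect_true(all(s$values == 0))
})

test_that("FIDF of a periodic train converges to its rate", {
  proto <- contraction_protocol(c(0, 0, 0, 10, 10, 10), 35)
  idf <- instantaneous_discharge_frequency(periodic_train(8, 0.2, 9.8),
                                           proto)
  fidf <- filtered_idf(idf)
  interior <- fidf$times > 1 & fidf$times < 9
  expect_true(all(abs(fidf$values[interior] - 8) / 8 < 0.01))
  # all-zero IDF stays zero
  z <- rate_series(protocol_grid(proto),
                   numeric(length(protocol_grid(proto))), "IDF-impulse")
  expect_true(all(filtered_idf(z)$values == 0))
  # the smoother is supported only near discharges: a single-interval train
  # yields its rate on the window support and zero far away
  one <- instantaneous_discharge_frequency(spike_train(c(5, 5.1)), proto)
  f1 <- filtered_idf(one)
  expect_equal(f1$values[which.min(abs(f1$times - 5))], 10, tolerance = 1e-6)
  expect_equal(f1$values[which.min(abs(f1$times - 8))], 0)
  expect_error(filtered_idf(one, window_s = 1e-4), "window")
})

test_that("polynomial trend reproduces polynomial rates and degrades safely", {
  proto <- contraction_protocol(c(0, 0, 0, 10, 10, 10), 35)
  # build a train whose IDF values lie exactly on a quadratic in time
  ft <- seq(1, 9, by = 0.1)
  q <- function(t) 10 + 2 * (t - 5) + 0.3 * (t - 5)^2
  grid <- protocol_grid(proto)
  idf <- rate_series(grid, numeric(length(grid)), "IDF-impulse")
  k <- round(ft * 2048) + 1
  idf$values[k] <- q(grid[k]) # values exactly on the quadratic
  tre <- polynomial_trend(idf, order = 2)
  expect_lt(max(abs(tre$values - q(tre$times))), 1e-8)
  # noisy constant-rate train: trend close to the constant
  set.seed(1)
  idf2 <- idf
  idf2$values[k] <- 10 + rnorm(length(k), 0, 0.5)
  tre2 <- polynomial_trend(idf2, order = 6)
  expect_true(max(abs(tre2$values - 10)) < 1.5)
  # too few points: order reduced with a warning
  idf3 <- rate_series(idf$times, 0 * idf$values, "IDF-impulse")
  idf3$values[round(c(1, 2, 3, 4, 5) * 2048) + 1] <- c(9, 10, 11, 10, 9)
  expect_warning(polynomial_trend(idf3, order = 6), "reduced to 4")
})

test_that("cumulative spike train is a conservative per-sample sum", {
  proto <- short_protocol()
  a <- periodic_train(10, 1, 4, mn_id = 1)
  b <- periodic_train(7, 5, 8, mn_id = 2)
  one <- cumulative_spike_train(list(a), proto)
  expect_equal(one$values, binarize(a, proto)$values)
  both <- cumulative_spike_train(list(a, b), proto)
  expect_equal(sum(both$values), n_discharges(a) + n_discharges(b))
  dup <- cumulative_spike_train(list(a, a), proto)
  expect_equal(dup$values, 2 * binarize(a, proto)$values)
  expect_error(cumulative_spike_train(list(), proto), "at least one")
})
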