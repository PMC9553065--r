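# Shared fixtures.  Expensive objects are built once per test run and
# memoised here; everything is generated in code (no stored data).

.cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

# short trapezoid protocol for unit tests (zero hold, 2 s ramps, 4 s plateau)
short_protocol <- function(fs = 2048)
  contraction_protocol(c(0, 1, 3, 7, 9, 10), plateau_mvc = 35,
                       sampling_rate = fs)

# periodic spike train at a given rate over [from, to]
periodic_train <- function(rate, from, to, mn_id = 1L, fth = NA_real_)
  spike_train(seq(from, to, by = 1 / rate), mn_id = mn_id,
              recruitment_threshold = fth)

# constant-current drive on a protocol grid
constant_current <- function(protocol, amps) {
  g <- protocol_grid(protocol)
  drive_signal(g, rep(amps, length(g)), role = "current")
}

# reference fixture truth, generated once (DTA35-like defaults, seed 1)
dta35_truth <- function()
  memo("dta35_truth", generate_truth(make_reference_fixture("DTA35-like")))

# biased identified dataset drawn from the reference truth
dta35_dataset <- function()
  memo("dta35_dataset", sample_identified(dta35_truth()))

# full four-step reconstruction of the biased dataset
dta35_reconstruction <- function()
  memo("dta35_recon", {
    ds <- dta35_dataset()
    suppressWarnings(reconstruct_pool(ds$trains, ds$force, ds$protocol,
                                      n_pool = 400, master_seed = 1,
                                      run_coherence = FALSE))
  })

# twenty identified units evenly spread over the recruited pool (clean
# thresholds), for leave-one-out validation
dta35_spread_dataset <- function()
  memo("dta35_spread", {
    truth <- dta35_truth()
    fx <- truth$spec
    eligible <- which(vapply(truth$pool$trains, function(x)
      n_discharges(x) >= 2 && x$firing_times[1] < fx$protocol$t_tr[4],
      logical(1)))
    idx <- eligible[round(seq(1, length(eligible), length.out = 20))]
    trains <- lapply(seq_along(idx), function(k) {
      x <- truth$pool$trains[[idx[k]]]
      x$mn_id <- k
      x$recruitment_threshold <- evaluate_fth(fx$fth_dist, idx[k])
      x
    })
    list(trains = trains, force = truth$drive_norm,
         protocol = fx$protocol, true_idx = idx)
  })
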