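# FRET efficiency, state calling, dwell times, rates

test_that("efficiency is the acceptor fraction with invalid frames flagged", {
  tr <- fret_trace(donor = c(100, 200, 0, 0), acceptor = c(100, 0, 300, 0),
                   dt = 0.1)
  E <- fret_efficiency(tr)
  expect_equal(E[1], 0.5)
  expect_equal(E[2], 0)
  expect_equal(E[3], 1)
  expect_true(is.na(E[4]))
})

test_that("state calling handles constant, square-wave, and noisy traces", {
  expect_equal(call_states(rep(0.9, 50), window = 1),
               rep(1L, 50))
  # noiseless square wave: transitions within half a window of the switches
  E <- rep(c(0.1, 0.9), each = 25, times = 4)
  st <- call_states(E, window = 5, low_thr = 0.4, high_thr = 0.6)
  truth <- rep(c(0L, 1L), each = 25, times = 4)
  expect_lte(sum(st != truth), 2 * 8)  # <= window//2 frames per switch
  expect_error(call_states(rep(0.5, 10), window = 11), "shorter")
})

test_that("state calling recovers >=99% of telegraph ground truth", {
  sim <- gen_fret_telegraph(0.5, 0.5, dt = 0.05, duration = 2000,
                            noise_sd = 0.1, seed = 77)
  st <- call_states(fret_efficiency(sim$trace), window = 1,
                    low_thr = 0.4, high_thr = 0.6)
  expect_gte(mean(st == sim$states), 0.99)
  # smoothing trades a ~1-frame delay per transition for noise robustness
  st5 <- call_states(fret_efficiency(sim$trace), window = 5,
                     low_thr = 0.4, high_thr = 0.6)
  expect_gte(mean(st5 == sim$states), 0.97)
})

test_that("dwell enumeration and edge policies", {
  # both 1-runs touch the trace edges and are censored
  d1 <- dwell_times(c(1, 1, 1, 0, 0, 1, 1), dt = 1)
  expect_length(d1$on, 0)
  expect_equal(d1$off, 2)
  d2 <- dwell_times(c(0, 1, 1, 0, 1, 0), dt = 0.5)
  expect_equal(sort(d2$on), c(0.5, 1.0))
  expect_equal(d2$off, 0.5)
  # conservation: dwells plus censored edges account for the whole trace
  set.seed(2)
  states <- rbinom(500, 1, 0.5)
  d3 <- dwell_times(states, dt = 0.2)
  expect_equal(sum(d3$on) + sum(d3$off) + d3$dropped, 500 * 0.2)
  d4 <- dwell_times(states, dt = 0.2, edge_policy = "keep")
  expect_equal(sum(d4$on) + sum(d4$off), 500 * 0.2)
})

test_that("rates follow from mean dwells with the probe concentration", {
  dw <- structure(list(on = rep(2, 10), off = rep(5, 10), dropped = 0,
                       edge_policy = "drop_partial"), class = "dwell_set")
  rm <- rates_from_dwells(dw, conc = 20e-9, seed = 1)
  expect_equal(rm$koff, 0.5)
  expect_equal(rm$kon, 1 / (20e-9 * 5))  # 1e7 / (M s)
  expect_error(rates_from_dwells(
    structure(list(on = 1, off = numeric(0), dropped = 0,
                   edge_policy = "drop_partial"), class = "dwell_set"),
    conc = 20e-9), "insufficient")
})

test_that("trace pipeline recovers generating rates (single condition)", {
  conc <- 20e-9
  kon_c <- 0.5; koff <- 0.5
  rm <- run_trace_pipeline(kon_c, koff, n_traces = 200, duration = 60,
                           dt = 0.0125, conc = conc, seed = 3)
  expect_lt(abs(rm$kon - kon_c / conc), 2 * rm$kon_sem)
  expect_lt(abs(rm$koff - koff), 2 * rm$koff_sem)
  # analytic exponential-dwell SEM agrees with the bootstrap SEM
  expect_lt(abs(rm$kon_sem_analytic - rm$kon_sem) / rm$kon_sem, 0.3)
  expect_lt(abs(rm$koff_sem_analytic - rm$koff_sem) / rm$koff_sem, 0.3)
})

test_that("auto thresholds straddle the two efficiency modes", {
  set.seed(6)
  E <- c(rnorm(3000, 0.2, 0.08), rnorm(3000, 0.8, 0.08))
  thr <- auto_thresholds(E)
  expect_gt(thr[["low"]], 0.25)
  expect_lt(thr[["high"]], 0.75)
  expect_equal(thr[["high"]] - thr[["low"]], 0.2, tolerance = 1e-9)
})

test_that("rates tables round-trip through the interchange CSV", {
  dw <- structure(list(on = rexp(20, 0.5), off = rexp(20, 0.1),
                       edges = data.frame(state = integer(0),
                                          duration = numeric(0),
                                          exit_observed = logical(0)),
                       dropped = 0, dt = 0.05, edge_policy = "drop_partial"),
                  class = "dwell_set")
  rm1 <- rates_from_dwells(dw, conc = 20e-9, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rates_csv(list(rm1), sequence = "GTAAATTCA", force = 3.8,
                  force_err = 0.4, path = path)
  back <- read_rates_csv(path)
  expect_equal(back$kon, rm1$kon)
  expect_equal(back$force, 3.8)
  expect_equal(back$sequence, "GTAAATTCA")
})

test_that("trace files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  sim <- gen_fret_telegraph(1, 1, dt = 0.1, duration = 10, seed = 12)
  write.csv(data.frame(time_s = (seq_along(sim$trace$donor) - 1) * 0.1,
                       donor = sim$trace$donor,
                       acceptor = sim$trace$acceptor),
            path, row.names = FALSE)
  tr <- read_fret_trace(path)
  expect_equal(tr$dt, 0.1)
  expect_equal(tr$donor, sim$trace$donor)
})
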