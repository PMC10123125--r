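# shared fixtures for the test suite (all built in code, seeded)

kBT22 <- thermal_energy(22)

# trapezoid integral of a radial_distribution
trapz_density <- function(dist) pracma::trapz(dist$x, dist$density)

# a tabulated Gaussian wrapped as a radial_distribution (wide support so the
# natural-spline boundary condition does not contaminate the interior)
gaussian_dist <- function(mu, sigma, half_width = 8, n = 4001) {
  x <- seq(mu - half_width * sigma, mu + half_width * sigma, length.out = n)
  radial_distribution(x, exp(-(x - mu)^2 / (2 * sigma^2)))
}

# default per-nucleotide FER triplet used across kinetics tests
default_fers <- function(n = 9) {
  list(u = linear_fer_per_nt(30.7, 0.21, n),
       b = linear_fer_per_nt(Inf, 0.34, n),
       ts = linear_fer_per_nt(355.3, 0.39, n))
}

# full trace pipeline for one simulated condition: generate -> efficiency ->
# states -> dwells -> rates (pooled over traces)
run_trace_pipeline <- function(kon_c, koff, n_traces, duration, dt,
                               conc = 20e-9, window = 1L, seed = 1L,
                               noise_sd = 0.1, thresholds = c(0.35, 0.65),
                               estimator = "censored_mle") {
  sims <- lapply(seq_len(n_traces), function(i) {
    gen_fret_telegraph(kon_c, koff, dt = dt, duration = duration,
                       noise_sd = noise_sd, seed = seed * 100000L + i)
  })
  dls <- lapply(sims, function(s) {
    E <- fret_efficiency(s$trace)
    st <- call_states(E, window = window, low_thr = thresholds[1],
                      high_thr = thresholds[2])
    dwell_times(st, s$trace$dt)
  })
  rates_from_dwells(pool_dwells(dls), conc = conc, estimator = estimator,
                    seed = seed)
}
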