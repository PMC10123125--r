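# force-dependent rate laws, thermodynamics, model fitting, NN stability

test_that("rate law reduces to the zero-force rate and the Bell formula", {
  fers <- default_fers()
  law <- rate_law(1e7, 0.5, fers$u, fers$b, fers$ts)
  expect_equal(rate_vs_force(law, "on", 0)$rate, 1e7)
  expect_equal(rate_vs_force(law, "off", 0)$rate, 0.5)
  # constant gap Delta x -> pure Bell exponential
  bell <- rate_law(1, 1, fer_u = linear_fer(Inf, 1.0),
                   fer_b = linear_fer(Inf, 1.0), fer_ts = linear_fer(Inf, 1.45))
  f <- c(0.5, 2, 5)
  expect_equal(rate_vs_force(bell, "off", f)$rate,
               exp(f * 0.45 / kBT22), tolerance = 1e-10)
  expect_error(rate_vs_force(law, "on", -1), "non-negative")
})

test_that("quadrature of linear FERs equals the closed forms", {
  fers <- default_fers()
  law <- rate_law(1e7, 0.5, fers$u, fers$b, fers$ts)
  f <- seq(0, 7, by = 0.5)
  expect_equal(rate_vs_force(law, "on", f)$rate,
               kon_closed_form(f, 1e7, 355.3, 0.39, 30.7, 0.21, 9),
               tolerance = 1e-8)
  expect_equal(rate_vs_force(law, "off", f)$rate,
               koff_closed_form(f, 0.5, 355.3, 0.39, 0.34, 9),
               tolerance = 1e-8)
})

test_that("slope identity: d log k/df equals the extension gap over kBT", {
  fers <- default_fers()
  law <- rate_law(1e7, 0.5, fers$u, fers$b, fers$ts)
  for (f0 in c(1, 3.3, 6)) {
    h <- 1e-4
    num <- (log(rate_vs_force(law, "on", f0 + h)$rate) -
            log(rate_vs_force(law, "on", f0 - h)$rate)) / (2 * h)
    gap <- (fer_extension(fers$ts, f0) - fer_extension(fers$u, f0)) / kBT22
    expect_equal(num, gap, tolerance = 1e-6)
    expect_equal(rate_vs_force(law, "on", f0)$slope, gap, tolerance = 1e-12)
  }
})

test_that("stiff transition state reduces koff to Bell", {
  f <- c(1, 3, 6)
  expect_equal(koff_closed_form(f, 0.5, 1e12, 0.39, 0.34, 9),
               0.5 * exp(9 * (0.39 - 0.34) * f / kBT22), tolerance = 1e-8)
})

test_that("sequence-averaged parameters give the published force response", {
  p <- seq_averaged_params()
  ratio <- koff_closed_form(6.25, 1, p$kappa_ts, p$x0_ts, p$x0_b, 9) /
    koff_closed_form(1.6, 1, p$kappa_ts, p$x0_ts, p$x0_b, 9)
  expect_equal(ratio, 1.9, tolerance = 0.05)  # ~2-fold dynamic range
  # kon stationary point (plateau onset) at >= 6 pN
  dlog <- function(f) (1 / p$kappa_ts - 1 / p$kappa_u) * f + (p$x0_ts - p$x0_u)
  fstar <- uniroot(dlog, c(1, 20))$root
  expect_gte(fstar, 6)
})

test_that("duplex stability from rates, with error propagation", {
  expect_equal(delta_g(2e5, 2e5)$dG, 0)
  expect_equal(delta_g(1e7, 0.1)$dG, log(1e8), tolerance = 1e-12)
  # propagated error vs bootstrap over synthetic rate draws
  set.seed(31)
  kon <- 1e7; koff <- 0.3; s_on <- 0.08 * kon; s_off <- 0.06 * koff
  dg <- delta_g(kon, koff, s_on, s_off)
  boot <- sd(log(rnorm(20000, kon, s_on) / rnorm(20000, koff, s_off)))
  expect_lt(abs(dg$dG_err - boot) / boot, 0.2)
})

test_that("stability versus force: limits, crossover maximum, quadratic form", {
  defs <- polymer_defaults()
  ss <- wlc_model(9 * defs$ssdna_nm_per_nt, defs$ssdna_persistence_nm)
  ds <- wlc_model(9 * defs$dsdna_rise_nm, defs$dsdna_persistence_nm)
  tab <- delta_g_vs_force(12, ss, ds, seq(0, 8, by = 0.05))
  expect_equal(tab$dG_kBT[1], 12)
  expect_equal(tab$force_pN[which.max(tab$dG_kBT)], 4.25, tolerance = 0.03)
  # linear FERs integrate to the analytic quadratic in f
  u <- linear_fer(3, 1.0); b <- linear_fer(10, 2.0)
  f <- seq(0, 6, by = 0.5)
  got <- delta_g_vs_force(5, u, b, f)$dG_kBT
  ana <- 5 - ((1 / 3 - 1 / 10) * f^2 / 2 + (1.0 - 2.0) * f) / kBT22
  expect_equal(got, ana, tolerance = 1e-10)
})

test_that("noiseless six-parameter fit inverts the model exactly", {
  d <- gen_rate_dataset(kon0 = 2e7, koff0 = 0.8, sigma_log = 0, seed = 1)
  fit <- fit_rate_model(d, "linear", n = 9)
  expect_equal(fit$par$kon0, 2e7, tolerance = 1e-6)
  expect_equal(fit$par$koff0, 0.8, tolerance = 1e-6)
  expect_equal(fit$par$kappa_ts, 355.3, tolerance = 1e-6)
  expect_equal(fit$par$x0_ts, 0.39, tolerance = 1e-6)
  expect_equal(fit$par$kappa_u, 30.7, tolerance = 1e-6)
  expect_equal(fit$par$x0_u, 0.21, tolerance = 1e-6)
  expect_error(fit_rate_model(d[d$force < 3, ], "linear", n = 9),
               "distinct forces")
})

test_that("noisy fits recover the rates and intercepts (seeded recovery study)", {
  biases_on <- biases_off <- x0u_z <- x0ts_z <- numeric(60)
  for (s in 1:60) {
    d <- gen_rate_dataset(sigma_log = 0.05, replicates = 3, seed = 1000 + s)
    fit <- suppressWarnings(fit_rate_model(d, "linear", n = 9))
    biases_on[s] <- fit$par$kon0 / 1e7 - 1
    biases_off[s] <- fit$par$koff0 / 0.5 - 1
    x0u_z[s] <- abs(fit$par$x0_u - 0.21) / fit$se$x0_u
    x0ts_z[s] <- abs(fit$par$x0_ts - 0.39) / fit$se$x0_ts
  }
  expect_lt(median(abs(biases_on)), 0.10)
  expect_lt(median(abs(biases_off)), 0.10)
  expect_lt(median(x0u_z), 2)
  expect_lt(median(x0ts_z), 2)
})

test_that("linear and Marko-Siggia fits agree on transition-state stiffness ordering", {
  # conditions chosen so the stiffness is identifiable: the curvature of
  # log k(f) scales as n f^2 / (2 kappa kBT), so very stiff transition
  # states are indistinguishable from Bell behavior at this noise level
  a_ts <- P_ts <- numeric(20)
  for (i in seq_along(a_ts)) {
    set.seed(400 + i)
    kap <- exp(runif(1, log(40), log(400)))  # vary true stiffness
    d <- gen_rate_dataset(kappa_ts = kap, sigma_log = 0.02, replicates = 3,
                          seed = 500 + i)
    lin <- suppressWarnings(fit_rate_model(d, "linear", n = 9))
    ms <- fit_rate_model(d, "marko_siggia", n = 9, n_starts = 6, seed = i)
    a_ts[i] <- lin$par$kappa_ts
    P_ts[i] <- ms$par$P_ts
  }
  expect_gt(cor(a_ts, P_ts, method = "spearman"), 0.8)
})

test_that("sequence averaging rescales by n and averages per nucleotide", {
  f1 <- linear_fer_per_nt(300, 0.4, 8)
  f2 <- linear_fer_per_nt(400, 0.3, 9)
  avg <- sequence_average_fer(list(f1, f2))
  expect_equal(avg$kappa, 350)
  expect_equal(avg$x0, 0.35)
  same <- sequence_average_fer(list(f1, f1))
  expect_equal(same$kappa, 300)
  expect_equal(same$x0, 0.4)
})

test_that("dynamic range: identity, Bell closed form, error propagation", {
  f <- c(1.6, 3, 6.25)
  expect_equal(dynamic_range(f, rep(2, 3))$ratio, 1)
  k <- exp(0.45 * f / kBT22)
  dr <- dynamic_range(f, k)
  expect_equal(dr$ratio, exp(0.45 * (6.25 - 1.6) / kBT22), tolerance = 1e-12)
  # propagated error against a bootstrap over rate draws
  set.seed(13)
  sem <- 0.05 * k
  dr2 <- dynamic_range(f, k, sem)
  boot <- sd(rnorm(20000, k[3], sem[3]) / rnorm(20000, k[1], sem[1]))
  expect_lt(abs(dr2$ratio_err - boot) / boot, 0.2)
})

test_that("nearest-neighbor stability: symmetry, hand sum, corrections", {
  expect_equal(nn_duplex_dg("GTAAATTCA"), nn_duplex_dg("TGAATTTAC"))
  # 3-mer: two stacking steps plus two initiation terms, summed by hand
  tb <- read.csv(system.file("extdata", "nn_unified_dna.csv",
                             package = "bowkit"))
  gstep <- function(m) {
    i <- match(m, tb$motif)
    tb$dh_kcal_mol[i] - 295.15 * tb$ds_cal_mol_k[i] / 1000
  }
  hand <- gstep("GA") + gstep("AT") + gstep("init_GC") + gstep("init_AT")
  expect_equal(nn_duplex_dg("GAT"), -hand / (0.0019872 * 295.15))
  # dangling-end and dye corrections are additive
  base <- nn_duplex_dg("GTAAATTCA")
  expect_equal(nn_duplex_dg("GTAAATTCA", dangling_ends = 2, dye = TRUE),
               base + 4)
  expect_error(nn_duplex_dg("GTN"), "A/C/G/T")
})
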