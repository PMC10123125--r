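# umbrella reweighting and 2-D melting free-energy surfaces

test_that("hydrogen-bond counting applies the cutoff strictly", {
  expect_equal(hbond_count(c(0, 0, 0)), 0L)
  expect_equal(hbond_count(c(-0.5, -0.05, -0.2)), 2L)
  m <- rbind(c(-0.5, -0.05), c(-0.2, -0.3))
  expect_equal(hbond_count(m), c(1L, 2L))
  # unit registry: 0.1 energy units ~ 1 kBT at 22 C, 0.1 length units ~
  # 0.085 nm (the default extension bin), unit stiffness ~ 57.1 pN/nm
  u <- sim_units()
  expect_equal(0.1 * u$energy_pN_nm / thermal_energy(22), 1, tolerance = 0.02)
  expect_equal(0.1 * u$length_nm, 0.085, tolerance = 0.01)
  expect_equal(u$stiffness_pN_per_nm, 57.1, tolerance = 0.001)
})

test_that("unit weights reproduce the raw histogram and normalize exactly", {
  set.seed(41)
  x <- rnorm(5000, 3, 0.4)
  nb <- sample(0:3, 5000, replace = TRUE)
  pe <- umbrella_reweight(x, nb)
  expect_equal(sum(pe$p), 1, tolerance = 1e-12)
  raw <- pe$counts / sum(pe$counts)
  expect_equal(pe$p, raw, tolerance = 1e-12)
  # an observed stratum without a weight is an error
  expect_error(umbrella_reweight(x, nb, weights = c("0" = 1, "1" = 1)),
               "without a bias weight")
})

test_that("reweighting inverts a known biased categorical distribution", {
  # truth p(n_bp) with an exponential bias W(n_bp); q ~ p*W
  p_true <- c(0.35, 0.05, 0.10, 0.20, 0.30)
  W <- exp(0.9 * (0:4))
  q <- p_true * W; q <- q / sum(q)
  set.seed(99)
  n <- 1e6
  nb <- sample(0:4, n, replace = TRUE, prob = q)
  pe <- umbrella_reweight(rep(0.5, n), nb, weights = setNames(W, 0:4),
                          bin_width = 1)
  est <- colSums(pe$p)
  # Monte-Carlo error band from 10 independent batches of the same draw
  batch <- matrix(nb, ncol = 10)
  bests <- apply(batch, 2, function(b) {
    colSums(umbrella_reweight(rep(0.5, length(b)), b,
                              weights = setNames(W, 0:4), bin_width = 1)$p)
  })
  mc_sd <- apply(bests, 1, sd) / sqrt(10)
  expect_true(all(abs(est - p_true) < 3 * mc_sd + 1e-4))
})

test_that("reweight-then-bin equals bin-then-reweight for stratified weights", {
  set.seed(55)
  x <- runif(20000, 0, 2)
  nb <- sample(0:3, 20000, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  W <- setNames(c(1, 2, 4, 8), 0:3)
  a <- umbrella_reweight(x, nb, W, bin_width = 0.1, x_range = c(0, 2))
  # oracle: bin first, then divide each stratum column and renormalize
  raw <- umbrella_reweight(x, nb, NULL, bin_width = 0.1, x_range = c(0, 2))
  manual <- sweep(raw$counts, 2, W, "/")
  manual <- manual / sum(manual)
  expect_equal(a$p, manual, tolerance = 1e-12)
})

test_that("surface construction: offsets, two-bin ratio, empty bins", {
  u <- build_surface(matrix(0.25, 2, 2))
  expect_true(all(u$G == 0))
  two <- build_surface(matrix(c(0.6, 0.3, 0.1, 0), 2, 2))
  expect_equal(two$G[2, 1] - two$G[1, 1], log(0.6 / 0.3), tolerance = 1e-12)
  expect_true(is.infinite(two$G[2, 2]))
  expect_equal(min(two$G), 0)
})

test_that("minimum-energy path finds analytic column minima with the tie rule", {
  xg <- seq(0, 4, by = 0.05)
  xc <- c(1.0, 2.5, 3.2)
  G <- vapply(1:3, function(j) (xg - xc[j])^2 / (2 * 0.3^2) + j, numeric(length(xg)))
  surf <- build_surface(exp(-G) / sum(exp(-G)), x_mids = xg, n_bp_levels = 0:2)
  path <- min_energy_path(surf)
  expect_equal(path$x, xc, tolerance = 0.051)
  # flat column: tie broken toward smaller extension
  flat <- build_surface(matrix(0.5, 4, 1), x_mids = 1:4, n_bp_levels = 0)
  expect_equal(min_energy_path(flat)$x, 1)
})

test_that("path offset zeroes every column minimum, preserves shape, idempotent", {
  surf <- zipper_surface(force = 4)
  off <- path_offset(surf)
  mins <- apply(off$G, 2, function(col) min(col[is.finite(col)]))
  expect_equal(unname(mins), rep(0, ncol(off$G)), tolerance = 1e-12)
  j <- 3
  fin <- is.finite(surf$G[, j])
  expect_equal(diff(off$G[fin, j]), diff(surf$G[fin, j]), tolerance = 1e-12)
  off2 <- path_offset(off)
  expect_equal(off2$G, off$G, tolerance = 1e-12)
})

test_that("zipper landscapes put the barrier and maximal extension at one base pair", {
  for (f in 2:6) {
    sim <- gen_landscape_samples(2e5, force = f, weights = "flatten",
                                 seed = 600 + f)
    pe <- umbrella_reweight(sim$x, sim$n_bp, sim$weights)
    surf <- build_surface(pe, force = f)
    path <- min_energy_path(surf)
    x1 <- path$x[path$n_bp == 1]
    expect_gte(x1 + 1e-9, path$x[path$n_bp == 9])
    expect_gte(x1 + 1e-9, path$x[path$n_bp == 0])
    expect_equal(path$n_bp[which.max(path$G_kBT)], 1)
  }
})

test_that("surface and sample files round-trip", {
  surf <- zipper_surface(force = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  pcsv <- withr::local_tempfile(fileext = ".csv")
  write_surface_csv(surf, path, pcsv)
  long <- read.csv(path)
  expect_true(all(c("x_bin", "n_bp", "G_kBT") %in% names(long)))
  expect_equal(nrow(read.csv(pcsv)), 10)
  # landscape sample reader with a YAML bias table
  sfile <- withr::local_tempfile(fileext = ".csv")
  bfile <- withr::local_tempfile(fileext = ".yml")
  write.csv(data.frame(x_nm = c(1, 2), n_bp = c(0, 1)), sfile,
            row.names = FALSE)
  writeLines(c("W:", "  0: 1.0", "  1: 2.5"), bfile)
  ls <- read_landscape_samples(sfile, bfile)
  expect_equal(ls$weights[["1"]], 2.5)
})
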