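# rigid base-pair geometry and restrained minimization

test_that("straight chain composes to a straight path of length N*rise", {
  ch <- rbp_chain(10, twist0 = 34.3)
  gs <- rbp_ground_state(ch)
  expect_equal(attr(gs, "end_to_end"), 10 * 0.34, tolerance = 1e-12)
  expect_equal(gs[, 1:2], matrix(0, 11, 2), ignore_attr = TRUE)
})

test_that("constant roll generates a planar circular arc (polygon chord)", {
  gamma <- 5 * pi / 180
  ch <- rbp_chain(20, roll0 = 5, twist0 = 0)
  ee <- attr(rbp_ground_state(ch), "end_to_end")
  R_poly <- 0.34 / (2 * sin(gamma / 2))
  expect_equal(ee, 2 * R_poly * sin(20 * gamma / 2), tolerance = 1e-6)
})

test_that("path equals an independent composition of homogeneous transforms", {
  set.seed(9)
  n <- 12
  ang <- cbind(roll = rnorm(n, 0, 6), tilt = rnorm(n, 0, 6),
               twist = rnorm(n, 34, 8))
  ch <- rbp_chain(n)
  pos <- rbp_ground_state(ch, angles = ang)
  # oracle: explicit 4x4 matrix products
  d <- pi / 180
  T_all <- diag(4)
  oracle <- matrix(0, n + 1, 3)
  for (i in 1:n) {
    Tr <- diag(4); Tr[1:3, 4] <- T_all[1:3, 1:3] %*% c(0, 0, 0.34)
    T_all[1:3, 4] <- T_all[1:3, 4] + Tr[1:3, 4]
    Rz <- matrix(c(cos(ang[i,3]*d), sin(ang[i,3]*d), 0,
                   -sin(ang[i,3]*d), cos(ang[i,3]*d), 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cos(ang[i,1]*d), 0, -sin(ang[i,1]*d),
                   0, 1, 0, sin(ang[i,1]*d), 0, cos(ang[i,1]*d)), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[i,2]*d), sin(ang[i,2]*d),
                   0, -sin(ang[i,2]*d), cos(ang[i,2]*d)), 3, 3)
    T_all[1:3, 1:3] <- T_all[1:3, 1:3] %*% (Rz %*% Ry %*% Rx)
    oracle[i + 1, ] <- T_all[1:3, 4]
  }
  expect_equal(pos[, ], oracle, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("a ground state already satisfying the restraint is a zero-force minimum", {
  ch <- rbp_chain(8, twist0 = 34.3)
  res <- rbp_restrained_minimize(ch, kappa = 57.1, r0 = 8 * 0.34,
                                 start_register = 0)
  expect_lt(res$energy_kBT, 1e-10)
  expect_lt(abs(res$force), 1e-6)
  expect_equal(res$angles, ch$angles0, tolerance = 1e-8)
})

test_that("line-searched descent never increases the energy and satisfies the force identity", {
  ch <- rbp_chain(15, roll0 = 3, twist0 = 34.3)
  res <- rbp_restrained_minimize(ch, kappa = 30, r0 = 2.5, start_register = 40)
  expect_true(all(diff(res$energy_trace) <= 0))
  expect_equal(res$force, 2 * 30 * (res$r - 2.5), tolerance = 1e-12)
  expect_lte(res$energy, res$energy_trace[1])
})

test_that("small-chain minimum matches a multi-start BFGS oracle within 1%", {
  ch <- rbp_chain(5, roll0 = 4, twist0 = 30)
  kappa <- 10; r0 <- 1.2
  res <- rbp_restrained_minimize(ch, kappa, r0, start_register = 0)
  efun <- function(v) {
    a <- matrix(v, 5, 3, dimnames = list(NULL, c("roll", "tilt", "twist")))
    kBT22 * sum(ch$beta * (a - ch$angles0)^2) +
      kappa * (attr(rbp_ground_state(ch, a), "end_to_end") - r0)^2
  }
  set.seed(17)
  best <- Inf
  for (i in 1:10) {
    o <- optim(as.vector(ch$angles0) + rnorm(15, 0, 10), efun,
               method = "BFGS", control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_lt(res$energy, best * 1.01 + 1e-12)
})

test_that("register scan: symmetric chains are register-independent, seeds reproduce", {
  ch <- rbp_chain(12, twist0 = 34.3)
  sc <- register_scan(ch, kappa = 57.1, r0 = 2.0, n_registers = 6, seed = 4)
  expect_lt(sc$sd_force / abs(sc$mean_force), 0.01)
  sc2 <- register_scan(ch, kappa = 57.1, r0 = 2.0, n_registers = 6, seed = 4)
  expect_identical(sc$forces, sc2$forces)
})

test_that("uniform and random register sampling agree for a curved chain", {
  ch <- rbp_chain(12, roll0 = 4, twist0 = 34.3)
  uni <- register_scan(ch, kappa = 30, r0 = 2.0,
                       registers = seq(0, 330, by = 30))
  rnd <- register_scan(ch, kappa = 30, r0 = 2.0, n_registers = 12, seed = 8)
  spread <- max(uni$sd_force, rnd$sd_force, 1e-6)
  expect_lt(abs(uni$mean_force - rnd$mean_force), 2 * spread)
})

test_that("rigid base-pair parameter tables load", {
  path <- withr::local_tempfile(fileext = ".csv")
  tb <- data.frame(step = 1:6, roll0 = 2, tilt0 = 0, twist0 = 34.3,
                   beta_roll = 0.02, beta_tilt = 0.02, beta_twist = 0.04)
  write.csv(tb, path, row.names = FALSE)
  ch <- read_rbp_table(path)
  expect_equal(ch$n_steps, 6L)
  expect_equal(unname(ch$angles0[, "roll"]), rep(2, 6))
})
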