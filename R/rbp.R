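#' Rigid base-pair chain
#'
#' Describes dsDNA at the base-pair-step level: each step has ground-state
#' roll, tilt and twist angles (degrees), harmonic stiffnesses for each
#' angle (in units of \eqn{k_B T}/deg^2), and a rise (nm). Nonzero
#' ground-state roll/tilt encode sequence-dependent intrinsic curvature.
#' Scalars are recycled to the number of steps.
#'
#' @param n_steps Number of base-pair steps.
#' @param roll0,tilt0,twist0 Ground-state angles in degrees.
#' @param beta_roll,beta_tilt,beta_twist Stiffnesses in kBT/deg^2 (> 0).
#'   Defaults correspond to a bending persistence length of ~50 nm split
#'   evenly between roll and tilt, and a ~100 nm twist persistence length.
#' @param rise Rise per step in nm.
#' @return Object of class `rbp_chain`.
#' @examples
#' straight <- rbp_chain(10, twist0 = 34.3)
#' rbp_ground_state(straight)
#' @export
rbp_chain <- function(n_steps, roll0 = 0, tilt0 = 0, twist0 = 34.3,
                      beta_roll = 0.0224, beta_tilt = 0.0224,
                      beta_twist = 0.045, rise = 0.34) {
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 1, rise > 0)
  rec <- function(v) {
    stopifnot(length(v) %in% c(1L, n_steps))
    rep_len(as.numeric(v), n_steps)
  }
  beta <- cbind(roll = rec(beta_roll), tilt = rec(beta_tilt),
                twist = rec(beta_twist))
  if (any(beta <= 0)) stop("all stiffnesses must be positive")
  structure(list(
    n_steps = n_steps,
    angles0 = cbind(roll = rec(roll0), tilt = rec(tilt0), twist = rec(twist0)),
    beta = beta,
    rise = rise
  ), class = "rbp_chain")
}

#' @export
print.rbp_chain <- function(x, ...) {
  cat(sprintf("<rbp_chain> %d steps, rise %.3g nm, mean twist %.3g deg\n",
              x$n_steps, x$rise, mean(x$angles0[, "twist"])))
  invisible(x)
}

#' Read a rigid base-pair parameter table
#'
#' CSV with columns `step, roll0, tilt0, twist0, beta_roll, beta_tilt,
#' beta_twist` (one row per base-pair step).
#'
#' @param path CSV path.
#' @param rise Rise per step in nm.
#' @return An [rbp_chain()].
#' @export
read_rbp_table <- function(path, rise = 0.34) {
  tb <- read.csv(path)
  need <- c("roll0", "tilt0", "twist0", "beta_roll", "beta_tilt", "beta_twist")
  if (!all(need %in% names(tb))) {
    stop("rigid base-pair table must have columns: ", paste(need, collapse = ", "))
  }
  rbp_chain(nrow(tb), tb$roll0, tb$tilt0, tb$twist0,
            tb$beta_roll, tb$beta_tilt, tb$beta_twist, rise = rise)
}

# Step rotation: twist about the local helical (z) axis, roll about y,
# tilt about x; step i maps frame i to frame i+1. Angles in degrees.
.rbp_step_rotation <- function(roll, tilt, twist) {
  d <- pi / 180
  cr <- cos(roll * d); sr <- sin(roll * d)
  ct <- cos(tilt * d); st <- sin(tilt * d)
  cw <- cos(twist * d); sw <- sin(twist * d)
  Rz <- matrix(c(cw, sw, 0, -sw, cw, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cr, 0, -sr, 0, 1, 0, sr, 0, cr), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, ct, st, 0, -st, ct), 3, 3)
  Rz %*% Ry %*% Rx
}

# Path of base-pair centers for a given angle matrix (n_steps x 3).
# Returns (n_steps + 1) x 3 coordinates; the first center is the origin and
# each step translates by `rise` along the current local z axis before the
# step rotation is applied.
.rbp_path <- function(chain, angles) {
  n <- chain$n_steps
  pos <- matrix(0, n + 1L, 3L)
  R <- diag(3)
  dz <- c(0, 0, chain$rise)
  for (i in seq_len(n)) {
    pos[i + 1L, ] <- pos[i, ] + R %*% dz
    R <- R %*% .rbp_step_rotation(angles[i, 1L], angles[i, 2L], angles[i, 3L])
  }
  pos
}

#' Ground-state path of a rigid base-pair chain
#'
#' Composes the per-step rotations and rise translations at the ground-state
#' angles into 3-D coordinates of the base-pair centers.
#'
#' @param chain An [rbp_chain()].
#' @param angles Optional angle matrix (`n_steps` x 3, columns roll, tilt,
#'   twist in degrees) overriding the ground state.
#' @return Matrix `(n_steps + 1) x 3` of coordinates (nm), with the
#'   end-to-end distance in attribute `"end_to_end"`.
#' @export
rbp_ground_state <- function(chain, angles = NULL) {
  stopifnot(inherits(chain, "rbp_chain"))
  if (is.null(angles)) angles <- chain$angles0
  stopifnot(is.matrix(angles), nrow(angles) == chain$n_steps, ncol(angles) == 3L)
  pos <- .rbp_path(chain, angles)
  attr(pos, "end_to_end") <- sqrt(sum((pos[nrow(pos), ] - pos[1L, ])^2))
  pos
}

# End-to-end distance plus the prefix/suffix decomposition needed for O(1)
# re-evaluation under single-step perturbations:
#   p_end = A_j + P_j (d + M_j S_{j+1})   for every step j,
# where P_j is the frame before step j, A_j the position before step j, and
# S_j the remaining displacement expressed in frame j.
.rbp_decompose <- function(chain, angles) {
  n <- chain$n_steps
  d <- c(0, 0, chain$rise)
  M <- vector("list", n)
  P <- vector("list", n)
  A <- matrix(0, n, 3L)
  R <- diag(3)
  pos <- c(0, 0, 0)
  for (i in seq_len(n)) {
    M[[i]] <- .rbp_step_rotation(angles[i, 1L], angles[i, 2L], angles[i, 3L])
    P[[i]] <- R
    A[i, ] <- pos
    pos <- pos + R %*% d
    R <- R %*% M[[i]]
  }
  S <- matrix(0, n + 1L, 3L)           # S[j,] = displacement after step j's translation
  for (j in n:1) S[j, ] <- M[[j]] %*% S[j + 1L, ]
  # S[j,] currently excludes the translations; rebuild including them:
  S2 <- matrix(0, n + 1L, 3L)
  for (j in n:1) S2[j, ] <- d + M[[j]] %*% S2[j + 1L, ]
  list(M = M, P = P, A = A, S = S2, p_end = pos + 0, d = d)
}

# r and dr/dangles by central finite differences (step `h` degrees), using
# the prefix/suffix decomposition so the full gradient costs O(n).
.rbp_r_and_grad <- function(chain, angles, h = 1e-5) {
  n <- chain$n_steps
  dec <- .rbp_decompose(chain, angles)
  p_end <- dec$A[n, ] + dec$P[[n]] %*% dec$S[n, ]
  r <- sqrt(sum(p_end^2))
  grad <- matrix(0, n, 3L)
  for (j in seq_len(n)) {
    base <- angles[j, ]
    Sj1 <- dec$S[j + 1L, ]
    for (c in 1:3) {
      ap <- base; ap[c] <- ap[c] + h
      am <- base; am[c] <- am[c] - h
      Mp <- .rbp_step_rotation(ap[1L], ap[2L], ap[3L])
      Mm <- .rbp_step_rotation(am[1L], am[2L], am[3L])
      pp <- dec$A[j, ] + dec$P[[j]] %*% (dec$d + Mp %*% Sj1)
      pm <- dec$A[j, ] + dec$P[[j]] %*% (dec$d + Mm %*% Sj1)
      grad[j, c] <- (sqrt(sum(pp^2)) - sqrt(sum(pm^2))) / (2 * h)
    }
  }
  list(r = as.numeric(r), grad = grad)
}

# Restrained energy in pN nm: elastic term (beta in kBT/deg^2) plus the
# harmonic end-to-end restraint kappa (pN/nm) * (r - r0)^2.
.rbp_energy <- function(chain, angles, kappa, r0, temp_c = 22) {
  kBT <- thermal_energy(temp_c)
  dev <- angles - chain$angles0
  pos <- .rbp_path(chain, angles)
  r <- sqrt(sum((pos[nrow(pos), ] - pos[1L, ])^2))
  list(E = kBT * sum(chain$beta * dev^2) + kappa * (r - r0)^2, r = r)
}

#' Restrained minimization of a rigid base-pair chain
#'
#' Minimizes the restrained elastic energy
#' \deqn{E\{x_i\} = \sum_i \beta_i (x_i - x_{i,0})^2 + \kappa (r\{x_i\} - r_0)^2}
#' by gradient descent with a backtracking line search, starting from a
#' conformation uniformly curved toward a rotational register angle. The
#' force the arc exerts on the restraint follows from the minimizer as
#' \eqn{f = 2\kappa (r - r_0)}.
#'
#' @param chain An [rbp_chain()].
#' @param kappa Restraint stiffness in pN/nm (> 0).
#' @param r0 Restraint rest distance in nm (>= 0); typically the bowstring
#'   rest length.
#' @param start_register Initial register angle in degrees; drawn uniformly
#'   on `[0, 360)` when `NULL`.
#' @param seed Optional seed for the register draw.
#' @param temp_c Temperature in Celsius.
#' @param max_iter Maximum gradient-descent iterations.
#' @param tol Energy-change convergence tolerance in units of kBT.
#' @param fd_step Finite-difference step (degrees) for the gradient of r.
#' @return List of class `rbp_minimization` with `angles`, `energy` (pN nm),
#'   `energy_kBT`, `r` (nm), `force` (pN, `2*kappa*(r - r0)`), `iterations`,
#'   `converged`, `register`, and the monotone `energy_trace` of accepted
#'   line-search steps (pN nm).
#' @export
rbp_restrained_minimize <- function(chain, kappa, r0, start_register = NULL,
                                    seed = NULL, temp_c = 22,
                                    max_iter = 2000L, tol = 1e-8,
                                    fd_step = 1e-5) {
  stopifnot(inherits(chain, "rbp_chain"), kappa > 0, r0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start_register)) start_register <- runif(1, 0, 360)
  kBT <- thermal_energy(temp_c)
  n <- chain$n_steps
  # uniformly curved start toward the register angle in the twist-following
  # frame; the bend amplitude is chosen so the starting end-to-end distance
  # is as close to r0 as possible (zero amplitude when the ground state
  # already satisfies the restraint)
  psi <- cumsum(c(0, chain$angles0[-n, "twist"])) + start_register
  curved <- function(amp) {
    a <- chain$angles0
    a[, "roll"] <- a[, "roll"] + amp * cos(psi * pi / 180)
    a[, "tilt"] <- a[, "tilt"] + amp * sin(psi * pi / 180)
    a
  }
  r_of_amp <- function(amp) {
    pos <- .rbp_path(chain, curved(amp))
    sqrt(sum((pos[nrow(pos), ] - pos[1L, ])^2))
  }
  if (abs(r_of_amp(0) - r0) < 1e-9) {
    amp <- 0
  } else {
    amp <- optimize(function(a) abs(r_of_amp(a) - r0), c(0, 720 / n))$minimum
    if (abs(r_of_amp(0) - r0) <= abs(r_of_amp(amp) - r0)) amp <- 0
  }
  angles <- curved(amp)

  en <- .rbp_energy(chain, angles, kappa, r0, temp_c)
  E <- en$E
  iter <- 0L
  converged <- FALSE
  tol_E <- tol * kBT
  # preconditioned conjugate-gradient descent (Polak-Ribiere with restart),
  # kept monotone by an Armijo backtracking line search
  g_prev <- NULL
  dir <- NULL
  step <- 1
  small_prev <- FALSE
  energy_trace <- E
  while (iter < max_iter) {
    iter <- iter + 1L
    rg <- .rbp_r_and_grad(chain, angles, h = fd_step)
    grad <- 2 * kBT * chain$beta * (angles - chain$angles0) +
      2 * kappa * (rg$r - r0) * rg$grad
    if (sum(grad^2) < 1e-30) { converged <- TRUE; break }
    precond <- 2 * kBT * chain$beta + 2 * kappa * rg$grad^2
    pg <- grad / precond
    if (is.null(g_prev)) {
      dir <- -pg
    } else {
      beta_pr <- sum(grad * (pg - g_prev$pg)) / sum(g_prev$grad * g_prev$pg)
      dir <- -pg + max(0, beta_pr) * dir
      if (sum(dir * grad) >= 0) dir <- -pg   # restart on non-descent
    }
    g_prev <- list(grad = grad, pg = pg)
    slope <- -sum(grad * dir)
    accepted <- FALSE
    step <- max(step, 1e-6)
    for (ls in 1:60) {
      trial <- angles + step * dir
      et <- .rbp_energy(chain, trial, kappa, r0, temp_c)
      if (et$E <= E - 1e-4 * step * slope) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    dE <- E - et$E
    angles <- trial
    E <- et$E
    energy_trace <- c(energy_trace, E)
    step <- min(step * 2, 1)
    # require two consecutive sub-tolerance drops so a single short CG step
    # does not end the minimization early
    if (dE < tol_E) {
      if (small_prev) { converged <- TRUE; break }
      small_prev <- TRUE
    } else small_prev <- FALSE
  }
  en <- .rbp_energy(chain, angles, kappa, r0, temp_c)
  if (!converged) {
    warning("rbp_restrained_minimize: not converged after ", iter,
            " iterations; result reported anyway")
  }
  structure(list(angles = angles, energy = en$E, energy_kBT = en$E / kBT,
                 r = en$r, force = 2 * kappa * (en$r - r0),
                 iterations = iter, converged = converged,
                 register = start_register, energy_trace = energy_trace),
            class = "rbp_minimization")
}

#' @export
print.rbp_minimization <- function(x, ...) {
  cat(sprintf(
    "<rbp_minimization> E = %.4g kBT, r = %.4g nm, f = %.4g pN (%d iter%s)\n",
    x$energy_kBT, x$r, x$force, x$iterations,
    if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Scan rotational registers of the initial curvature
#'
#' Repeats [rbp_restrained_minimize()] from initial conformations curved
#' toward different register angles and summarizes the spread of the
#' resulting restraint forces. For sequence-dependent ground states the
#' register matters; for an intrinsically straight chain it does not.
#'
#' @inheritParams rbp_restrained_minimize
#' @param n_registers Number of register angles.
#' @param registers Optional explicit register angles (degrees); when
#'   `NULL`, drawn uniformly at random on `[0, 360)` under `seed`.
#' @param ... Passed to [rbp_restrained_minimize()].
#' @return List with `mean_force`, `sd_force`, `forces`, `registers`.
#' @export
register_scan <- function(chain, kappa, r0, n_registers = 36L, seed = NULL,
                          registers = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(registers)) registers <- runif(n_registers, 0, 360)
  forces <- vapply(registers, function(phi) {
    rbp_restrained_minimize(chain, kappa, r0, start_register = phi, ...)$force
  }, numeric(1))
  list(mean_force = mean(forces), sd_force = sd(forces),
       forces = forces, registers = registers)
}
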