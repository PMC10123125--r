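#' Simulate a two-state telegraph FRET trace
#'
#' Simulates probe binding/unbinding as a continuous-time two-state Markov
#' chain with exact exponential waiting times, then renders a camera trace:
#' each frame takes the state at its midpoint (no intra-frame mixing, so the
#' ground truth stays unambiguous for state-calling tests; set `blur = TRUE`
#' for time-averaged frame efficiencies when studying missed events).
#' Intensities are drawn so that the apparent efficiency is Gaussian around
#' the state mean with standard deviation `noise_sd`.
#'
#' @param kon_c Binding pseudo-rate \eqn{k_{on} [c]} in 1/s (> 0).
#' @param koff Unbinding rate in 1/s (> 0).
#' @param dt Frame time in s.
#' @param duration Trace duration in s.
#' @param e_off,e_on Mean FRET efficiencies of the unbound/bound states
#'   (`0 <= e_off < e_on <= 1`).
#' @param noise_sd Gaussian efficiency noise per frame.
#' @param intensity Total intensity scale (counts/frame).
#' @param seed Seed; the generator is a pure function of (params, seed).
#' @param start_state Initial state (0/1); drawn from the stationary
#'   distribution when `NULL`.
#' @param blur Average the state over each frame instead of sampling the
#'   midpoint.
#' @return List with `trace` (a [fret_trace()]), `states` (ground-truth 0/1
#'   per frame; under `blur` the fraction of the frame spent bound), and
#'   `params`.
#' @examples
#' sim <- gen_fret_telegraph(0.5, 0.5, dt = 0.05, duration = 60, seed = 1)
#' mean(sim$states)   # ~ kon_c / (kon_c + koff)
#' @export
gen_fret_telegraph <- function(kon_c, koff, dt, duration, e_off = 0.2,
                               e_on = 0.8, noise_sd = 0.1, intensity = 1000,
                               seed = NULL, start_state = NULL, blur = FALSE) {
  stopifnot(kon_c >= 0, koff >= 0, kon_c + koff > 0, dt > 0, duration > dt,
            e_off >= 0, e_on <= 1, e_off < e_on)
  if (!is.null(seed)) set.seed(seed)
  p_bound <- kon_c / (kon_c + koff)
  state <- if (is.null(start_state)) rbinom(1, 1, p_bound) else as.integer(start_state)
  # jump times of the alternating renewal process
  t_jump <- numeric(0)
  s_jump <- integer(0)
  t <- 0
  s <- state
  while (t < duration) {
    rate <- if (s == 1L) koff else kon_c
    if (rate <= 0) break   # absorbing state: no further transitions
    t <- t + rexp(1, rate)
    t_jump <- c(t_jump, t)
    s <- 1L - s
    s_jump <- c(s_jump, s)
  }
  n_frames <- floor(duration / dt)
  mids <- (seq_len(n_frames) - 0.5) * dt
  if (blur) {
    # bound-time fraction per frame from the jump times
    edges <- seq(0, n_frames * dt, by = dt)
    tj <- c(0, t_jump)
    sj <- c(state, s_jump)
    occ <- numeric(n_frames)
    for (k in seq_along(tj)) {
      a <- tj[k]
      b <- if (k < length(tj)) tj[k + 1] else n_frames * dt
      if (a >= n_frames * dt || sj[k] == 0L) next
      i0 <- max(1L, ceiling(a / dt + 1e-12))
      i1 <- min(n_frames, ceiling(b / dt - 1e-12))
      if (i1 < i0) next
      for (i in i0:i1) {
        occ[i] <- occ[i] + max(0, min(b, edges[i + 1]) - max(a, edges[i]))
      }
    }
    states <- occ / dt
  } else {
    idx <- findInterval(mids, t_jump)
    states <- ifelse(idx == 0L, state, s_jump[pmax(idx, 1L)])
  }
  e_true <- e_off + (e_on - e_off) * states
  e_obs <- e_true + rnorm(n_frames, 0, noise_sd)
  list(
    trace = fret_trace(donor = intensity * (1 - e_obs),
                       acceptor = intensity * e_obs, dt = dt),
    states = if (blur) states else as.integer(states),
    params = list(kon_c = kon_c, koff = koff, dt = dt, duration = duration,
                  e_off = e_off, e_on = e_on, noise_sd = noise_sd,
                  intensity = intensity, seed = seed, blur = blur)
  )
}

#' Simulate a rate-versus-force dataset
#'
#' Evaluates the closed-form linear-FER rate laws at the requested forces
#' and perturbs them with log-normal noise, emulating per-bow-size rate
#' measurements. The default forces span the calibrated bound-state range
#' of the bow assay (1.6-6.25 pN, one force per bow size).
#'
#' @param kon0,koff0 Zero-force rates.
#' @param kappa_ts,x0_ts,kappa_u,x0_u,x0_b Per-nucleotide FER parameters
#'   (defaults: the sequence-averaged values, [seq_averaged_params()]).
#' @param n Nucleotides in the probe-binding region.
#' @param forces Forces in pN (default: 7 values spanning 1.6-6.25 pN).
#' @param sigma_log Log-normal noise standard deviation (0 = exact).
#' @param replicates Replicate measurements per force.
#' @param seed Seed.
#' @param temp_c Temperature in Celsius.
#' @return Data frame with columns `force`, `replicate`, `kon`, `kon_sem`,
#'   `koff`, `koff_sem` plus attribute `"truth"` holding the generating
#'   parameters.
#' @export
gen_rate_dataset <- function(kon0 = 1e7, koff0 = 0.5,
                             kappa_ts = 355.3, x0_ts = 0.39,
                             kappa_u = 30.7, x0_u = 0.21, x0_b = 0.34,
                             n = 9, forces = seq(1.6, 6.25, length.out = 7),
                             sigma_log = 0.05, replicates = 1L, seed = NULL,
                             temp_c = 22) {
  stopifnot(sigma_log >= 0, replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), force = forces)
  kon_true <- kon_closed_form(grid$force, kon0, kappa_ts, x0_ts, kappa_u,
                              x0_u, n, temp_c)
  koff_true <- koff_closed_form(grid$force, koff0, kappa_ts, x0_ts, x0_b, n,
                                temp_c)
  kon <- kon_true * exp(rnorm(nrow(grid), 0, sigma_log))
  koff <- koff_true * exp(rnorm(nrow(grid), 0, sigma_log))
  out <- data.frame(force = grid$force, replicate = grid$replicate,
                    kon = kon, kon_sem = kon * max(sigma_log, 1e-6),
                    koff = koff, koff_sem = koff * max(sigma_log, 1e-6))
  attr(out, "truth") <- list(kon0 = kon0, koff0 = koff0, kappa_ts = kappa_ts,
                             x0_ts = x0_ts, kappa_u = kappa_u, x0_u = x0_u,
                             x0_b = x0_b, n = n, sigma_log = sigma_log)
  out
}

#' Toy zipper free-energy surface
#'
#' Constructs a 2-D melting surface G(x, n_bp) at force f for a duplex of
#' `n_pairs` base pairs. Each stratum is a Gaussian extension basin centered
#' on a state-appropriate linear FER: the fully paired state follows the
#' bound FER, the fully melted state the unbound (ssDNA) FER, the
#' single-pair state the transition-state FER, and intermediate strata
#' interpolate between transition and bound centers. The single-pair column
#' center is pinned to be at least as extended as every other column
#' (steric repulsion between the unpaired dangling strands makes the
#' nucleated duplex the most extended state), and its baseline is the
#' free-energy maximum along the melting coordinate.
#'
#' @param force Force in pN.
#' @param n_pairs Base pairs in the duplex (default 9).
#' @param eps_kbt Free-energy cost per broken base pair (kBT).
#' @param unbound_drop_kbt Free-energy drop from the single-pair barrier to
#'   the fully melted state (entropy gain on release, kBT).
#' @param kappa_ts,x0_ts,kappa_u,x0_u,x0_b Per-nucleotide FER parameters
#'   (defaults: sequence-averaged values).
#' @param sigma_x Basin widths in nm: length-1 or one per stratum
#'   (n_bp = 0..n_pairs).
#' @param x_range,bin_width Extension grid (nm).
#' @return A `free_energy_surface` with the column centers in attribute
#'   `"centers"`.
#' @export
zipper_surface <- function(force, n_pairs = 9L, eps_kbt = 1.5,
                           unbound_drop_kbt = 3,
                           kappa_ts = 355.3, x0_ts = 0.39,
                           kappa_u = 30.7, x0_u = 0.21, x0_b = 0.34,
                           sigma_x = 0.25, x_range = NULL,
                           bin_width = 0.085) {
  stopifnot(force >= 0, n_pairs >= 2, eps_kbt > 0)
  nb <- 0:n_pairs
  x_u <- n_pairs * (force / kappa_u + x0_u)
  x_b <- n_pairs * x0_b
  x_t <- n_pairs * (force / kappa_ts + x0_ts)
  x_t <- max(x_t, x_u, x_b)   # nucleated duplex is the most extended state
  centers <- numeric(length(nb))
  centers[1] <- x_u
  centers[-1] <- x_t + (nb[-1] - 1) / (n_pairs - 1) * (x_b - x_t)
  g0 <- c(eps_kbt * (n_pairs - 1) - unbound_drop_kbt,   # n_bp = 0
          eps_kbt * (n_pairs - nb[-1]))                 # n_bp = 1..n_pairs
  sigma_x <- rep_len(sigma_x, length(nb))
  if (is.null(x_range)) {
    x_range <- c(min(centers) - 4 * max(sigma_x),
                 max(centers) + 4 * max(sigma_x))
  }
  x_mids <- seq(x_range[1] + bin_width / 2, x_range[2], by = bin_width)
  G <- vapply(seq_along(nb), function(j) {
    g0[j] + (x_mids - centers[j])^2 / (2 * sigma_x[j]^2)
  }, numeric(length(x_mids)))
  p <- exp(-G)
  surf <- build_surface(p / sum(p), x_mids = x_mids, n_bp_levels = nb,
                        force = force)
  attr(surf, "centers") <- centers
  surf
}

#' Sample biased configurations from a toy zipper surface
#'
#' Draws exact samples from the discretized biased distribution
#' \eqn{q(x, n_{bp}) \propto e^{-G(x, n_{bp})} W(n_{bp})}, providing ground
#' truth for umbrella-reweighting tests.
#'
#' @param n Number of samples.
#' @param force Force in pN.
#' @param weights Named umbrella weights per n_bp stratum;
#'   `"flatten"` derives weights proportional to the inverse equilibrium
#'   stratum marginals (the idealized umbrella protocol, giving every
#'   stratum comparable sampling); default `exp(bias_c * n_bp)`.
#' @param bias_c Exponential bias rate used for the default weights.
#' @param seed Seed.
#' @param ... Passed to [zipper_surface()].
#' @return List with `x`, `n_bp`, `weights`, and the generating `surface`.
#' @export
gen_landscape_samples <- function(n, force, weights = NULL, bias_c = 0.8,
                                  seed = NULL, ...) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  surf <- zipper_surface(force, ...)
  nb <- surf$n_bp_levels
  if (is.null(weights)) {
    weights <- setNames(exp(bias_c * nb), nb)
  } else if (identical(weights, "flatten")) {
    marg <- colSums(exp(-surf$G))
    weights <- setNames(max(marg) / marg, nb)
  }
  q <- exp(-surf$G)
  q <- sweep(q, 2, weights[as.character(nb)], "*")
  cells <- sample.int(length(q), n, replace = TRUE, prob = as.vector(q))
  i <- (cells - 1L) %% nrow(q) + 1L
  j <- (cells - 1L) %/% nrow(q) + 1L
  list(x = surf$x_mids[i], n_bp = nb[j], weights = weights, surface = surf)
}

#' Sample end-to-end distances of discrete worm-like chains
#'
#' Discrete WLC: `n_segments` straight segments; between consecutive
#' segments the tangent bends by independent Gaussian angles of variance
#' (segment length)/P in each of the two transverse directions. Used as the
#' Monte-Carlo oracle for the interpolated radial distribution.
#'
#' @param L Contour length (nm).
#' @param P Persistence length (nm).
#' @param n_segments Segments per chain.
#' @param n_chains Number of chains.
#' @param seed Seed.
#' @return Numeric vector of end-to-end distances (nm).
#' @export
gen_wlc_chains <- function(L, P, n_segments = 100L, n_chains = 1000L,
                           seed = NULL) {
  stopifnot(L > 0, P > 0, n_segments >= 2, n_chains >= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- L / n_segments
  sd_ang <- sqrt(s / P)
  # vectorized across chains: tangents as n_chains x 3 matrices
  t1 <- matrix(rep(c(0, 0, 1), each = n_chains), ncol = 3)
  pos <- matrix(0, n_chains, 3)
  for (i in seq_len(n_segments)) {
    pos <- pos + t1 * s
    if (i < n_segments) {
      # orthonormal transverse frame per chain
      use_x <- abs(t1[, 1]) < 0.9
      u <- cbind(ifelse(use_x, 1, 0), ifelse(use_x, 0, 1), 0)
      dotp <- rowSums(u * t1)
      e1 <- u - dotp * t1
      e1 <- e1 / sqrt(rowSums(e1^2))
      e2 <- cbind(t1[, 2] * e1[, 3] - t1[, 3] * e1[, 2],
                  t1[, 3] * e1[, 1] - t1[, 1] * e1[, 3],
                  t1[, 1] * e1[, 2] - t1[, 2] * e1[, 1])
      a1 <- rnorm(n_chains, 0, sd_ang)
      a2 <- rnorm(n_chains, 0, sd_ang)
      # rotate the tangent by the bend angle (a true rotation, so the
      # tangent correlation is exactly E[cos theta])
      theta <- sqrt(a1^2 + a2^2)
      perp <- (a1 * e1 + a2 * e2) / ifelse(theta > 0, theta, 1)
      t1 <- cos(theta) * t1 + sin(theta) * perp
    }
  }
  sqrt(rowSums(pos^2))
}
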