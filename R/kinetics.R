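#' Force-dependent rate law
#'
#' Two-state binding/unbinding kinetics under tension follow
#' \deqn{k_\alpha(f) = k_\alpha(0)\exp\Big(\int_0^f \Delta x^\ddagger(f')\,
#'   df'/k_BT\Big),}
#' where \eqn{\Delta x^\ddagger(f) = x_\ddagger(f) - x_\alpha(f)} is the
#' extension of the transition state relative to the unbound (binding) or
#' bound (unbinding) state. The rate law bundles the zero-force rates with
#' force-extension relations for the three states.
#'
#' @param kon0 Zero-force binding rate (1/(M s), > 0).
#' @param koff0 Zero-force unbinding rate (1/s, > 0).
#' @param fer_u,fer_b,fer_ts Force-extension relations of the unbound,
#'   bound, and transition states (anything accepted by [fer_extension()]).
#' @param temp_c Temperature in Celsius.
#' @return Object of class `rate_law`.
#' @export
rate_law <- function(kon0, koff0, fer_u, fer_b, fer_ts, temp_c = 22) {
  stopifnot(kon0 > 0, koff0 > 0)
  structure(list(kon0 = kon0, koff0 = koff0, fer_u = fer_u, fer_b = fer_b,
                 fer_ts = fer_ts, temp_c = temp_c), class = "rate_law")
}

#' @export
print.rate_law <- function(x, ...) {
  cat(sprintf("<rate_law> kon(0) = %.4g /(M s), koff(0) = %.4g /s, T = %g C\n",
              x$kon0, x$koff0, x$temp_c))
  invisible(x)
}

#' Rate at force by quadrature of the transition-state extension gap
#'
#' Evaluates the rate law by adaptive quadrature of
#' \eqn{\int_0^f \Delta x^\ddagger(f')df'}. Also returns the local slope
#' \eqn{d\log k/df = \Delta x^\ddagger(f)/k_BT}.
#'
#' @param law A [rate_law()].
#' @param direction `"on"` (relative to the unbound state) or `"off"`
#'   (relative to the bound state).
#' @param f Force(s) in pN (>= 0).
#' @return List with `rate` (same length as `f`) and `slope`
#'   (d log k / df, 1/pN).
#' @examples
#' law <- rate_law(1e7, 0.5,
#'   fer_u = linear_fer_per_nt(30.7, 0.21, 9),
#'   fer_b = linear_fer_per_nt(1e9, 0.34, 9),
#'   fer_ts = linear_fer_per_nt(355.3, 0.39, 9))
#' rate_vs_force(law, "off", c(1.6, 6.25))
#' @export
rate_vs_force <- function(law, direction = c("on", "off"), f) {
  direction <- match.arg(direction)
  stopifnot(inherits(law, "rate_law"))
  if (any(f < 0)) stop("force must be non-negative")
  kBT <- thermal_energy(law$temp_c)
  ref <- if (direction == "on") law$fer_u else law$fer_b
  k0 <- if (direction == "on") law$kon0 else law$koff0
  dx <- function(fp) fer_extension(law$fer_ts, fp) - fer_extension(ref, fp)
  integral <- vapply(f, function(fi) {
    if (fi == 0) return(0)
    integrate(dx, 0, fi, rel.tol = 1e-12, abs.tol = 1e-14,
              subdivisions = 400L)$value
  }, numeric(1))
  list(rate = k0 * exp(integral / kBT), slope = dx(f) / kBT)
}

#' Closed-form rates for linear force-extension relations
#'
#' With linear per-nucleotide FERs the rate-law integral evaluates in closed
#' form:
#' \deqn{k_{on}(f) = k_{on}(0)\exp\Big[\frac{n}{k_BT}\Big\{
#'   \Big(\frac{1}{\kappa_\ddagger}-\frac{1}{\kappa_u}\Big)\frac{f^2}{2}
#'   + (x_{0,\ddagger}-x_{0,u})f\Big\}\Big]}
#' \deqn{k_{off}(f) = k_{off}(0)\exp\Big[\frac{n}{k_BT}\Big\{
#'   \frac{1}{\kappa_\ddagger}\frac{f^2}{2}
#'   + (x_{0,\ddagger}-x_{0,b})f\Big\}\Big]}
#' (the bound state is treated as inextensible). Because the transition
#' state is stiff, `koff` is close to a pure Bell exponential.
#'
#' @param f Force(s) in pN.
#' @param kon0,koff0 Zero-force rates.
#' @param kappa_ts,x0_ts Transition-state per-nucleotide stiffness (pN/nm)
#'   and relaxed extension (nm).
#' @param kappa_u,x0_u Unbound-state per-nucleotide parameters.
#' @param x0_b Bound-state relaxed extension per nucleotide (nm/bp rise).
#' @param n Number of nucleotides in the probe-binding region.
#' @param temp_c Temperature in Celsius.
#' @return Rate(s), same length as `f`.
#' @examples
#' p <- seq_averaged_params()
#' koff_closed_form(6.25, 1, p$kappa_ts, p$x0_ts, n = 9) /
#'   koff_closed_form(1.6, 1, p$kappa_ts, p$x0_ts, n = 9)   # ~2-fold
#' @export
kon_closed_form <- function(f, kon0, kappa_ts, x0_ts, kappa_u, x0_u, n,
                            temp_c = 22) {
  stopifnot(kappa_ts > 0, kappa_u > 0, n > 0)
  kBT <- thermal_energy(temp_c)
  kon0 * exp((n / kBT) *
               ((1 / kappa_ts - 1 / kappa_u) * f^2 / 2 + (x0_ts - x0_u) * f))
}

#' @rdname kon_closed_form
#' @export
koff_closed_form <- function(f, koff0, kappa_ts, x0_ts, x0_b = 0.34, n,
                             temp_c = 22) {
  stopifnot(kappa_ts > 0, n > 0)
  kBT <- thermal_energy(temp_c)
  koff0 * exp((n / kBT) * ((1 / kappa_ts) * f^2 / 2 + (x0_ts - x0_b) * f))
}

#' Sequence-averaged per-nucleotide FER parameters
#'
#' The per-nucleotide stiffness and relaxed extension of the transition and
#' unbound states obtained by rescaling per-sequence linear FERs by their
#' nucleotide count and averaging across sequences:
#' \eqn{\kappa_\ddagger = 355.3} pN/nm, \eqn{x_{0,\ddagger} = 0.39} nm,
#' \eqn{\kappa_u = 30.7} pN/nm, \eqn{x_{0,u} = 0.21} nm, with the bound
#' state fixed at \eqn{x_{0,b} = 0.34} nm and treated as inextensible.
#'
#' @return Named list `kappa_ts`, `x0_ts`, `kappa_u`, `x0_u`, `x0_b`.
#' @export
seq_averaged_params <- function() {
  list(kappa_ts = 355.3, x0_ts = 0.39, kappa_u = 30.7, x0_u = 0.21,
       x0_b = 0.34)
}

#' Standard free energy of duplex formation from rates
#'
#' \eqn{\Delta G^\circ = k_BT \log(k_{on}[c_0]/k_{off})} with reference
#' concentration \eqn{c_0 = 1} M; positive values mean a more stable duplex.
#' If rate SEMs are given, the uncertainty is propagated as
#' \eqn{\sigma_{\Delta G} = \sqrt{(\sigma_{on}/k_{on})^2 +
#'   (\sigma_{off}/k_{off})^2}} (in kBT).
#'
#' @param kon Binding rate (1/(M s)).
#' @param koff Unbinding rate (1/s).
#' @param kon_sem,koff_sem Optional SEMs.
#' @param c0 Reference concentration (M), 1 by default.
#' @return List with `dG` (kBT units) and `dG_err` (kBT, `NA` without SEMs).
#' @examples
#' delta_g(1e7, 0.1)   # ln(1e8) ~ 18.42 kBT
#' @export
delta_g <- function(kon, koff, kon_sem = NULL, koff_sem = NULL, c0 = 1) {
  stopifnot(kon > 0, koff > 0, c0 > 0)
  err <- if (!is.null(kon_sem) && !is.null(koff_sem)) {
    sqrt((kon_sem / kon)^2 + (koff_sem / koff)^2)
  } else NA_real_
  list(dG = log(kon * c0 / koff), dG_err = err)
}

#' Duplex stability versus force
#'
#' \deqn{\Delta G^\circ(f) = \Delta G^\circ(0) - \int_0^f
#'   \big(x_u(f') - x_b(f')\big)\,df'} in kBT units. With worm-like-chain
#' FERs for ssDNA and dsDNA the curve is concave with its maximum at the
#' extension crossover force.
#'
#' @param dg0 Zero-force stability in kBT.
#' @param fer_u,fer_b Force-extension relations of the unbound and bound
#'   states ([fer_extension()]-compatible).
#' @param f_grid Forces (pN) at which to evaluate.
#' @param temp_c Temperature in Celsius.
#' @return Data frame with columns `force_pN`, `dG_kBT`.
#' @export
delta_g_vs_force <- function(dg0, fer_u, fer_b, f_grid, temp_c = 22) {
  stopifnot(all(f_grid >= 0))
  kBT <- thermal_energy(temp_c)
  gap <- function(fp) fer_extension(fer_u, fp) - fer_extension(fer_b, fp)
  dg <- vapply(f_grid, function(fi) {
    if (fi == 0) return(dg0)
    dg0 - integrate(gap, 0, fi, rel.tol = 1e-10,
                    subdivisions = 400L)$value / kBT
  }, numeric(1))
  data.frame(force_pN = f_grid, dG_kBT = dg)
}

# ---- model fitting -------------------------------------------------------

# Weighted polynomial regression of log-rate on (f, f^2/2): the linear-FER
# rate law is linear in (log k0, slope, curvature), so weighted linear least
# squares is the exact joint optimum.
.fit_logquad <- function(f, k, sem) {
  y <- log(k)
  w <- if (all(is.finite(sem)) && all(sem > 0)) (k / sem)^2 else rep(1, length(k))
  X <- cbind(1, f, f^2 / 2)
  fit <- lm.wfit(X, y, w)
  XtWX <- crossprod(X * sqrt(w))
  res <- y - X %*% fit$coefficients
  dof <- length(y) - 3L
  s2 <- if (dof > 0) sum(w * res^2) / dof else 1
  list(coef = fit$coefficients, vcov = s2 * solve(XtWX),
       residuals = as.numeric(res), weights = w)
}

#' Fit a force-dependent rate model to measured rates
#'
#' Simultaneously fits `kon(f)` and `koff(f)` in log-rate space, weighted by
#' the measurement SEMs.
#'
#' Two models are available:
#' * `"linear"` -- linear per-nucleotide FERs for the unbound and transition
#'   states with the bound state fixed at `x0_b` nm per nucleotide; six free
#'   parameters (`kon0`, `koff0`, `kappa_ts`, `x0_ts`, `kappa_u`, `x0_u`).
#'   After the log transform the model is linear in its parameters, so the
#'   optimum is found exactly by weighted linear least squares.
#' * `"marko_siggia"` -- all three states follow Marko-Siggia FERs; the
#'   unbound and bound persistence/contour lengths are fixed (package
#'   defaults unless overridden via `fixed`) and `P_ts`, `L_ts`, `kon0`,
#'   `koff0` are fitted by multi-start Levenberg-Marquardt.
#'
#' @param data Data frame with columns `force`, `kon`, `koff` and optionally
#'   `kon_sem`, `koff_sem` (used as weights).
#' @param model `"linear"` or `"marko_siggia"`.
#' @param n Number of nucleotides in the probe-binding region (8 or 9).
#' @param x0_b Bound-state rise per nucleotide (nm), fixed.
#' @param fixed For `"marko_siggia"`: named list overriding `P_u`, `L_u`,
#'   `P_b`, `L_b` (nm).
#' @param n_starts Number of seeded starts for the Marko-Siggia fit.
#' @param seed Seed for the multi-start draw.
#' @param temp_c Temperature in Celsius.
#' @return Object of class `rate_fit` with fields `model`, `par` (named
#'   list), `se`, `residuals`, `n_obs`, and for the linear model `fers`
#'   (per-state [linear_fer()]s) and `vcov` of the regression coefficients.
#' @export
fit_rate_model <- function(data, model = c("linear", "marko_siggia"), n,
                           x0_b = 0.34, fixed = list(), n_starts = 10L,
                           seed = 1L, temp_c = 22) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data), all(c("force", "kon", "koff") %in% names(data)),
            n > 0)
  if (length(unique(data$force)) < 4) {
    stop("need measurements at >= 4 distinct forces for identifiability")
  }
  kBT <- thermal_energy(temp_c)
  kon_sem <- if ("kon_sem" %in% names(data)) data$kon_sem else rep(NA_real_, nrow(data))
  koff_sem <- if ("koff_sem" %in% names(data)) data$koff_sem else rep(NA_real_, nrow(data))

  if (model == "linear") {
    fon <- .fit_logquad(data$force, data$kon, kon_sem)
    foff <- .fit_logquad(data$force, data$koff, koff_sem)
    s <- n / kBT
    c_ts <- unname(foff$coef[3]) / s         # 1/kappa_ts
    dc <- unname(fon$coef[3]) / s            # 1/kappa_ts - 1/kappa_u
    c_u <- c_ts - dc
    # physical bounds kappa in [1, 1e4] pN/nm; noisy fits can push a
    # compliance past them, in which case it is clamped to the boundary
    if (c_ts < 1e-4 || c_ts > 1 || c_u < 1e-4 || c_u > 1) {
      warning("fitted compliance outside physical bounds; clamped")
      c_ts <- min(max(c_ts, 1e-4), 1)
      c_u <- min(max(c_u, 1e-4), 1)
    }
    x0_ts <- unname(foff$coef[2] / s + x0_b)
    x0_u <- unname(x0_ts - fon$coef[2] / s)
    par <- list(kon0 = exp(unname(fon$coef[1])), koff0 = exp(unname(foff$coef[1])),
                kappa_ts = 1 / c_ts, x0_ts = x0_ts,
                kappa_u = 1 / c_u, x0_u = x0_u, x0_b = x0_b, n = n)
    # delta-method standard errors from the two independent regressions
    v_on <- fon$vcov; v_off <- foff$vcov
    se <- list(
      kon0 = par$kon0 * sqrt(v_on[1, 1]),
      koff0 = par$koff0 * sqrt(v_off[1, 1]),
      kappa_ts = sqrt(v_off[3, 3]) / s / c_ts^2,
      x0_ts = sqrt(v_off[2, 2]) / s,
      kappa_u = sqrt((v_off[3, 3] + v_on[3, 3])) / s / c_u^2,
      x0_u = sqrt(v_off[2, 2] + v_on[2, 2]) / s
    )
    fers <- list(
      u = linear_fer_per_nt(par$kappa_u, par$x0_u, n),
      ts = linear_fer_per_nt(par$kappa_ts, par$x0_ts, n),
      b = linear_fer_per_nt(1e9, x0_b, n)
    )
    out <- list(model = "linear", par = par, se = se, fers = fers,
                vcov = list(on = v_on, off = v_off),
                residuals = c(on = fon$residuals, off = foff$residuals),
                n_obs = 2L * nrow(data))
    return(structure(out, class = "rate_fit"))
  }

  # Marko-Siggia variant: P_ts, L_ts free; unbound/bound fixed
  defs <- polymer_defaults()
  fx <- modifyList(list(P_u = defs$ssdna_persistence_nm,
                        L_u = n * defs$ssdna_nm_per_nt,
                        P_b = defs$dsdna_persistence_nm,
                        L_b = n * defs$dsdna_rise_nm), fixed)
  fer_u <- wlc_model(fx$L_u, fx$P_u)
  fer_b <- wlc_model(fx$L_b, fx$P_b)
  fmax <- max(data$force)
  fg <- seq(0, fmax * 1.001, length.out = 257L)
  # cumulative integral of an extension curve on the shared force grid
  cumint <- function(x) pracma::cumtrapz(fg, x)[, 1]
  int_u <- cumint(ms_extension(fer_u, fg, temp_c))
  int_b <- cumint(ms_extension(fer_b, fg, temp_c))
  w_on <- if (all(is.finite(kon_sem)) && all(kon_sem > 0)) data$kon / kon_sem else rep(1, nrow(data))
  w_off <- if (all(is.finite(koff_sem)) && all(koff_sem > 0)) data$koff / koff_sem else rep(1, nrow(data))
  residfun <- function(p) {
    P_ts <- exp(p[1]); L_ts <- exp(p[2])
    int_ts <- cumint(ms_extension(wlc_model(L_ts, P_ts), fg, temp_c))
    ion <- approx(fg, int_ts - int_u, data$force)$y / kBT
    ioff <- approx(fg, int_ts - int_b, data$force)$y / kBT
    c(w_on * (log(data$kon) - (p[3] + ion)),
      w_off * (log(data$koff) - (p[4] + ioff)))
  }
  set.seed(seed)
  starts <- cbind(log(runif(n_starts, 0.5, 60)),
                  log(n * runif(n_starts, 0.3, 0.75)),
                  log(mean(data$kon)) + rnorm(n_starts, 0, 0.3),
                  log(mean(data$koff)) + rnorm(n_starts, 0, 0.3))
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(starts[i, ], fn = residfun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("Marko-Siggia fit failed from every start")
  p <- best$par
  par <- list(P_ts = exp(p[1]), L_ts = exp(p[2]),
              kon0 = exp(p[3]), koff0 = exp(p[4]),
              P_u = fx$P_u, L_u = fx$L_u, P_b = fx$P_b, L_b = fx$L_b, n = n)
  se_log <- tryCatch(sqrt(diag(vcov(best))), error = function(e) rep(NA_real_, 4))
  se <- list(P_ts = par$P_ts * se_log[1], L_ts = par$L_ts * se_log[2],
             kon0 = par$kon0 * se_log[3], koff0 = par$koff0 * se_log[4])
  structure(list(model = "marko_siggia", par = par, se = se,
                 fers = list(u = fer_u, b = fer_b,
                             ts = wlc_model(par$L_ts, par$P_ts)),
                 residuals = best$fvec, deviance = best$deviance,
                 n_obs = 2L * nrow(data)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> model = %s, %d observations\n", x$model, x$n_obs))
  if (x$model == "linear") {
    cat(sprintf("  kon0 = %.4g, koff0 = %.4g\n", x$par$kon0, x$par$koff0))
    cat(sprintf("  kappa_ts = %.4g pN/nm, x0_ts = %.4g nm\n",
                x$par$kappa_ts, x$par$x0_ts))
    cat(sprintf("  kappa_u  = %.4g pN/nm, x0_u  = %.4g nm\n",
                x$par$kappa_u, x$par$x0_u))
  } else {
    cat(sprintf("  kon0 = %.4g, koff0 = %.4g, P_ts = %.4g nm, L_ts = %.4g nm\n",
                x$par$kon0, x$par$koff0, x$par$P_ts, x$par$L_ts))
  }
  invisible(x)
}

#' Predict rates from a fitted model
#'
#' @param object A `rate_fit`.
#' @param f Forces in pN.
#' @param temp_c Temperature in Celsius.
#' @param ... Unused.
#' @return Data frame `force`, `kon`, `koff`.
#' @export
predict.rate_fit <- function(object, f, temp_c = 22, ...) {
  p <- object$par
  if (object$model == "linear") {
    data.frame(
      force = f,
      kon = kon_closed_form(f, p$kon0, p$kappa_ts, p$x0_ts, p$kappa_u,
                            p$x0_u, p$n, temp_c),
      koff = koff_closed_form(f, p$koff0, p$kappa_ts, p$x0_ts, p$x0_b, p$n,
                              temp_c))
  } else {
    law <- rate_law(p$kon0, p$koff0, object$fers$u, object$fers$b,
                    object$fers$ts, temp_c)
    data.frame(force = f,
               kon = rate_vs_force(law, "on", f)$rate,
               koff = rate_vs_force(law, "off", f)$rate)
  }
}

#' Sequence-averaged per-nucleotide FER
#'
#' Rescales per-sequence linear FERs by their nucleotide counts and averages
#' the per-nucleotide stiffness and relaxed extension.
#'
#' @param fers List of [linear_fer()] objects. Each must carry `per_nt`
#'   metadata, or `n` must be supplied.
#' @param n Optional vector of nucleotide counts overriding `per_nt`.
#' @return A list with `kappa` and `x0` (per-nucleotide averages) and the
#'   per-sequence values in `per_sequence`.
#' @export
sequence_average_fer <- function(fers, n = NULL) {
  stopifnot(length(fers) >= 1)
  if (is.null(n)) {
    n <- vapply(fers, function(fer) {
      if (is.null(fer$per_nt)) stop("FER lacks per-nt metadata; supply n")
      fer$per_nt$n
    }, numeric(1))
  }
  stopifnot(length(n) == length(fers))
  kappa <- vapply(seq_along(fers), function(i) fers[[i]]$a * n[i], numeric(1))
  x0 <- vapply(seq_along(fers), function(i) fers[[i]]$b / n[i], numeric(1))
  list(kappa = mean(kappa), x0 = mean(x0),
       per_sequence = data.frame(n = n, kappa = kappa, x0 = x0))
}

#' Dynamic range of a rate across the measured force range
#'
#' Ratio of the rate at the highest force to the rate at the lowest force,
#' with the uncertainty propagated from the two underlying rates:
#' \eqn{\sigma_R/R = \sqrt{(\sigma_1/k_1)^2 + (\sigma_2/k_2)^2}}.
#'
#' @param force Forces in pN.
#' @param rate Rates at those forces.
#' @param sem Optional rate SEMs.
#' @return List with `ratio`, `ratio_err`, `f_low`, `f_high`.
#' @export
dynamic_range <- function(force, rate, sem = NULL) {
  stopifnot(length(force) == length(rate), length(force) >= 2, all(rate > 0))
  ilo <- which.min(force); ihi <- which.max(force)
  ratio <- rate[ihi] / rate[ilo]
  err <- if (!is.null(sem)) {
    ratio * sqrt((sem[ihi] / rate[ihi])^2 + (sem[ilo] / rate[ilo])^2)
  } else NA_real_
  list(ratio = ratio, ratio_err = err,
       f_low = force[ilo], f_high = force[ihi])
}

# ---- nearest-neighbor thermodynamics -------------------------------------

.nn_complement <- function(s) {
  chartr("ACGT", "TGCA", s)
}

.nn_revcomp <- function(s) {
  paste(rev(strsplit(.nn_complement(s), "")[[1]]), collapse = "")
}

#' Nearest-neighbor duplex stability
#'
#' Standard free energy of a DNA/DNA duplex from a nearest-neighbor
#' parameter table (dimer stacking enthalpies/entropies plus terminal
#' initiation), evaluated at the configured temperature and reported in kBT
#' with the convention that positive values mean a more stable duplex.
#' Optional additive corrections model dangling-end stacking (about 1 kBT
#' per duplex end flanked by unpaired bases) and a terminal 5' cyanine dye
#' (about 2 kBT).
#'
#' @param sequence Duplex top-strand sequence, 5'->3' (A/C/G/T, length >= 2).
#' @param table Parameter table: data frame with columns `motif`,
#'   `dh_kcal_mol`, `ds_cal_mol_k`. Defaults to the unified DNA set shipped
#'   with the package.
#' @param dangling_ends Number of duplex ends with adjacent unpaired bases
#'   (0, 1, or 2); each adds `dangling_kbt`.
#' @param dye Logical: add a 5' dye-stabilization term of `dye_kbt`.
#' @param dangling_kbt,dye_kbt Correction magnitudes in kBT.
#' @param temp_c Temperature in Celsius.
#' @return Stability in kBT (positive = stable).
#' @examples
#' nn_duplex_dg("GTAAATTCA")
#' nn_duplex_dg("GTAAATTCA", dangling_ends = 2, dye = TRUE)
#' @export
nn_duplex_dg <- function(sequence, table = NULL, dangling_ends = 0,
                         dye = FALSE, dangling_kbt = 1, dye_kbt = 2,
                         temp_c = 22) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGT]+$", sequence)) stop("sequence must contain only A/C/G/T")
  if (nchar(sequence) < 2) stop("sequence must have length >= 2")
  stopifnot(dangling_ends %in% 0:2)
  if (is.null(table)) {
    table <- read.csv(system.file("extdata", "nn_unified_dna.csv",
                                  package = "bowkit"))
  }
  tK <- temp_c + 273.15
  dg_kcal <- function(motif) {
    i <- match(motif, table$motif)
    if (is.na(i)) i <- match(.nn_revcomp(motif), table$motif)
    if (is.na(i)) stop("no nearest-neighbor parameters for motif ", motif)
    table$dh_kcal_mol[i] - tK * table$ds_cal_mol_k[i] / 1000
  }
  chars <- strsplit(sequence, "")[[1]]
  steps <- paste0(chars[-length(chars)], chars[-1])
  total <- sum(vapply(steps, dg_kcal, numeric(1)))
  ends <- c(chars[1], chars[length(chars)])
  total <- total + sum(vapply(ends, function(b) {
    dg_kcal(if (b %in% c("A", "T")) "init_AT" else "init_GC")
  }, numeric(1)))
  # kcal/mol -> kBT; flip sign so that stable duplexes are positive
  R_kcal <- 0.0019872
  dg <- -total / (R_kcal * tK)
  dg + dangling_ends * dangling_kbt + if (dye) dye_kbt else 0
}
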