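#' Worm-like chain model
#'
#' A worm-like chain (WLC) is described by its contour length and persistence
#' length. This object parameterizes both the interpolated end-to-end
#' distance distribution (used for arc tension calibration) and the
#' Marko-Siggia force-extension relation.
#'
#' @param contour_length Contour length L in nm (> 0).
#' @param persistence_length Persistence length P in nm (> 0).
#' @return An object of class `wlc_model`.
#' @examples
#' arc <- wlc_model(74 * 0.34, 50)  # 74 bp dsDNA arc
#' @export
wlc_model <- function(contour_length, persistence_length) {
  stopifnot(is.numeric(contour_length), length(contour_length) == 1L,
            contour_length > 0,
            is.numeric(persistence_length), length(persistence_length) == 1L,
            persistence_length > 0)
  structure(list(L = contour_length, P = persistence_length),
            class = "wlc_model")
}

#' @export
print.wlc_model <- function(x, ...) {
  cat(sprintf("<wlc_model> L = %.4g nm, P = %.4g nm (L/P = %.3g)\n",
              x$L, x$P, x$L / x$P))
  invisible(x)
}

# Log of the interpolated end-to-end *vector* density Q(r; kap), r = x/L,
# kap = P/L, up to an r-independent constant. Interpolates between the
# flexible-coil and stiff (Shimada-Yamakawa-like) limits and is accurate over
# a wide range of bending stiffness. The Bessel factor is evaluated in
# exponentially scaled form to stay finite for very stiff chains.
.wlc_log_qvec <- function(r, kap) {
  a <- 14.054
  b <- 0.473
  cc <- 1 - (1 + (0.38 * kap^(-0.95))^(-5))^(-1/5)
  d <- if (kap >= 0.125) {
    1 - 1 / (0.177 / (kap - 0.111) + 6.40 * (kap - 0.111)^0.783)
  } else 0
  cij <- rbind(c(-3 / 4, 23 / 64, -7 / 64),   # kap^{-1} row
               c(-1 / 2, 17 / 16, -9 / 16))   # kap^{0} row
  r2 <- r * r
  poly <- (cij[1, 1] / kap + cij[2, 1]) * r2 +
          (cij[1, 2] / kap + cij[2, 2]) * r2^2 +
          (cij[1, 3] / kap + cij[2, 3]) * r2^3
  z <- d * kap * a * (1 + b) * r / (1 - b^2 * r2)
  2.5 * log((1 - cc * r2) / (1 - r2)) +
    poly / (1 - r2) -
    d * kap * a * b * (1 + b) * r2 / (1 - b^2 * r2) +
    log(besselI(z, 0, expon.scaled = TRUE)) + z
}

# Log radial density log p(x) of the scalar end-to-end distance, up to a
# constant: includes the 4*pi*x^2 Jacobian.
.wlc_log_radial <- function(x, model) {
  r <- pmin(pmax(x / model$L, 1e-12), 1 - 1e-12)
  .wlc_log_qvec(r, model$P / model$L) + 2 * log(r)
}

#' End-to-end distance distribution of a worm-like chain
#'
#' Normalized probability density of the scalar end-to-end distance x of a
#' free WLC, from an interpolation formula valid from the flexible-coil to
#' the stiff-rod regime. The density is of the scalar distance (the
#' \eqn{4\pi x^2} Jacobian is included), which is the quantity whose
#' log-derivative gives the entropic force.
#'
#' @param model A [wlc_model()].
#' @param x_grid Grid of end-to-end distances in nm, all within `[0, L]`.
#'   Defaults to a dense regular grid on (0, L).
#' @param n_grid Number of grid points used when `x_grid` is `NULL`.
#' @return Object of class `radial_distribution` with fields `x`, `density`
#'   (1/nm, trapezoid-normalized), `log_density` (unnormalized), and `model`.
#' @examples
#' pdfn <- wlc_radial_pdf(wlc_model(25.16, 50))
#' sum(diff(pdfn$x) * (head(pdfn$density, -1) + tail(pdfn$density, -1)) / 2)
#' @export
wlc_radial_pdf <- function(model, x_grid = NULL, n_grid = 2001L) {
  stopifnot(inherits(model, "wlc_model"))
  if (is.null(x_grid)) {
    x_grid <- seq(model$L * 1e-4, model$L * (1 - 1e-9), length.out = n_grid)
  }
  if (any(x_grid < 0 | x_grid > model$L)) {
    stop("x_grid values must lie within [0, L]")
  }
  lp <- .wlc_log_radial(x_grid, model)
  p <- exp(lp - max(lp))
  z <- pracma::trapz(x_grid, p)
  structure(list(x = x_grid, density = p / z, log_density = lp, model = model),
            class = "radial_distribution")
}

#' @export
print.radial_distribution <- function(x, ...) {
  cat(sprintf("<radial_distribution> %d grid points on [%.3g, %.3g] nm",
              length(x$x), min(x$x), max(x$x)))
  if (!is.null(x$model)) cat(sprintf(" (WLC L = %.4g, P = %.4g)", x$model$L, x$model$P))
  cat("\n")
  invisible(x)
}

#' Construct a radial distribution from a tabulated density
#'
#' For densities that do not come from the WLC interpolation (for example
#' histograms of simulated extensions), wrap the table so that
#' [entropic_force()] and [bow_force_estimate()] can consume it. The
#' log-density is splined to suppress noise amplification in the derivative.
#'
#' @param x Grid of end-to-end distances (nm), strictly increasing.
#' @param density Density values (need not be normalized; must be >= 0).
#' @return A `radial_distribution`.
#' @export
radial_distribution <- function(x, density) {
  stopifnot(length(x) == length(density), all(diff(x) > 0), all(density >= 0))
  pos <- density > 0
  if (sum(pos) < 4) stop("need at least 4 grid points with positive density")
  z <- pracma::trapz(x, density)
  structure(list(x = x, density = density / z,
                 log_density = ifelse(pos, log(density), -Inf), model = NULL),
            class = "radial_distribution")
}

# Spline of log p over the positive-density support.
.log_density_spline <- function(dist) {
  ok <- is.finite(dist$log_density)
  splinefun(dist$x[ok], dist$log_density[ok], method = "natural")
}

#' Entropic force from an end-to-end distance distribution
#'
#' The force exerted along the end-to-end direction by a chain held at
#' end-to-end distance `x0` is the thermal log-derivative of the distance
#' distribution, \eqn{f(x_0) = -k_B T \, \partial \log p(x)/\partial x}.
#' For a bow arc held below its most probable extension this signed value is
#' negative (the arc pushes its ends apart); the default convention reports
#' the tension on the bowstring as positive in that situation.
#'
#' @param dist A `radial_distribution` (or a [wlc_model()], which is first
#'   converted via [wlc_radial_pdf()]).
#' @param x0 Evaluation point(s), strictly inside the support.
#' @param convention `"tension"` (default): positive when the arc pushes its
#'   ends apart (tensions the string); `"signed"`: the raw
#'   \eqn{-k_B T \,\partial_x \log p} pulling convention.
#' @param temp_c Temperature in Celsius.
#' @return Force(s) in pN.
#' @examples
#' arc <- wlc_model(25.16, 50)
#' entropic_force(arc, 6)   # tension a 74 bp arc exerts at 6 nm extension
#' @export
entropic_force <- function(dist, x0, convention = c("tension", "signed"),
                           temp_c = 22) {
  convention <- match.arg(convention)
  if (inherits(dist, "wlc_model")) dist <- wlc_radial_pdf(dist)
  stopifnot(inherits(dist, "radial_distribution"))
  ok <- is.finite(dist$log_density)
  lo <- min(dist$x[ok]); hi <- max(dist$x[ok])
  if (any(x0 <= lo | x0 >= hi)) {
    stop(sprintf("x0 must lie strictly inside the sampled support (%.4g, %.4g)",
                 lo, hi))
  }
  kBT <- thermal_energy(temp_c)
  if (!is.null(dist$model)) {
    h <- 1e-6 * dist$model$L
    dlog <- (.wlc_log_radial(x0 + h, dist$model) -
             .wlc_log_radial(x0 - h, dist$model)) / (2 * h)
  } else {
    sf <- .log_density_spline(dist)
    dlog <- sf(x0, deriv = 1L)
  }
  f_signed <- -kBT * dlog
  if (convention == "signed") f_signed else -f_signed
}

#' Marko-Siggia force-extension relation
#'
#' `ms_force()` returns the force needed to hold a WLC at extension `x`;
#' `ms_extension()` inverts it by bracketed root finding (the relation is
#' strictly monotone on `[0, L)`).
#'
#' @param model A [wlc_model()].
#' @param x Extension(s) in nm, `0 <= x < L`.
#' @param f Force(s) in pN, `>= 0`.
#' @param temp_c Temperature in Celsius.
#' @return Force in pN (`ms_force`) or extension in nm (`ms_extension`).
#' @examples
#' ss <- wlc_model(9 * 0.68, 1.04)
#' ms_extension(ss, ms_force(ss, 3))  # = 3
#' @export
ms_force <- function(model, x, temp_c = 22) {
  stopifnot(inherits(model, "wlc_model"))
  if (any(x < 0 | x >= model$L)) stop("extension must satisfy 0 <= x < L")
  z <- x / model$L
  (thermal_energy(temp_c) / model$P) * (1 / (4 * (1 - z)^2) - 1 / 4 + z)
}

# Vectorized bisection for the Marko-Siggia inverse. Root of
# 4u^3 + (4*phi - 3)u^2 - 1 = 0 in u = 1 - x/L for phi = f P / kBT;
# g(0+) = -1 < 0 and g(1) = 4 phi > 0 bracket the unique physical root.
.ms_z_of_phi <- function(phi) {
  lo <- rep(1e-12, length(phi))
  hi <- rep(1 - 1e-12, length(phi))
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    g <- 4 * mid^3 + (4 * phi - 3) * mid^2 - 1
    neg <- g < 0
    lo[neg] <- mid[neg]
    hi[!neg] <- mid[!neg]
  }
  1 - (lo + hi) / 2
}

#' @rdname ms_force
#' @export
ms_extension <- function(model, f, temp_c = 22) {
  stopifnot(inherits(model, "wlc_model"))
  if (any(f < 0)) stop("force must be non-negative")
  z <- numeric(length(f))
  pos <- f > 0
  if (any(pos)) {
    phi <- f[pos] * model$P / thermal_energy(temp_c)
    z[pos] <- .ms_z_of_phi(phi)
  }
  z * model$L
}

#' Finite-chain (short-chain) extension under tension
#'
#' Mean extension of a chain of finite contour length held under constant
#' tension, from the discrete transverse-fluctuation mode sum:
#' \deqn{x/L = 1 - \tfrac12\sqrt{k_BT/(fP)}\,\coth\!\big(L\sqrt{f/(k_BT P)}\big)
#'   + k_BT/(2fL).}
#' Unlike the Marko-Siggia interpolation (an infinite-chain result), this
#' formula retains the chain-length dependence that matters for
#' oligonucleotide-scale segments; its zero-force limit is
#' \eqn{L(1 - L/(6P))}, finite and possibly small or negative for very
#' flexible chains, where the small-transverse-fluctuation assumption breaks
#' down.
#'
#' @inheritParams ms_force
#' @return Extension(s) in nm.
#' @export
short_chain_extension <- function(model, f, temp_c = 22) {
  stopifnot(inherits(model, "wlc_model"))
  if (any(f < 0)) stop("force must be non-negative")
  kBT <- thermal_energy(temp_c)
  L <- model$L; P <- model$P
  out <- numeric(length(f))
  tiny <- f < 1e-9
  # zero-force limit of the mode sum
  out[tiny] <- L * (1 - L / (6 * P))
  fi <- f[!tiny]
  if (length(fi)) {
    y <- L * sqrt(fi / (kBT * P))
    out[!tiny] <- L * (1 - 0.5 * sqrt(kBT / (fi * P)) / tanh(y) +
                         kBT / (2 * fi * L))
  }
  out
}
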