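#' Linear force-extension relation
#'
#' Short DNA segments under weak tension show spring-like behavior,
#' \eqn{x_\alpha(f) = f/a_\alpha + b_\alpha}, with stiffness `a` (pN/nm) and
#' relaxed extension `b` (nm). If the extension scales with the number of
#' nucleotides n, the same relation can be written per nucleotide,
#' \eqn{x = n f/\kappa + n x_0}, with \eqn{a = \kappa/n} and
#' \eqn{b = n x_0}; [linear_fer_per_nt()] constructs that parameterization.
#'
#' @param a Stiffness in pN/nm (> 0).
#' @param b Relaxed extension (intercept) in nm.
#' @param se Optional named numeric with standard errors `a`, `b`.
#' @return Object of class `linear_fer`.
#' @examples
#' u <- linear_fer_per_nt(kappa = 30.7, x0 = 0.21, n = 15)  # unbound 15-nt ssDNA
#' fer_extension(u, 6)
#' @export
linear_fer <- function(a, b, se = NULL) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            is.numeric(b), length(b) == 1L)
  structure(list(a = a, b = b, per_nt = NULL, se = se), class = "linear_fer")
}

#' @param kappa Per-nucleotide stiffness in pN nm^-1 (strictly, the stiffness
#'   of a single nucleotide unit; the chain stiffness is `kappa / n`).
#' @param x0 Relaxed extension per nucleotide in nm.
#' @param n Number of nucleotide units.
#' @rdname linear_fer
#' @export
linear_fer_per_nt <- function(kappa, x0, n) {
  stopifnot(kappa > 0, n > 0)
  out <- linear_fer(a = kappa / n, b = n * x0)
  out$per_nt <- list(kappa = kappa, x0 = x0, n = n)
  out
}

#' @export
print.linear_fer <- function(x, ...) {
  cat(sprintf("<linear_fer> x(f) = f/%.4g + %.4g nm", x$a, x$b))
  if (!is.null(x$per_nt)) {
    cat(sprintf("  [per-nt: kappa = %.4g pN/nm, x0 = %.4g nm, n = %d]",
                x$per_nt$kappa, x$per_nt$x0, as.integer(x$per_nt$n)))
  }
  cat("\n")
  invisible(x)
}

#' Evaluate a force-extension relation
#'
#' Generic extension-at-force operator used by crossover and rate-law code.
#' Methods exist for [linear_fer()] objects, for [wlc_model()] objects
#' (Marko-Siggia inversion), for [short_chain_fer()] wrappers, and for plain
#' functions `f -> x`.
#'
#' @param fer A force-extension relation object.
#' @param f Force(s) in pN.
#' @param ... Passed to methods (e.g. `temp_c`).
#' @return Extension(s) in nm.
#' @export
fer_extension <- function(fer, f, ...) UseMethod("fer_extension")

#' @export
fer_extension.linear_fer <- function(fer, f, ...) f / fer$a + fer$b

#' @export
fer_extension.wlc_model <- function(fer, f, ...) ms_extension(fer, f, ...)

#' @export
fer_extension.function <- function(fer, f, ...) fer(f)

#' Short-chain FER wrapper
#'
#' Marks a [wlc_model()] so that [fer_extension()] uses the finite-chain
#' formula [short_chain_extension()] instead of the Marko-Siggia inversion.
#'
#' @param model A [wlc_model()].
#' @return The model with class `short_chain_fer` prepended.
#' @export
short_chain_fer <- function(model) {
  stopifnot(inherits(model, "wlc_model"))
  class(model) <- c("short_chain_fer", class(model))
  model
}

#' @export
fer_extension.short_chain_fer <- function(fer, f, ...) {
  short_chain_extension(structure(unclass(fer), class = "wlc_model"), f, ...)
}

#' Extension evaluated on the linear FER
#'
#' Convenience alias for `fer_extension()` on a [linear_fer()].
#'
#' @inheritParams fer_extension
#' @export
linear_fer_extension <- function(fer, f) {
  stopifnot(inherits(fer, "linear_fer"))
  fer_extension(fer, f)
}

#' Force at which two force-extension curves cross
#'
#' Finds the force where the extensions of two states become identical, e.g.
#' ssDNA and dsDNA. The curves must cross exactly once inside the bracket.
#'
#' @param fer_a,fer_b Force-extension relations accepted by
#'   [fer_extension()].
#' @param bracket Force bracket in pN (default `c(1e-3, 20)`).
#' @param ... Passed to [fer_extension()].
#' @return Crossover force in pN.
#' @examples
#' ss <- wlc_model(9 * 0.68, 1.04)
#' ds <- wlc_model(9 * 0.34, 50)
#' crossover_force(ss, ds)            # ~4.25 pN
#' # the finite-chain formula assumes small transverse fluctuations, so its
#' # low-force branch is unphysical; bracket above ~0.5 pN
#' crossover_force(short_chain_fer(ss), ds, bracket = c(0.5, 20))  # ~1.8 pN
#' @export
crossover_force <- function(fer_a, fer_b, bracket = c(1e-3, 20), ...) {
  g <- function(f) fer_extension(fer_a, f, ...) - fer_extension(fer_b, f, ...)
  glo <- g(bracket[1]); ghi <- g(bracket[2])
  if (!is.finite(glo) || !is.finite(ghi) || sign(glo) == sign(ghi)) {
    stop("no extension crossover in the force bracket [",
         bracket[1], ", ", bracket[2], "] pN")
  }
  uniroot(g, bracket, tol = 1e-10)$root
}

#' Fit a linear force-extension relation
#'
#' Ordinary least squares of extension on force; the inverse slope is the
#' stiffness `a` and the intercept the relaxed extension `b`. Standard
#' errors are propagated from the regression coefficients.
#'
#' @param force Forces in pN (or a data frame with columns `force_pN`,
#'   `extension_nm`).
#' @param extension Extensions in nm.
#' @return A [linear_fer()] with an `se` field and the underlying `lm` fit
#'   in attribute `"fit"`.
#' @export
fit_linear_fer <- function(force, extension = NULL) {
  if (is.data.frame(force)) {
    extension <- force$extension_nm
    force <- force$force_pN
  }
  stopifnot(length(force) == length(extension), length(force) >= 3)
  if (length(unique(force)) < 2) {
    stop("force values are rank-deficient: need at least two distinct forces")
  }
  fit <- lm(extension ~ force)
  slope <- coef(fit)[["force"]]
  if (slope <= 0) stop("fitted slope is non-positive; not a tension response")
  a <- 1 / slope
  b <- coef(fit)[["(Intercept)"]]
  se <- sqrt(diag(suppressWarnings(vcov(fit))))  # exact fits warn in summary.lm
  out <- linear_fer(a, b,
                    se = c(a = se[["force"]] / slope^2, b = se[["(Intercept)"]]))
  attr(out, "fit") <- fit
  out
}

#' Force from a harmonic trap reading
#'
#' In mutual-trap simulations the strand ends are connected by a harmonic
#' spring of stiffness k and relaxed extension x0; the tension follows from
#' the mean extension as \eqn{f = -k(\bar{x} - x_0)}.
#'
#' @param k Trap stiffness in pN/nm (> 0).
#' @param x0 Relaxed trap extension in nm.
#' @param xbar Observed mean extension in nm.
#' @return Force in pN.
#' @examples
#' trap_force(57.1, 7.0, 6.9)  # 5.71 pN
#' @export
trap_force <- function(k, x0, xbar) {
  stopifnot(k > 0)
  -k * (xbar - x0)
}

#' Read or write linear FER parameters as JSON
#'
#' Serializes a named list of [linear_fer()] objects (per state) to the
#' interchange schema `state, a_pN_per_nm, b_nm, kappa, x0, n`.
#'
#' @param fers Named list of `linear_fer` objects.
#' @param path File path.
#' @return `write_fer_json()` returns `path` invisibly; `read_fer_json()`
#'   returns a named list of `linear_fer` objects.
#' @export
write_fer_json <- function(fers, path) {
  stopifnot(is.list(fers), length(names(fers)) == length(fers))
  rows <- lapply(names(fers), function(nm) {
    fer <- fers[[nm]]
    list(state = nm, a_pN_per_nm = fer$a, b_nm = fer$b,
         kappa = if (is.null(fer$per_nt)) NA else fer$per_nt$kappa,
         x0 = if (is.null(fer$per_nt)) NA else fer$per_nt$x0,
         n = if (is.null(fer$per_nt)) NA else fer$per_nt$n)
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_fer_json
#' @export
read_fer_json <- function(path) {
  rows <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list()
  for (row in rows) {
    fer <- if (!is.null(row$kappa) && !is.na(row$kappa)) {
      linear_fer_per_nt(row$kappa, row$x0, row$n)
    } else {
      linear_fer(row$a_pN_per_nm, row$b_nm)
    }
    out[[row$state]] <- fer
  }
  out
}
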