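#' Summary statistics of an extension ensemble
#'
#' Mean and standard deviation of a molecule's end-to-end extension
#' distribution, the inputs to [bow_force_estimate()].
#'
#' @param mean_extension Mean extension in nm (or a numeric vector of raw
#'   extension samples, in which case the other arguments are ignored).
#' @param sd_extension Standard deviation in nm (>= 0).
#' @param n_samples Number of samples (>= 2).
#' @return Object of class `extension_stats`.
#' @export
extension_stats <- function(mean_extension, sd_extension = NULL,
                            n_samples = NULL) {
  if (length(mean_extension) > 1L) {
    x <- mean_extension
    stopifnot(length(x) >= 2, all(is.finite(x)))
    return(structure(list(mean = mean(x), sd = sd(x), n = length(x)),
                     class = "extension_stats"))
  }
  stopifnot(sd_extension >= 0, n_samples >= 2)
  structure(list(mean = mean_extension, sd = sd_extension, n = n_samples),
            class = "extension_stats")
}

#' @export
print.extension_stats <- function(x, ...) {
  cat(sprintf("<extension_stats> mean = %.4g nm, sd = %.4g nm, n = %d\n",
              x$mean, x$sd, as.integer(x$n)))
  invisible(x)
}

#' Read extension samples from a text file
#'
#' Accepts either a CSV with a column `extension_nm` or a plain one-column
#' series of extensions (one value per line, as written by coarse-grained
#' simulation post-processing).
#'
#' @param path File path.
#' @return An [extension_stats()] with the raw samples in attribute
#'   `"samples"`.
#' @export
read_extension_samples <- function(path) {
  first <- readLines(path, n = 1L)
  x <- if (grepl("extension_nm", first, fixed = TRUE)) {
    read.csv(path)$extension_nm
  } else {
    scan(path, quiet = TRUE)
  }
  out <- extension_stats(x)
  attr(out, "samples") <- x
  out
}

#' Bow tension from the arc's end-to-end distribution
#'
#' Evaluates the entropic tension the arc exerts on the bowstring at the
#' observed mean extension, and propagates the extension spread into a force
#' uncertainty via the local slope:
#' \eqn{\sigma_f = |\partial f/\partial x|_{\bar{x}} \cdot \sigma(x)}.
#'
#' @param arc A [wlc_model()] (or precomputed `radial_distribution`) for the
#'   dsDNA arc.
#' @param stats An [extension_stats()] from simulation or experiment.
#' @param temp_c Temperature in Celsius.
#' @return List with `force` (pN, tension convention: positive pulls the
#'   string taut), `force_err` (pN), and `extension` (nm).
#' @examples
#' arc <- wlc_model(74 * 0.34, 50)
#' bow_force_estimate(arc, extension_stats(6.0, 0.5, 1000))
#' @export
bow_force_estimate <- function(arc, stats, temp_c = 22) {
  stopifnot(inherits(stats, "extension_stats"))
  dist <- if (inherits(arc, "wlc_model")) wlc_radial_pdf(arc) else arc
  stopifnot(inherits(dist, "radial_distribution"))
  ok <- is.finite(dist$log_density)
  lo <- min(dist$x[ok]); hi <- max(dist$x[ok])
  if (stats$mean - 3 * stats$sd <= lo || stats$mean + 3 * stats$sd >= hi) {
    stop("mean extension +/- 3 sd must lie inside the distribution support")
  }
  f <- entropic_force(dist, stats$mean, temp_c = temp_c)
  h <- max(1e-4, stats$sd * 1e-2)
  dfdx <- (entropic_force(dist, stats$mean + h, temp_c = temp_c) -
           entropic_force(dist, stats$mean - h, temp_c = temp_c)) / (2 * h)
  list(force = f, force_err = abs(dfdx) * stats$sd, extension = stats$mean)
}

#' Self-consistent arc-string equilibrium
#'
#' In a bow, the extension settles where the tension exerted by the bent arc
#' equals the restoring tension of the bowstring. This solves
#' \eqn{t_{arc}(x) = f_{string}(x)} for the common extension and force; it is
#' a deterministic stand-in for the mean extension that would otherwise come
#' from coarse-grained simulation of the full construct.
#'
#' @param arc A [wlc_model()] for the dsDNA arc.
#' @param string_fer A [linear_fer()] for the bowstring (its inverse gives
#'   the string tension at extension x; tension is clipped at zero below the
#'   relaxed extension), or any monotone function `x -> f` supplied directly.
#' @param temp_c Temperature in Celsius.
#' @param bracket Optional extension bracket in nm.
#' @return List with `extension` (nm) and `force` (pN).
#' @examples
#' arc <- wlc_model(74 * 0.34, 50)
#' string <- linear_fer_per_nt(30.7, 0.21, 15)   # unbound 15-nt ssDNA
#' bow_self_consistent(arc, string)              # ~6 pN
#' @export
bow_self_consistent <- function(arc, string_fer, temp_c = 22, bracket = NULL) {
  stopifnot(inherits(arc, "wlc_model"))
  f_string <- if (inherits(string_fer, "linear_fer")) {
    function(x) pmax(0, string_fer$a * (x - string_fer$b))
  } else if (is.function(string_fer)) {
    string_fer
  } else stop("string_fer must be a linear_fer or a function x -> force")
  dist <- wlc_radial_pdf(arc)
  if (is.null(bracket)) bracket <- c(arc$L * 2e-3, arc$L * 0.95)
  g <- function(x) {
    entropic_force(dist, x, temp_c = temp_c) - f_string(x)
  }
  glo <- g(bracket[1]); ghi <- g(bracket[2])
  if (!is.finite(glo) || !is.finite(ghi) || sign(glo) == sign(ghi)) {
    stop("no arc-string equilibrium found in the extension bracket")
  }
  xeq <- uniroot(g, bracket, tol = 1e-10)$root
  list(extension = xeq, force = f_string(xeq))
}
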