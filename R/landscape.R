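#' Count intact base pairs from hydrogen-bond energies
#'
#' A nucleotide pair counts as bonded when its hydrogen-bonding energy is
#' below the cutoff (default -0.1 simulation units, i.e. about 1 kBT at
#' 22 C).
#'
#' @param energies Numeric vector (one molecule) or matrix (rows =
#'   configurations) of per-pair hydrogen-bond energies.
#' @param cutoff Bond-calling threshold; energies strictly below it count.
#' @return Integer count (or vector of counts for a matrix).
#' @examples
#' hbond_count(c(-0.5, -0.05, -0.2))  # 2
#' @export
hbond_count <- function(energies, cutoff = -0.1) {
  if (is.matrix(energies)) {
    return(as.integer(rowSums(energies < cutoff)))
  }
  as.integer(sum(energies < cutoff))
}

#' Invert per-stratum umbrella weights
#'
#' Umbrella sampling applies a multiplicative bias `W(n_bp)` per base-pair
#' stratum so that rare melted states are visited. The equilibrium joint
#' probability is recovered by dividing the biased histogram by the weight
#' of its stratum and renormalizing:
#' \deqn{p_{eq}(x, n_{bp}) \propto p_{biased}(x, n_{bp}) / W(n_{bp}).}
#'
#' @param x Extensions in nm (one per sample).
#' @param n_bp Base-pair counts (integers, one per sample).
#' @param weights Named numeric of biases `W(n_bp) > 0`; names are the
#'   n_bp values. `NULL` means unbiased (identity).
#' @param bin_width Extension bin width in nm (default 0.085).
#' @param x_range Optional `c(min, max)` extension range for binning.
#' @return Object of class `peq_grid`: matrix `p` (rows = x bins, columns =
#'   n_bp strata, sums to 1), with `x_mids`, `n_bp_levels`, `counts`, and
#'   `sparse_strata` (strata observed with < 50 samples).
#' @export
umbrella_reweight <- function(x, n_bp, weights = NULL, bin_width = 0.085,
                              x_range = NULL) {
  stopifnot(length(x) == length(n_bp), length(x) >= 1)
  n_bp <- as.integer(n_bp)
  levels_bp <- sort(unique(n_bp))
  if (is.null(weights)) {
    weights <- setNames(rep(1, length(levels_bp)), levels_bp)
  }
  wn <- names(weights)
  if (is.null(wn)) stop("weights must be named by their n_bp value")
  missing_w <- setdiff(as.character(levels_bp), wn)
  if (length(missing_w)) {
    stop("observed n_bp strata without a bias weight: ",
         paste(missing_w, collapse = ", "))
  }
  if (any(weights <= 0)) stop("all umbrella weights must be positive")
  if (is.null(x_range)) x_range <- range(x)
  breaks <- seq(floor(x_range[1] / bin_width) * bin_width,
                ceiling(x_range[2] / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  xb <- cut(x, breaks, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0, nrow = length(breaks) - 1L, ncol = length(levels_bp),
                   dimnames = list(NULL, levels_bp))
  tab <- table(factor(xb, levels = seq_len(nrow(counts))),
               factor(n_bp, levels = levels_bp))
  counts[] <- as.numeric(tab)
  p <- sweep(counts, 2, weights[as.character(levels_bp)], "/")
  p <- p / sum(p)
  sparse <- levels_bp[colSums(counts) > 0 & colSums(counts) < 50]
  structure(list(p = p, x_mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 n_bp_levels = levels_bp, counts = counts,
                 bin_width = bin_width, sparse_strata = sparse),
            class = "peq_grid")
}

#' @export
print.peq_grid <- function(x, ...) {
  cat(sprintf("<peq_grid> %d x-bins (%.3g nm) x %d n_bp strata, %d samples\n",
              nrow(x$p), x$bin_width, ncol(x$p), sum(x$counts)))
  if (length(x$sparse_strata)) {
    cat("  sparse strata (< 50 samples): ",
        paste(x$sparse_strata, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Free-energy surface from equilibrium probabilities
#'
#' \eqn{G(x, n_{bp}) = -k_BT \log p_{eq}(x, n_{bp}) + C} in kBT units, with
#' the offset C chosen so the global minimum is zero. Unsampled bins are
#' `Inf` and excluded from path/minimum operations.
#'
#' @param peq A `peq_grid` from [umbrella_reweight()], or a bare probability
#'   matrix (rows = x bins, columns = n_bp strata).
#' @param x_mids,n_bp_levels Grid coordinates (taken from the `peq_grid`
#'   when available).
#' @param force Optional force label in pN, stored as metadata.
#' @return Object of class `free_energy_surface` with matrix `G` (kBT),
#'   `x_mids`, `n_bp_levels`, `force`, `offset`.
#' @export
build_surface <- function(peq, x_mids = NULL, n_bp_levels = NULL,
                          force = NA_real_) {
  if (inherits(peq, "peq_grid")) {
    x_mids <- peq$x_mids
    n_bp_levels <- peq$n_bp_levels
    p <- peq$p
  } else {
    p <- as.matrix(peq)
    if (is.null(x_mids)) x_mids <- seq_len(nrow(p))
    if (is.null(n_bp_levels)) n_bp_levels <- seq_len(ncol(p)) - 1L
  }
  stopifnot(all(p >= 0), sum(p) > 0)
  G <- ifelse(p > 0, -log(p / sum(p)), Inf)
  off <- min(G)
  structure(list(G = G - off, x_mids = x_mids, n_bp_levels = n_bp_levels,
                 force = force, offset = off),
            class = "free_energy_surface")
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf("<free_energy_surface> %d x-bins x %d n_bp strata",
              nrow(x$G), ncol(x$G)))
  if (is.finite(x$force)) cat(sprintf(" at f = %g pN", x$force))
  cat(sprintf("; max finite G = %.3g kBT\n", max(x$G[is.finite(x$G)])))
  invisible(x)
}

#' Minimum-energy path across base-pair strata
#'
#' For each n_bp column, the extension bin with the lowest free energy
#' (ties broken toward smaller extension). Connecting these points gives
#' the most probable transition pathway.
#'
#' @param surface A `free_energy_surface`.
#' @return Data frame with `n_bp`, `x` (nm, the argmin extension), and
#'   `G_kBT` along the path. Columns with no finite bin are dropped.
#' @export
min_energy_path <- function(surface) {
  stopifnot(inherits(surface, "free_energy_surface"))
  rows <- lapply(seq_along(surface$n_bp_levels), function(j) {
    col <- surface$G[, j]
    if (!any(is.finite(col))) return(NULL)
    i <- which(col == min(col))[1]   # ties -> smaller x (grid is ascending)
    data.frame(n_bp = surface$n_bp_levels[j], x = surface$x_mids[i],
               G_kBT = col[i])
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Offset each stratum so its path minimum is zero
#'
#' Subtracts the column minimum from every n_bp stratum, i.e. sets
#' `G(x_path(n_bp)) = 0` per column. Highlights the extension profile within
#' each stratum; idempotent.
#'
#' @param surface A `free_energy_surface`.
#' @return A new `free_energy_surface` with per-column minima at zero.
#' @export
path_offset <- function(surface) {
  stopifnot(inherits(surface, "free_energy_surface"))
  mins <- apply(surface$G, 2, function(col) {
    if (any(is.finite(col))) min(col[is.finite(col)]) else 0
  })
  out <- surface
  out$G <- sweep(surface$G, 2, mins, "-")
  out$offset <- NA_real_
  out
}

#' Write a surface and its path as long-form CSV
#'
#' @param surface A `free_energy_surface`.
#' @param path Output CSV path for the surface (`x_bin, n_bp, G_kBT`; only
#'   finite bins are written).
#' @param path_csv Optional output CSV for the minimum-energy path.
#' @return `path`, invisibly.
#' @export
write_surface_csv <- function(surface, path, path_csv = NULL) {
  long <- expand.grid(x_bin = surface$x_mids, n_bp = surface$n_bp_levels)
  long$G_kBT <- as.vector(surface$G)
  long <- long[is.finite(long$G_kBT), ]
  write.csv(long, path, row.names = FALSE)
  if (!is.null(path_csv)) {
    write.csv(min_energy_path(surface), path_csv, row.names = FALSE)
  }
  invisible(path)
}

#' Read landscape samples and a bias table
#'
#' Samples: CSV with columns `x_nm, n_bp` (extra columns ignored). Bias:
#' YAML mapping of n_bp value to weight, e.g. `W: {0: 1.0, 1: 2.5}`.
#'
#' @param samples_path CSV path.
#' @param bias_path Optional YAML path with top-level key `W`.
#' @return List with `x`, `n_bp`, `weights` (or `NULL`).
#' @export
read_landscape_samples <- function(samples_path, bias_path = NULL) {
  tb <- read.csv(samples_path)
  if (!all(c("x_nm", "n_bp") %in% names(tb))) {
    stop("samples file must have columns x_nm, n_bp")
  }
  weights <- NULL
  if (!is.null(bias_path)) {
    y <- yaml::read_yaml(bias_path)
    if (is.null(y$W)) stop("bias file must contain a top-level key W")
    weights <- unlist(y$W)
  }
  list(x = tb$x_nm, n_bp = as.integer(tb$n_bp), weights = weights)
}
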