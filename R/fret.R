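#' Two-color FRET intensity trace
#'
#' Background-subtracted donor/acceptor intensity time series for one
#' molecule, sampled at a fixed frame time.
#'
#' @param donor,acceptor Intensity vectors (equal length).
#' @param dt Frame time in seconds (> 0).
#' @return Object of class `fret_trace`.
#' @export
fret_trace <- function(donor, acceptor, dt) {
  stopifnot(length(donor) == length(acceptor), length(donor) >= 1,
            is.numeric(dt), dt > 0)
  structure(list(donor = as.numeric(donor), acceptor = as.numeric(acceptor),
                 dt = dt), class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace> %d frames at dt = %.4g s (%.4g s total)\n",
              length(x$donor), x$dt, length(x$donor) * x$dt))
  invisible(x)
}

#' Read a FRET trace from a delimited file
#'
#' Expects columns `time_s, donor, acceptor` (comma- or tab-separated); the
#' frame time is inferred from the time column unless given.
#'
#' @param path File path.
#' @param dt Optional frame time override (s).
#' @return A [fret_trace()].
#' @export
read_fret_trace <- function(path, dt = NULL) {
  tb <- read.csv(path, sep = if (grepl("\\.tsv$", path)) "\t" else ",")
  if (!all(c("donor", "acceptor") %in% names(tb))) {
    stop("trace file must have columns donor, acceptor (and optionally time_s)")
  }
  if (is.null(dt)) {
    if (!"time_s" %in% names(tb) || nrow(tb) < 2) {
      stop("cannot infer frame time: supply dt or a time_s column")
    }
    dt <- median(diff(tb$time_s))
  }
  fret_trace(tb$donor, tb$acceptor, dt)
}

#' FRET efficiency series
#'
#' Framewise apparent FRET efficiency \eqn{E = I_A/(I_A + I_D)}. Frames with
#' non-positive total intensity are invalid and returned as `NA` (they are
#' carried over from the previous state during state calling).
#'
#' @param trace A [fret_trace()].
#' @return Numeric vector of efficiencies in `[0, 1]` with `NA` for invalid
#'   frames.
#' @export
fret_efficiency <- function(trace) {
  stopifnot(inherits(trace, "fret_trace"))
  tot <- trace$donor + trace$acceptor
  E <- ifelse(tot > 0, trace$acceptor / tot, NA_real_)
  pmin(pmax(E, 0), 1)
}

# forward-fill NA with the previous value; leading NAs get `first`
.locf <- function(x, first) {
  idx <- which(!is.na(x))
  if (!length(idx)) return(rep(first, length(x)))
  vals <- c(first, x[idx])
  vals[findInterval(seq_along(x), idx) + 1L]
}

#' Two-state calling by smoothing and hysteresis thresholding
#'
#' Applies a centered moving average and then hysteresis thresholding: the
#' molecule enters the high-FRET (bound) state when the filtered signal
#' exceeds `high_thr` and leaves it when the signal drops below `low_thr`.
#' Frames in the hysteresis band (and invalid frames) carry the previous
#' state, which absorbs sub-frame noise excursions.
#'
#' @param E Efficiency series (from [fret_efficiency()]).
#' @param window Odd moving-average window in frames (1 = no smoothing).
#' @param low_thr,high_thr Hysteresis thresholds, `0 <= low <= high <= 1`.
#' @return Integer vector of states (0 = low FRET / unbound, 1 = high FRET
#'   / bound).
#' @export
call_states <- function(E, window = 5L, low_thr = 0.4, high_thr = 0.6) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L,
            low_thr >= 0, high_thr <= 1, low_thr <= high_thr)
  if (window >= length(E)) stop("window must be shorter than the trace")
  Es <- if (window > 1L) {
    as.numeric(stats::filter(E, rep(1 / window, window), sides = 2))
  } else E
  raw <- ifelse(is.na(Es), NA_real_,
                ifelse(Es > high_thr, 1, ifelse(Es < low_thr, 0, NA_real_)))
  first <- raw[which(!is.na(raw))[1]]
  if (is.na(first)) stop("trace never leaves the hysteresis band; cannot call states")
  as.integer(.locf(raw, first))
}

#' Dwell times from a two-state series
#'
#' Converts run lengths of the binary state series into dwell times. Under
#' the default `drop_partial` policy the first and last runs are censored
#' (their start/end was not observed) and excluded.
#'
#' @param states Binary state vector (0/1), e.g. from [call_states()].
#' @param dt Frame time in seconds.
#' @param edge_policy `"drop_partial"` (default) excludes the first and last
#'   runs from the dwell lists; `"keep"` treats them as ordinary dwells.
#'   The edge runs are always recorded separately in `edges` (with a flag
#'   for whether their exit was observed: the leading run ends in an
#'   observed transition, the trailing run is right-censored) so that
#'   censoring-aware rate estimators can use them.
#' @return Object of class `dwell_set`: list with `on` and `off` dwell
#'   vectors (s), an `edges` data frame (`state`, `duration`,
#'   `exit_observed`), `dropped` (total edge time under `drop_partial`, s),
#'   `dt`, and `edge_policy`.
#' @examples
#' dwell_times(c(0, 1, 1, 0, 1, 0), dt = 0.5)
#' @export
dwell_times <- function(states, dt,
                        edge_policy = c("drop_partial", "keep")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(all(states %in% c(0L, 1L)), dt > 0)
  r <- rle(as.integer(states))
  durs <- r$lengths * dt
  vals <- r$values
  nr <- length(durs)
  edge <- unique(c(1L, nr))
  edges <- data.frame(state = vals[edge], duration = durs[edge],
                      exit_observed = edge < nr)
  dropped <- 0
  if (edge_policy == "drop_partial") {
    dropped <- sum(durs[edge])
    keep <- setdiff(seq_len(nr), edge)
    durs <- durs[keep]
    vals <- vals[keep]
  }
  structure(list(on = durs[vals == 1L], off = durs[vals == 0L],
                 edges = edges, dropped = dropped, dt = dt,
                 edge_policy = edge_policy),
            class = "dwell_set")
}

#' @export
print.dwell_set <- function(x, ...) {
  cat(sprintf("<dwell_set> %d on-dwells (mean %.3g s), %d off-dwells (mean %.3g s)\n",
              length(x$on), mean(x$on), length(x$off), mean(x$off)))
  invisible(x)
}

#' Pool dwell sets across molecules
#'
#' Dwells from all trajectories of one condition are pooled before rates are
#' computed, matching the per-condition aggregation of the assay.
#'
#' @param dwell_list List of [dwell_times()] results.
#' @return A single `dwell_set`.
#' @export
pool_dwells <- function(dwell_list) {
  pull <- function(fld) unlist(lapply(dwell_list, `[[`, fld), use.names = FALSE)
  dts <- vapply(dwell_list, `[[`, numeric(1), "dt")
  if (max(dts) - min(dts) > 1e-12) {
    stop("cannot pool dwell sets with different frame times")
  }
  structure(list(
    on = pull("on"), off = pull("off"),
    edges = do.call(rbind, lapply(dwell_list, `[[`, "edges")),
    dropped = sum(vapply(dwell_list, `[[`, numeric(1), "dropped")),
    dt = dts[1],
    edge_policy = dwell_list[[1]]$edge_policy
  ), class = "dwell_set")
}

#' Rate constants from dwell times
#'
#' The default estimator uses the mean dwell times,
#' \eqn{k_{on} = 1/([c]\,\bar\tau_{off})} and
#' \eqn{k_{off} = 1/\bar\tau_{on}}, where `[c]` is the probe concentration.
#' When observation windows are not much longer than the slower dwell time,
#' conditioning on dwell completeness biases the means short. The
#' `"censored_mle"` estimator instead divides the number of observed exits
#' from a state (interior dwells plus the leading edge run, whose residual
#' lifetime is exponential by memorylessness) by the total observed time in
#' that state, including the right-censored trailing run, and applies the
#' sampled-chain correction \eqn{-\log(1 - x)/x} (with x the summed
#' per-frame transition probabilities) that removes the frame-discretization
#' bias. It requires the default `drop_partial` edge policy.
#'
#' Two standard errors are computed: the analytic exponential SEM
#' (`rate / sqrt(N)`) and a seeded bootstrap over dwells (reported by
#' default in the `kon_sem` / `koff_sem` fields).
#'
#' @param dwells A `dwell_set`.
#' @param conc Probe concentration in mol/L (> 0).
#' @param estimator `"mean_dwell"` (default) or `"censored_mle"`.
#' @param min_dwells Minimum complete dwells required per class.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return List of class `rate_measurement`: `kon`, `kon_sem`, `koff`,
#'   `koff_sem` (bootstrap), `kon_sem_analytic`, `koff_sem_analytic`,
#'   `n_on`, `n_off`, `conc`, `estimator`.
#' @export
rates_from_dwells <- function(dwells, conc,
                              estimator = c("mean_dwell", "censored_mle"),
                              min_dwells = 5L, n_boot = 1000L, seed = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(dwells, "dwell_set"), conc > 0)
  if (length(dwells$on) < min_dwells || length(dwells$off) < min_dwells) {
    stop(sprintf("insufficient dwells (need >= %d per class; have %d on, %d off)",
                 min_dwells, length(dwells$on), length(dwells$off)))
  }
  if (!is.null(seed)) set.seed(seed)

  if (estimator == "mean_dwell") {
    kon <- 1 / (conc * mean(dwells$off))
    koff <- 1 / mean(dwells$on)
    boot <- function(tau, fn) {
      n <- length(tau)
      sd(vapply(seq_len(n_boot), function(i) {
        fn(mean(tau[sample.int(n, n, replace = TRUE)]))
      }, numeric(1)))
    }
    kon_sem <- boot(dwells$off, function(m) 1 / (conc * m))
    koff_sem <- boot(dwells$on, function(m) 1 / m)
  } else {
    if (!identical(dwells$edge_policy, "drop_partial")) {
      stop("censored_mle requires edge_policy = 'drop_partial' dwell sets")
    }
    eg <- dwells$edges
    rate_pair <- function(on, off, e_on, e_off) {
      ex_on <- length(on) + sum(e_on$exit_observed)
      ex_off <- length(off) + sum(e_off$exit_observed)
      t_on <- sum(on) + sum(e_on$duration)
      t_off <- sum(off) + sum(e_off$duration)
      # per-frame transition probabilities and the exact CTMC inversion
      x <- dwells$dt * (ex_on / t_on + ex_off / t_off)
      corr <- if (x > 0 && x < 1) -log(1 - x) / x else 1
      c(koff = corr * ex_on / t_on, kon_c = corr * ex_off / t_off)
    }
    e_on <- eg[eg$state == 1L, ]
    e_off <- eg[eg$state == 0L, ]
    rp <- rate_pair(dwells$on, dwells$off, e_on, e_off)
    koff <- rp[["koff"]]
    kon <- rp[["kon_c"]] / conc
    n_on <- length(dwells$on); n_off <- length(dwells$off)
    reps <- vapply(seq_len(n_boot), function(i) {
      rate_pair(dwells$on[sample.int(n_on, n_on, replace = TRUE)],
                dwells$off[sample.int(n_off, n_off, replace = TRUE)],
                e_on[sample.int(nrow(e_on), nrow(e_on), replace = TRUE), ],
                e_off[sample.int(nrow(e_off), nrow(e_off), replace = TRUE), ])
    }, numeric(2))
    koff_sem <- sd(reps["koff", ])
    kon_sem <- sd(reps["kon_c", ]) / conc
  }
  structure(list(
    kon = kon, koff = koff, kon_sem = kon_sem, koff_sem = koff_sem,
    kon_sem_analytic = kon / sqrt(length(dwells$off)),
    koff_sem_analytic = koff / sqrt(length(dwells$on)),
    n_on = length(dwells$on), n_off = length(dwells$off), conc = conc,
    estimator = estimator
  ), class = "rate_measurement")
}

#' @export
print.rate_measurement <- function(x, ...) {
  cat(sprintf("<rate_measurement> kon = %.4g +/- %.2g 1/(M s), koff = %.4g +/- %.2g 1/s\n",
              x$kon, x$kon_sem, x$koff, x$koff_sem))
  invisible(x)
}

#' Write or read a per-condition rates table
#'
#' Interchange schema: CSV with columns `sequence, force_pN, force_err,
#' kon, kon_sem, koff, koff_sem, n_molecules`. The reader also returns the
#' columns `force`, `kon`, `koff` (etc.) expected by [fit_rate_model()].
#'
#' @param measurements List of [rates_from_dwells()] results.
#' @param sequence,force,force_err Per-condition metadata vectors (recycled).
#' @param path CSV path.
#' @return The written data frame (`write_rates_csv`, invisibly) or the
#'   table read back (`read_rates_csv`).
#' @export
write_rates_csv <- function(measurements, sequence, force, force_err, path) {
  if (inherits(measurements, "rate_measurement")) measurements <- list(measurements)
  n <- length(measurements)
  tab <- data.frame(
    sequence = rep_len(sequence, n),
    force_pN = rep_len(force, n),
    force_err = rep_len(force_err, n),
    kon = vapply(measurements, `[[`, numeric(1), "kon"),
    kon_sem = vapply(measurements, `[[`, numeric(1), "kon_sem"),
    koff = vapply(measurements, `[[`, numeric(1), "koff"),
    koff_sem = vapply(measurements, `[[`, numeric(1), "koff_sem"),
    n_molecules = vapply(measurements, function(m) {
      nm <- attr(m, "n_molecules")
      if (is.null(nm)) NA_integer_ else as.integer(nm)
    }, integer(1))
  )
  write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_rates_csv
#' @export
read_rates_csv <- function(path) {
  tab <- read.csv(path)
  need <- c("force_pN", "kon", "koff")
  if (!all(need %in% names(tab))) {
    stop("rates table must have columns: ", paste(need, collapse = ", "))
  }
  tab$force <- tab$force_pN
  tab
}

#' Automatic hysteresis thresholds from the efficiency histogram
#'
#' Places the hysteresis band at the midpoint between the two dominant modes
#' of the pooled efficiency density, +/- `half_band`.
#'
#' @param E Pooled efficiency values (NA ignored).
#' @param half_band Half-width of the hysteresis band.
#' @return Named numeric `c(low, high)`.
#' @export
auto_thresholds <- function(E, half_band = 0.1) {
  E <- E[is.finite(E)]
  d <- density(E, from = 0, to = 1, n = 512)
  y <- d$y
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(loc) < 2) {
    mid <- 0.5
  } else {
    top <- loc[order(y[loc], decreasing = TRUE)][1:2]
    mid <- mean(d$x[top])
  }
  c(low = max(0, mid - half_band), high = min(1, mid + half_band))
}

#' Full per-condition trace analysis
#'
#' Runs the efficiency/state/dwell pipeline over all trajectories of one
#' condition, pools dwells, and returns the rate measurement.
#'
#' @param traces List of [fret_trace()] objects (one per molecule).
#' @param conc Probe concentration in mol/L.
#' @param window Moving-average window (frames).
#' @param thresholds Optional `c(low, high)`; computed by
#'   [auto_thresholds()] from the pooled efficiencies when `NULL`.
#' @param seed Seed for the bootstrap SEM.
#' @param ... Passed to [rates_from_dwells()].
#' @return A `rate_measurement` with the pooled `dwells` and the thresholds
#'   used attached as attributes.
#' @export
analyze_traces <- function(traces, conc, window = 5L, thresholds = NULL,
                           seed = NULL, ...) {
  effs <- lapply(traces, fret_efficiency)
  if (is.null(thresholds)) thresholds <- auto_thresholds(unlist(effs))
  dls <- lapply(seq_along(traces), function(i) {
    st <- call_states(effs[[i]], window = window,
                      low_thr = thresholds[[1]], high_thr = thresholds[[2]])
    dwell_times(st, traces[[i]]$dt)
  })
  pooled <- pool_dwells(dls)
  out <- rates_from_dwells(pooled, conc, seed = seed, ...)
  attr(out, "dwells") <- pooled
  attr(out, "thresholds") <- thresholds
  attr(out, "n_molecules") <- length(traces)
  out
}
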