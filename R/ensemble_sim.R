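# Ensemble simulation: mass-action trajectories from lognormal initial
# conditions, emitted as single-cell-like snapshots.

#' Construct an ensemble snapshot
#'
#' The unit of all inference: a cells x channels matrix of concentrations or
#' signals at one timepoint. Linear-space values must be strictly positive;
#' log-space values must be finite.
#'
#' @param values numeric matrix, cells in rows, channels in columns (column
#'   names become channel names).
#' @param channel_names optional channel names (default: column names).
#' @param time timepoint of the snapshot (NA if not applicable).
#' @param log_space TRUE if `values` are already log-transformed.
#' @return an object of class `"ensemble_snapshot"`.
#' @export
ensemble_snapshot <- function(values, channel_names = colnames(values),
                              time = NA_real_, log_space = FALSE) {
  values <- as.matrix(values)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(ncol(values)))
  if (length(channel_names) != ncol(values))
    stop("channel_names length must match column count", call. = FALSE)
  if (anyDuplicated(channel_names))
    stop("duplicate channel names", call. = FALSE)
  if (!log_space && any(values <= 0))
    stop("linear-space snapshot values must be strictly positive (",
         sum(values <= 0), " offending entries)", call. = FALSE)
  if (log_space && !all(is.finite(values)))
    stop("log-space snapshot values must be finite", call. = FALSE)
  colnames(values) <- channel_names
  structure(list(values = values, channel_names = channel_names,
                 time = time, log_space = log_space),
            class = "ensemble_snapshot")
}

#' @export
print.ensemble_snapshot <- function(x, ...) {
  cat(sprintf("ensemble_snapshot: %d cells x %d channels (%s space, t = %s)\n",
              nrow(x$values), ncol(x$values),
              if (x$log_space) "log" else "linear", format(x$time)))
  invisible(x)
}

#' Log-transform a snapshot
#'
#' Natural-log transform of a linear-space snapshot. Values are clipped at
#' `1e-300` before the log to avoid `-Inf`; clipped cells trigger a warning.
#'
#' @param snapshot an [ensemble_snapshot()].
#' @return a log-space [ensemble_snapshot()].
#' @export
snapshot_log <- function(snapshot) {
  stopifnot(inherits(snapshot, "ensemble_snapshot"))
  if (snapshot$log_space) return(snapshot)
  v <- snapshot$values
  n_clip <- sum(v < 1e-300)
  if (n_clip > 0) {
    warning(n_clip, " values clipped at 1e-300 before log transform")
    v[v < 1e-300] <- 1e-300
  }
  ensemble_snapshot(log(v), snapshot$channel_names, snapshot$time,
                    log_space = TRUE)
}

#' Subset a snapshot to selected channels
#'
#' Marginalizes the ensemble to an observed subset of species, preserving
#' channel order as given.
#'
#' @param snapshot an [ensemble_snapshot()].
#' @param channels character vector of channel names (or integer indices).
#' @return an [ensemble_snapshot()].
#' @export
snapshot_channels <- function(snapshot, channels) {
  stopifnot(inherits(snapshot, "ensemble_snapshot"))
  if (is.character(channels)) {
    bad <- setdiff(channels, snapshot$channel_names)
    if (length(bad))
      stop("unknown channel(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  v <- snapshot$values[, channels, drop = FALSE]
  ensemble_snapshot(v, colnames(v), snapshot$time, snapshot$log_space)
}

#' Sample lognormal initial conditions
#'
#' Draws i.i.d. lognormal concentrations per species per cell in the
#' natural-log parameterization: `log(c) ~ Normal(log_mean, log_variance)`.
#' Defaults match the complex-balanced simulation conditions (log-mean 4,
#' log-variance 4); gene-regulatory ensembles use log-mean 5, log-variance 8.
#'
#' @param network a [reaction_network()] (channels = its species), or a
#'   character vector of channel names.
#' @param n_cells number of cells (>= 2). Default 300.
#' @param log_mean,log_variance lognormal parameters (natural log).
#' @param seed optional integer seed.
#' @return an [ensemble_snapshot()] at `time = 0`.
#' @export
sample_initial_conditions <- function(network, n_cells = 300, log_mean = 4,
                                      log_variance = 4, seed = NULL) {
  channels <- if (inherits(network, "reaction_network")) network$species
              else as.character(network)
  stopifnot(n_cells >= 2, log_variance >= 0)
  with_seed(seed, {
    v <- matrix(rlnorm_lv(n_cells * length(channels), log_mean, log_variance),
                nrow = n_cells, ncol = length(channels))
    colnames(v) <- channels
    ensemble_snapshot(v, channels, time = 0, log_space = FALSE)
  })
}

#' Integrate an ensemble of mass-action trajectories
#'
#' Solves the mass-action ODE system for every cell of the initial snapshot
#' with a stiff-capable integrator (lsoda), returning one snapshot per
#' requested timepoint. Cells whose integration fails (or produces
#' non-finite or substantially negative values) are dropped from every
#' snapshot with a warning; diagnostics record which.
#'
#' @param network a [reaction_network()].
#' @param initial an [ensemble_snapshot()] in linear space whose channels are
#'   the network species (in order).
#' @param times strictly increasing positive timepoints.
#' @param rtol,atol integrator relative/absolute tolerances.
#' @return list of class `"simulation_result"`: `snapshots` (list of
#'   [ensemble_snapshot()], one per timepoint), `times`, `dropped` (indices
#'   of excluded cells), `n_cells`.
#' @export
integrate_ensemble <- function(network, initial, times, rtol = 1e-8,
                               atol = 1e-10) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(initial, "ensemble_snapshot"), !initial$log_space)
  if (!identical(initial$channel_names, network$species))
    stop("snapshot channels must equal network species, in order",
         call. = FALSE)
  times <- sort(unique(as.numeric(times)))
  if (any(times <= 0)) stop("timepoints must be positive", call. = FALSE)
  rhs <- mass_action_rhs(network)
  f_ode <- function(t, y, parms) list(rhs(pmax(y, 0)))
  n_cells <- nrow(initial$values)
  n_sp <- length(network$species)
  t_all <- c(0, times)
  out <- array(NA_real_, dim = c(length(times), n_cells, n_sp))
  ok <- rep(TRUE, n_cells)
  for (i in seq_len(n_cells)) {
    sol <- try(suppressWarnings(
      deSolve::ode(y = initial$values[i, ], times = t_all, func = f_ode,
                   parms = NULL, method = "lsoda", rtol = rtol, atol = atol,
                   maxsteps = 100000)), silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(t_all) ||
        anyNA(sol) || attr(sol, "istate")[1] < 0) {
      ok[i] <- FALSE
      next
    }
    y <- unname(sol[-1, -1, drop = FALSE])
    scale <- max(abs(initial$values[i, ]), 1)
    if (any(!is.finite(y)) || any(y < -1e-6 * scale)) {
      ok[i] <- FALSE
      next
    }
    out[, i, ] <- pmax(y, 1e-300)
  }
  if (!any(ok)) stop("integration failed for every cell", call. = FALSE)
  if (any(!ok))
    warning(sum(!ok), " cell(s) dropped after integration failure: ",
            paste(utils::head(which(!ok), 10), collapse = ", "))
  snaps <- lapply(seq_along(times), function(j) {
    v <- out[j, ok, , drop = TRUE]
    v <- matrix(v, nrow = sum(ok), ncol = n_sp)
    colnames(v) <- network$species
    ensemble_snapshot(v, network$species, time = times[j], log_space = FALSE)
  })
  structure(list(snapshots = snaps, times = times, dropped = which(!ok),
                 n_cells = sum(ok)),
            class = "simulation_result")
}

#' Integrate until the covariance spectrum stops contracting
#'
#' Runs the ensemble over a doubling time schedule and monitors the largest
#' eigenvalue below the detected spectral gap (falling back to the smallest
#' eigenvalue when no gap has opened yet). Integration stops when that
#' eigenvalue decreases by less than `rel_tol` per doubling of `t`, or at
#' `max_time`.
#'
#' @param network a [reaction_network()].
#' @param initial an [ensemble_snapshot()] at `t = 0`.
#' @param t_start first timepoint of the doubling schedule.
#' @param max_time hard cap on the final time. Default 1e4.
#' @param rel_tol relative per-doubling decrease regarded as converged.
#' @param ... passed to [integrate_ensemble()].
#' @return the final [ensemble_snapshot()], with attribute `"time"` equal to
#'   the stopping time.
#' @export
converge_ensemble <- function(network, initial, t_start = 1, max_time = 1e4,
                              rel_tol = 0.01, ...) {
  times <- t_start * 2^(0:ceiling(log2(max_time / t_start)))
  times <- times[times <= max_time]
  if (length(times) == 0L || max(times) < max_time)
    times <- c(times, max_time)
  res <- integrate_ensemble(network, initial, times, ...)
  lam_prev <- NA_real_
  for (j in seq_along(res$snapshots)) {
    sp <- fit_covariance_spectrum(res$snapshots[[j]])
    gr <- detect_gaps(sp)
    lam <- if (is.na(gr$chosen)) sp$values[1] else sp$values[gr$chosen]
    if (!is.na(lam_prev) && lam_prev > 0 &&
        (lam_prev - lam) / lam_prev < rel_tol)
      return(res$snapshots[[j]])
    lam_prev <- lam
  }
  res$snapshots[[length(res$snapshots)]]
}

#' Apply per-channel linear gains
#'
#' Models the linear-fluorescence assumption `I_i = k_i * c_i`: a fixed
#' positive gain per channel. In log space this is an additive shift only,
#' so the log-covariance (and hence any effective stoichiometric space
#' derived from it) is unchanged.
#'
#' @param snapshot an [ensemble_snapshot()].
#' @param gains positive numeric vector, one gain per channel (recycled if
#'   scalar).
#' @return an [ensemble_snapshot()] of signals.
#' @export
apply_gains <- function(snapshot, gains) {
  stopifnot(inherits(snapshot, "ensemble_snapshot"))
  gains <- rep_len(as.numeric(gains), ncol(snapshot$values))
  if (any(!is.finite(gains)) || any(gains <= 0))
    stop("gains must be positive and finite", call. = FALSE)
  if (snapshot$log_space) {
    v <- sweep(snapshot$values, 2L, log(gains), `+`)
  } else {
    v <- sweep(snapshot$values, 2L, gains, `*`)
  }
  ensemble_snapshot(v, snapshot$channel_names, snapshot$time,
                    snapshot$log_space)
}
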