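# Null model for row-reduced entry distributions and bootstrap confidence
# intervals for net-reaction vector entries.

#' Null distribution of row-reduced vector entries
#'
#' Monte-Carlo null for the entry distribution under random sparse
#' constraints: for each of `n_sets` sets, `s` vectors with entries uniform
#' on (-0.5, 0.5) are drawn, each entry is independently zeroed with
#' probability `sparsity`, and the set is row-reduced with complete
#' pivoting. The pivot columns -- whose 0s and 1s row reduction necessarily
#' produces -- are discarded; every remaining entry (including the zeros
#' inherited from sparsification, which are the null's analog of the data's
#' near-zero peak) is pooled, and Gaussian noise with variance
#' `noise_variance` is added. Sets that lose rank after sparsification are
#' redrawn (and counted). The pooled entries are kernel-smoothed exactly as
#' in [entry_distribution()].
#'
#' @param s number of constraint vectors per set.
#' @param dim ambient dimension (number of channels); must exceed `s`.
#' @param sparsity per-entry zeroing probability in [0, 1].
#' @param noise_variance variance of the Gaussian noise added to pooled
#'   entries.
#' @param n_sets number of Monte-Carlo sets. Default 1000.
#' @param bandwidth kernel bandwidth for the smoothed density.
#' @param seed optional integer seed.
#' @param max_redraws cap on rank-collapse redraws across all sets.
#' @return an `"entry_distribution"` (see [entry_distribution()]) with extra
#'   fields `n_sets` and `n_redraws`.
#' @export
null_entry_distribution <- function(s, dim, sparsity, noise_variance = 0,
                                    n_sets = 1000, bandwidth = 0.04,
                                    seed = NULL, max_redraws = 100 * n_sets) {
  stopifnot(s >= 1, dim > s, sparsity >= 0, sparsity <= 1,
            noise_variance >= 0, n_sets >= 1)
  with_seed(seed, {
    pooled <- vector("list", n_sets)
    redraws <- 0L
    for (i in seq_len(n_sets)) {
      repeat {
        M <- matrix(stats::runif(s * dim, -0.5, 0.5), s, dim)
        M[matrix(stats::runif(s * dim) < sparsity, s, dim)] <- 0
        rr <- try(row_reduce_complete_pivoting(t(M)), silent = TRUE)
        if (!inherits(rr, "try-error")) break
        redraws <- redraws + 1L
        if (sparsity >= 1) {          # all-zero sets can never gain rank
          rr <- NULL
          break
        }
        if (redraws > max_redraws)
          stop("rank-collapse redraw budget exhausted", call. = FALSE)
      }
      if (is.null(rr)) {
        pooled[[i]] <- numeric(0)
        next
      }
      e <- as.vector(rr$vectors[, -rr$pivots, drop = FALSE])
      if (length(e) && noise_variance > 0)
        e <- e + stats::rnorm(length(e), 0, sqrt(noise_variance))
      pooled[[i]] <- e
    }
    if (redraws > 0)
      message(redraws, " set(s) redrawn after rank collapse")
    entries <- unlist(pooled)
    out <- if (length(entries) == 0L) {
      structure(list(entries = numeric(0), density = NULL,
                     fraction_window = NA_real_, n_entries = 0L,
                     bandwidth = bandwidth),
                class = "entry_distribution")
    } else {
      dens <- stats::density(entries, bw = bandwidth, kernel = "gaussian",
                             from = -1.5, to = 1.5, n = 601L)
      structure(list(entries = entries,
                     density = data.frame(x = dens$x, y = dens$y),
                     fraction_window = mean(entries > -0.2 & entries < 0.2),
                     n_entries = length(entries), bandwidth = bandwidth),
                class = "entry_distribution")
    }
    out$n_sets <- n_sets
    out$n_redraws <- redraws
    out
  })
}

#' Calibrate the null model from observed entries
#'
#' Matches the null to the data the way its smoothed density is compared:
#' the zeroing probability is set to the fraction of observed entries in the
#' near-zero window (-0.2, 0.2), and the noise variance to the sample
#' variance of the entries inside that window.
#'
#' @param entries numeric vector of pooled row-reduced entries (e.g.
#'   `entry_distribution(...)$entries`).
#' @param s number of constraint vectors of the data run.
#' @param dim ambient dimension (channel count) of the data run.
#' @param window near-zero window.
#' @return list with `s`, `dim`, `sparsity`, `noise_variance`, `window`.
#' @export
calibrate_null_from_data <- function(entries, s, dim,
                                     window = c(-0.2, 0.2)) {
  if (length(entries) == 0L) stop("empty entry list", call. = FALSE)
  inside <- entries[entries > window[1] & entries < window[2]]
  sparsity <- length(inside) / length(entries)
  noise_variance <- if (length(inside) >= 2L) stats::var(inside) else 0
  if (length(inside) < 2L)
    warning("fewer than 2 entries inside the calibration window; ",
            "noise variance set to 0")
  list(s = s, dim = dim, sparsity = sparsity,
       noise_variance = noise_variance, window = window)
}

# Rotate basis B (channels x s) within its own span to best align with B0.
align_basis <- function(B, B0) {
  sv <- svd(crossprod(B, B0))
  B %*% tcrossprod(sv$u, sv$v)
}

#' Bootstrap confidence intervals for row-reduced vector entries
#'
#' Percentile bootstrap over cells: each replicate resamples cells with
#' replacement, refits the GMM with the original number of components (when
#' `k > 1`), keeps the dominant component, recomputes the log-covariance
#' spectrum, extracts the ESS at the original dimension, rotates the
#' replicate basis within its span to best align with the original (so
#' arbitrary eigenvector sign/rotation cannot flip entries), and replays the
#' original row reduction's row/column rearrangements instead of re-running
#' complete pivoting. Entrywise 2.5/97.5 percentiles bound each entry.
#'
#' @param snapshot the original [ensemble_snapshot()].
#' @param record the original run's `"row_reduced_basis"` (pivot bookkeeping
#'   to replay).
#' @param k GMM component count of the original run; `k = 1` (or `NULL`)
#'   skips mixture gating.
#' @param n_replicates number of bootstrap replicates. Default 1000.
#' @param level confidence level. Default 0.95.
#' @param seed optional integer seed.
#' @param gmm_n_init EM restarts per replicate (fewer than the original fit
#'   keeps the bootstrap affordable; the original fit's optimum seeds no
#'   part of the replicate fits).
#' @return object of class `"bootstrap_ci"`: `lower`, `upper`, `point` (s x
#'   channels matrices), `n_ok`, `n_dropped`, `level`.
#' @export
bootstrap_row_reduced_cis <- function(snapshot, record, k = 1,
                                      n_replicates = 1000, level = 0.95,
                                      seed = NULL, gmm_n_init = 5) {
  stopifnot(inherits(snapshot, "ensemble_snapshot"),
            inherits(record, "row_reduced_basis"))
  if (is.null(k)) k <- 1L
  s <- nrow(record$vectors)
  d <- ncol(record$vectors)
  n <- nrow(snapshot$values)
  # original basis on the full pipeline, for alignment
  orig_basis <- orthonormal_span(t(record$vectors))
  with_seed(seed, {
    draws <- array(NA_real_, dim = c(n_replicates, s, d))
    dropped <- 0L
    for (r in seq_len(n_replicates)) {
      idx <- sample.int(n, n, replace = TRUE)
      snap_r <- ensemble_snapshot(snapshot$values[idx, , drop = FALSE],
                                  snapshot$channel_names, snapshot$time,
                                  snapshot$log_space)
      rr <- try({
        if (k > 1L) {
          fit <- fit_gmm(snap_r, k, n_init = gmm_n_init)
          snap_r <- select_subpopulation(fit, snap_r)
        }
        spec <- fit_covariance_spectrum(snap_r)
        ess <- extract_ess(spec, dimension = s)
        aligned <- align_basis(ess$basis, orig_basis)
        replay_row_reduction(aligned, record)
      }, silent = TRUE)
      if (inherits(rr, "try-error")) {
        dropped <- dropped + 1L
        next
      }
      draws[r, , ] <- rr$vectors
    }
    n_ok <- n_replicates - dropped
    if (n_ok == 0L) stop("every bootstrap replicate failed", call. = FALSE)
    if (dropped / n_replicates > 0.05)
      warning(dropped, " of ", n_replicates,
              " bootstrap replicates dropped (> 5%)")
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    lower <- apply(draws, c(2, 3), stats::quantile, probs = probs[1],
                   na.rm = TRUE)
    upper <- apply(draws, c(2, 3), stats::quantile, probs = probs[2],
                   na.rm = TRUE)
    dimnames(lower) <- dimnames(upper) <- dimnames(record$vectors)
    structure(list(lower = lower, upper = upper, point = record$vectors,
                   n_ok = n_ok, n_dropped = dropped, level = level),
              class = "bootstrap_ci")
  })
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("bootstrap_ci: %g%% intervals from %d replicate(s) (%d dropped)\n",
              100 * x$level, x$n_ok, x$n_dropped))
  invisible(x)
}
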