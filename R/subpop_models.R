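# Subpopulation identification: Gaussian mixtures in log-signal space fit by
# EM (mclust E/M steps inside our own loop, so the likelihood trace is
# exposed), k-means++ restarts, dominant-component gating, and an LDA-style
# separation statistic between dominant components.

# k-means++ seeding: first center uniform, then each next center sampled
# with probability proportional to squared distance from the nearest center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j, ] <- x[sample.int(n, 1L, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
    }
  }
  centers
}

hard_assign_z <- function(x, centers) {
  k <- nrow(centers)
  d2 <- vapply(seq_len(k),
               function(j) rowSums(sweep(x, 2L, centers[j, ])^2),
               numeric(nrow(x)))
  cl <- max.col(-d2, ties.method = "first")
  z <- matrix(0, nrow(x), k)
  z[cbind(seq_len(nrow(x)), cl)] <- 1
  # every component needs support for the M step
  for (j in seq_len(k)) if (sum(z[, j]) < 2) z[, j] <- z[, j] + 1e-3
  z / rowSums(z)
}

jitter_parameters <- function(parameters, x) {
  jit <- 1e-6 * apply(x, 2L, stats::var)
  sig <- parameters$variance$sigma
  for (j in seq_len(dim(sig)[3]))
    sig[, , j] <- sig[, , j] + diag(jit, ncol(x))
  parameters$variance$sigma <- sig
  if (!is.null(parameters$variance$cholsigma))
    parameters$variance$cholsigma <- array(
      apply(sig, 3L, chol), dim = dim(sig))
  parameters
}

# One EM run from an initial responsibility matrix. Returns NULL when the
# run degenerates beyond repair.
em_run <- function(x, z, max_iter, tol) {
  trace <- numeric(0)
  ll_prev <- -Inf
  es <- NULL
  for (it in seq_len(max_iter)) {
    ms <- try(mclust::mstepVVV(data = x, z = z), silent = TRUE)
    if (inherits(ms, "try-error") || anyNA(ms$parameters$mean)) return(NULL)
    es <- try(mclust::estepVVV(data = x, parameters = ms$parameters),
              silent = TRUE)
    if (inherits(es, "try-error") || is.na(es$loglik)) {
      warning("singular covariance during EM; applying diagonal ",
              "regularization", call. = FALSE)
      ms$parameters <- jitter_parameters(ms$parameters, x)
      es <- try(mclust::estepVVV(data = x, parameters = ms$parameters),
                silent = TRUE)
      if (inherits(es, "try-error") || is.na(es$loglik)) return(NULL)
    }
    trace <- c(trace, es$loglik)
    if (is.finite(ll_prev) &&
        abs(es$loglik - ll_prev) < tol * abs(ll_prev)) break
    ll_prev <- es$loglik
    z <- es$z
  }
  list(loglik = es$loglik, trace = trace, z = es$z,
       parameters = es$parameters)
}

#' Fit a Gaussian mixture model in log-signal space
#'
#' Full-covariance GMM fit by expectation-maximization, restarted from at
#' least `20 * k` k-means++ initializations and keeping the
#' highest-likelihood run. EM iterates until the relative log-likelihood
#' change drops below `tol`. The highest-weight component is flagged as
#' *dominant*.
#'
#' @param snapshot an [ensemble_snapshot()]; linear-space snapshots are
#'   log-transformed first.
#' @param k number of mixture components.
#' @param n_init number of EM restarts (default `20 * k`).
#' @param max_iter EM iteration cap per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @param seed optional integer seed.
#' @return object of class `"gmm_fit"`: `k`, `weights`, `means` (channels x
#'   k), `covariances` (channels x channels x k), `z` (cells x k
#'   responsibilities), `loglik`, `loglik_trace` (best run), `dominant`
#'   (index of the largest-weight component), `channel_names`, `n_cells`.
#' @export
fit_gmm <- function(snapshot, k, n_init = 20 * k, max_iter = 500,
                    tol = 1e-8, seed = NULL) {
  stopifnot(inherits(snapshot, "ensemble_snapshot"), k >= 1)
  x <- snapshot_log(snapshot)$values
  if (nrow(x) <= k * ncol(x))
    stop("too few cells (", nrow(x), ") for a ", k, "-component ",
         ncol(x), "-channel mixture", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(max(1L, n_init))) {
      z0 <- hard_assign_z(x, kmeanspp_centers(x, k))
      run <- suppressWarnings(em_run(x, z0, max_iter, tol))
      if (is.null(run)) next
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
    if (is.null(best))
      stop("all EM initializations degenerated", call. = FALSE)
    p <- best$parameters
    weights <- if (k == 1L) 1 else p$pro
    structure(list(k = as.integer(k), weights = weights,
                   means = matrix(p$mean, ncol(x), k),
                   covariances = array(p$variance$sigma,
                                       dim = c(ncol(x), ncol(x), k)),
                   z = matrix(best$z, nrow(x), k),
                   loglik = best$loglik, loglik_trace = best$trace,
                   dominant = which.max(weights),
                   channel_names = colnames(x), n_cells = nrow(x)),
              class = "gmm_fit")
  })
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("gmm_fit: k = %d, loglik = %.3f, weights = %s (dominant: %d)\n",
              x$k, x$loglik,
              paste(signif(x$weights, 3), collapse = ", "), x$dominant))
  invisible(x)
}

#' Choose the number of mixture components
#'
#' Fits GMMs for `k = 1 .. k_max` and returns the smallest `k` at which the
#' incremental likelihood gain `LL(k+1) - LL(k)` either drops abruptly
#' (below a fraction `alpha` of the previous gain) or is no real gain at
#' all. Because maximum likelihood always increases a little with an extra
#' component, "no real gain" means a gain below twice the number of
#' parameters one extra full-covariance component adds
#' (`2 * (d + d(d+1)/2 + 1)` for `d` channels): four times the chi-square
#' mean, leaving headroom for the best-of-many-restarts selection to inflate
#' pure-overfitting gains. Returns 1 for data a single Gaussian already
#' explains, and `k_max` when the gains never flatten.
#'
#' @param snapshot an [ensemble_snapshot()].
#' @param k_max largest component count considered.
#' @param alpha gain-drop fraction.
#' @param seed optional integer seed.
#' @param ... passed to [fit_gmm()].
#' @return integer; attribute `"logliks"` carries the fitted log-likelihoods.
#' @export
choose_k <- function(snapshot, k_max, alpha = 0.2, seed = NULL, ...) {
  stopifnot(k_max >= 1)
  if (k_max == 1L) return(1L)
  ll <- vapply(seq_len(k_max),
               function(k) fit_gmm(snapshot, k, seed = seed, ...)$loglik,
               numeric(1))
  gains <- diff(ll)
  d <- length(snapshot$channel_names)
  floor_gain <- 2 * (d + d * (d + 1) / 2 + 1)
  out <- k_max
  for (k in seq_len(k_max - 1L)) {
    no_gain <- gains[k] <= floor_gain
    dropped <- k >= 2 && gains[k] < alpha * max(gains[k - 1], 0)
    if (no_gain || dropped) {
      out <- k
      break
    }
  }
  structure(as.integer(out), logliks = ll)
}

#' Cells of the dominant mixture component
#'
#' Subsets a snapshot to the cells assigned (by maximum posterior
#' responsibility) to the fit's dominant component.
#'
#' @param fit a [fit_gmm()] result.
#' @param snapshot the snapshot the fit was computed on.
#' @return an [ensemble_snapshot()] with the same channels.
#' @export
select_subpopulation <- function(fit, snapshot) {
  stopifnot(inherits(fit, "gmm_fit"), inherits(snapshot, "ensemble_snapshot"))
  if (nrow(snapshot$values) != fit$n_cells)
    stop("snapshot cell count does not match the fit", call. = FALSE)
  assign <- max.col(fit$z, ties.method = "first")
  keep <- assign == fit$dominant
  if (!any(keep)) stop("dominant component is empty after assignment",
                       call. = FALSE)
  ensemble_snapshot(snapshot$values[keep, , drop = FALSE],
                    snapshot$channel_names, snapshot$time,
                    snapshot$log_space)
}

#' LDA separation between two dominant components
#'
#' Mahalanobis distance between the dominant component means of two fits,
#' under the pooled (effective-count-weighted) within-component covariance:
#' the projection of the mean difference on the two-class LDA axis, in
#' pooled-standard-deviation units. Zero for identical components and
#' invariant under any invertible linear transform applied to both
#' populations.
#'
#' @param fitA,fitB [fit_gmm()] results over the same channels.
#' @return nonnegative scalar.
#' @export
lda_separation <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "gmm_fit"), inherits(fitB, "gmm_fit"))
  if (!identical(fitA$channel_names, fitB$channel_names))
    stop("fits use different channels", call. = FALSE)
  muA <- fitA$means[, fitA$dominant]
  muB <- fitB$means[, fitB$dominant]
  nA <- fitA$weights[fitA$dominant] * fitA$n_cells
  nB <- fitB$weights[fitB$dominant] * fitB$n_cells
  pooled <- (nA * fitA$covariances[, , fitA$dominant] +
             nB * fitB$covariances[, , fitB$dominant]) / (nA + nB)
  delta <- muA - muB
  sol <- try(solve(pooled, delta), silent = TRUE)
  if (inherits(sol, "try-error")) {
    warning("singular pooled covariance; using regularized inverse")
    pooled <- pooled + diag(1e-8 * mean(diag(pooled)), nrow(pooled))
    sol <- solve(pooled, delta)
  }
  sqrt(max(sum(delta * sol), 0))
}
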