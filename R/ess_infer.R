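# Core inference: log-covariance eigendecomposition, eigengap detection,
# effective stoichiometric space (ESS) extraction, row reduction with
# complete pivoting, and entry-distribution summaries.

# entries closer than this to 0 (or 1 at pivots) are treated as the exact
# values row reduction necessarily produces
.exact_tol <- 1e-9

#' Eigendecomposition of the log-space sample covariance
#'
#' Natural-log transforms the snapshot if needed, mean-centers, forms the
#' unbiased (1/(N-1)) sample covariance, and eigendecomposes it. Eigenvalues
#' are reported in ascending order, so the leading columns of `vectors` span
#' the candidate effective stoichiometric space.
#'
#' @param snapshot an [ensemble_snapshot()] (or a plain cells x channels
#'   matrix, taken as linear-space).
#' @return object of class `"eigen_spectrum"`: `values` (ascending),
#'   `vectors` (orthonormal columns aligned to `values`, rownames =
#'   channels), `n_cells`, `channel_names`.
#' @export
fit_covariance_spectrum <- function(snapshot) {
  if (!inherits(snapshot, "ensemble_snapshot"))
    snapshot <- ensemble_snapshot(as.matrix(snapshot))
  x <- snapshot_log(snapshot)$values
  if (nrow(x) < 2L) stop("need at least 2 cells", call. = FALSE)
  v0 <- apply(x, 2L, stats::var)
  if (any(v0 == 0))
    stop("zero-variance channel(s): ",
         paste(colnames(x)[v0 == 0], collapse = ", "), call. = FALSE)
  sigma <- stats::cov(x)
  e <- eigen(sigma, symmetric = TRUE)
  ord <- order(e$values)
  values <- pmax(e$values[ord], 0)
  vectors <- e$vectors[, ord, drop = FALSE]
  rownames(vectors) <- colnames(x)
  structure(list(values = values, vectors = vectors, n_cells = nrow(x),
                 channel_names = colnames(x)),
            class = "eigen_spectrum")
}

#' @export
print.eigen_spectrum <- function(x, ...) {
  cat("eigen_spectrum:", length(x$values), "channels,", x$n_cells, "cells\n")
  cat("  eigenvalues (ascending):",
      paste(signif(x$values, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Detect gaps in an ascending eigenvalue spectrum
#'
#' Flags every position `i` where the ratio of consecutive eigenvalues
#' `lambda[i+1] / max(lambda[i], eps)` is at least `min_ratio`
#' (`eps = 1e-15 * max(lambda)` guards exact zeros). A ratio criterion is
#' scale-free, so uniform rescaling of the data cannot create or destroy a
#' gap. Multiple gaps encode timescale separation; the default choice is the
#' rightmost gap, which selects the full slow-plus-fast small eigenspace.
#'
#' @param spectrum an `"eigen_spectrum"` (or a numeric vector of ascending
#'   eigenvalues).
#' @param min_ratio gap threshold on consecutive-eigenvalue ratios.
#' @return object of class `"gap_report"`: `indices` (positions after which
#'   a gap occurs), `scores` (the ratios at those positions), `chosen`
#'   (rightmost gap, NA if none), `policy`.
#' @export
detect_gaps <- function(spectrum, min_ratio = 3.0) {
  values <- if (inherits(spectrum, "eigen_spectrum")) spectrum$values
            else as.numeric(spectrum)
  if (length(values) < 2L) stop("need at least 2 eigenvalues", call. = FALSE)
  if (is.unsorted(values)) stop("eigenvalues must be ascending", call. = FALSE)
  eps <- 1e-15 * max(values)
  ratios <- values[-1] / pmax(values[-length(values)], eps)
  idx <- which(ratios >= min_ratio)
  structure(list(indices = idx, scores = ratios[idx],
                 chosen = if (length(idx)) max(idx) else NA_integer_,
                 policy = sprintf("rightmost ratio >= %g", min_ratio)),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  if (length(x$indices) == 0L) {
    cat("gap_report: no gaps\n")
  } else {
    cat("gap_report: gaps after indices",
        paste(x$indices, collapse = ", "),
        sprintf("(chosen: %d; %s)\n", x$chosen, x$policy))
  }
  invisible(x)
}

#' Extract the effective stoichiometric space
#'
#' The ESS basis is the span of the eigenvectors belonging to the smallest
#' eigenvalues, cut at a spectral gap. Either a gap index / fixed dimension
#' is supplied, or gaps are detected automatically. With `nested = TRUE`,
#' one basis per detected gap is returned (ascending dimension); each
#' contains the previous, mirroring the nesting of fast sub-subspaces inside
#' the full stoichiometric subspace.
#'
#' @param spectrum an `"eigen_spectrum"`.
#' @param dimension number of small eigenvectors to keep; default: the
#'   rightmost detected gap.
#' @param min_ratio passed to [detect_gaps()] when `dimension` is NULL.
#' @param nested return a list of ESS bases, one per detected gap.
#' @return an object of class `"ess_basis"` (`basis` orthonormal channels x
#'   dim, `dim`, `gap_index`), or a list of them when `nested = TRUE`.
#' @export
extract_ess <- function(spectrum, dimension = NULL, min_ratio = 3.0,
                        nested = FALSE) {
  stopifnot(inherits(spectrum, "eigen_spectrum"))
  d <- length(spectrum$values)
  take <- function(k) {
    structure(list(basis = spectrum$vectors[, seq_len(k), drop = FALSE],
                   dim = as.integer(k), gap_index = as.integer(k),
                   channel_names = spectrum$channel_names),
              class = "ess_basis")
  }
  if (nested) {
    gr <- detect_gaps(spectrum, min_ratio)
    if (length(gr$indices) == 0L) return(list())
    return(lapply(gr$indices, take))
  }
  if (is.null(dimension)) {
    gr <- detect_gaps(spectrum, min_ratio)
    if (is.na(gr$chosen))
      stop("no spectral gap detected; supply 'dimension' explicitly",
           call. = FALSE)
    dimension <- gr$chosen
  }
  if (dimension < 1 || dimension > d)
    stop("requested ESS dimension ", dimension, " outside [1, ", d, "]",
         call. = FALSE)
  take(dimension)
}

#' Row reduction with complete pivoting
#'
#' Gauss-Jordan elimination on the matrix whose rows are the (transposed)
#' ESS basis vectors. At every step the pivot is the largest-magnitude entry
#' of the remaining submatrix (ties broken toward the lowest column index,
#' then the lowest row index); the corresponding row and column are swapped
#' into place, the pivot row is scaled so the pivot equals 1, and the pivot
#' column is eliminated from every other row. The result represents the same
#' subspace by sparser vectors, each normalized to a pivot channel -- the
#' net reactions. The row/column permutation is recorded so bootstrap
#' replicates can replay exactly the same elimination
#' ([replay_row_reduction()]).
#'
#' @param basis an `"ess_basis"`, or a channels x s matrix with basis
#'   vectors in columns.
#' @return object of class `"row_reduced_basis"`: `vectors` (s x channels
#'   matrix in original channel order; pivot entries exactly 1, eliminated
#'   entries exactly 0), `pivots` (channel index per row), `row_perm`,
#'   `col_perm` (the permutations applied), `channel_names`.
#' @export
row_reduce_complete_pivoting <- function(basis) {
  B <- if (inherits(basis, "ess_basis")) basis$basis else as.matrix(basis)
  channel_names <- if (inherits(basis, "ess_basis")) basis$channel_names
                   else rownames(B)
  if (ncol(B) == 0L) stop("empty basis", call. = FALSE)
  M <- t(B)                       # s rows (vectors) x d columns (channels)
  s <- nrow(M); d <- ncol(M)
  if (s > d) stop("more basis vectors than channels", call. = FALSE)
  row_perm <- seq_len(s)
  col_perm <- seq_len(d)
  tol <- .rank_tol * max(abs(M), 1e-300)
  for (k in seq_len(s)) {
    sub <- abs(M[k:s, k:d, drop = FALSE])
    mx <- max(sub)
    if (mx < tol)
      stop("numerically rank-deficient basis (effective rank ", k - 1L, ")",
           call. = FALSE)
    # ties: lowest column index, then lowest row index
    hits <- which(sub == mx, arr.ind = TRUE)
    hit <- hits[order(hits[, "col"], hits[, "row"])[1L], ]
    pr <- k + hit[["row"]] - 1L
    pc <- k + hit[["col"]] - 1L
    if (pr != k) {
      M[c(k, pr), ] <- M[c(pr, k), ]
      row_perm[c(k, pr)] <- row_perm[c(pr, k)]
    }
    if (pc != k) {
      M[, c(k, pc)] <- M[, c(pc, k)]
      col_perm[c(k, pc)] <- col_perm[c(pc, k)]
    }
    M[k, ] <- M[k, ] / M[k, k]
    M[k, k] <- 1
    other <- setdiff(seq_len(s), k)
    M[other, ] <- M[other, ] - outer(M[other, k], M[k, ])
    M[other, k] <- 0
  }
  finalize_rref(M, row_perm, col_perm, channel_names)
}

finalize_rref <- function(M, row_perm, col_perm, channel_names) {
  s <- nrow(M); d <- ncol(M)
  M[abs(M) < .exact_tol] <- 0
  out <- matrix(0, s, d)
  out[, col_perm] <- M
  pivots <- col_perm[seq_len(s)]
  colnames(out) <- channel_names
  rownames(out) <- if (!is.null(channel_names)) channel_names[pivots]
  structure(list(vectors = out, pivots = pivots, row_perm = row_perm,
                 col_perm = col_perm, channel_names = channel_names),
            class = "row_reduced_basis")
}

#' Replay a recorded row reduction on a new basis
#'
#' Applies the row/column rearrangements recorded by
#' [row_reduce_complete_pivoting()] to another basis of the same shape and
#' eliminates in that fixed order, without searching for pivots. This keeps
#' entries comparable across bootstrap replicates.
#'
#' @param basis an `"ess_basis"` or channels x s matrix.
#' @param record a `"row_reduced_basis"` whose permutations to reuse.
#' @return a `"row_reduced_basis"`.
#' @export
replay_row_reduction <- function(basis, record) {
  stopifnot(inherits(record, "row_reduced_basis"))
  B <- if (inherits(basis, "ess_basis")) basis$basis else as.matrix(basis)
  M <- t(B)
  s <- nrow(M); d <- ncol(M)
  if (s != length(record$row_perm) || d != length(record$col_perm))
    stop("basis shape does not match the recorded reduction", call. = FALSE)
  M <- M[record$row_perm, record$col_perm, drop = FALSE]
  tol <- .rank_tol * max(abs(M), 1e-300)
  for (k in seq_len(s)) {
    if (abs(M[k, k]) < tol)
      stop("replayed pivot ", k, " is numerically zero", call. = FALSE)
    M[k, ] <- M[k, ] / M[k, k]
    M[k, k] <- 1
    other <- setdiff(seq_len(s), k)
    M[other, ] <- M[other, ] - outer(M[other, k], M[k, ])
    M[other, k] <- 0
  }
  finalize_rref(M, record$row_perm, record$col_perm, record$channel_names)
}

#' @export
print.row_reduced_basis <- function(x, ...) {
  cat("row_reduced_basis:", nrow(x$vectors), "net-reaction vector(s) over",
      ncol(x$vectors), "channels\n")
  print(round(x$vectors, 3))
  invisible(x)
}

#' Pooled distribution of row-reduced vector entries
#'
#' Pools the entries of one or more row-reduced bases, excluding the exact
#' 0s and pivot 1s that row reduction necessarily produces, and summarizes
#' them with a Gaussian kernel density (bandwidth 0.04 by default) on a
#' fixed grid. Also reports the fraction of entries inside the near-zero
#' window `(-0.2, 0.2)` -- the sparsity summary used to calibrate the null
#' model.
#'
#' @param bases a `"row_reduced_basis"` or list of them.
#' @param bandwidth Gaussian kernel bandwidth.
#' @param window near-zero window (open interval).
#' @param grid_from,grid_to,grid_by density evaluation grid.
#' @return list of class `"entry_distribution"`: `entries` (raw pooled
#'   values), `density` (data.frame x/y, NULL when no entries),
#'   `fraction_window` (NA when no entries), `n_entries`, `bandwidth`.
#' @export
entry_distribution <- function(bases, bandwidth = 0.04,
                               window = c(-0.2, 0.2), grid_from = -1.5,
                               grid_to = 1.5, grid_by = 0.005) {
  if (inherits(bases, "row_reduced_basis")) bases <- list(bases)
  if (length(bases) == 0L) stop("at least one basis required", call. = FALSE)
  entries <- unlist(lapply(bases, function(b) {
    stopifnot(inherits(b, "row_reduced_basis"))
    e <- as.vector(b$vectors)
    e[abs(e) >= .exact_tol & abs(e - 1) >= .exact_tol]
  }))
  if (length(entries) == 0L) {
    return(structure(list(entries = numeric(0), density = NULL,
                          fraction_window = NA_real_, n_entries = 0L,
                          bandwidth = bandwidth),
                     class = "entry_distribution"))
  }
  n_grid <- round((grid_to - grid_from) / grid_by) + 1L
  dens <- stats::density(entries, bw = bandwidth, kernel = "gaussian",
                         from = grid_from, to = grid_to, n = n_grid)
  frac <- mean(entries > window[1] & entries < window[2])
  structure(list(entries = entries,
                 density = data.frame(x = dens$x, y = dens$y),
                 fraction_window = frac, n_entries = length(entries),
                 bandwidth = bandwidth),
            class = "entry_distribution")
}
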