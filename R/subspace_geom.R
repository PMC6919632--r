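# Principal angle decomposition between subspaces and the scalar metric
# used for inter-condition comparison.

as_orthonormal_basis <- function(U, arg = "basis") {
  if (inherits(U, "ess_basis")) U <- U$basis
  U <- as.matrix(U)
  if (ncol(U) == 0L) stop(arg, " is empty", call. = FALSE)
  g <- crossprod(U)
  if (max(abs(g - diag(ncol(U)))) > 1e-6)
    stop(arg, " is not orthonormal; orthonormalize first ",
         "(e.g. orthonormal_span())", call. = FALSE)
  U
}

#' Principal angles between two subspaces
#'
#' Canonical angles of the subspaces spanned by the orthonormal columns of
#' `U` and `W`: the arccosines of the singular values of `t(U) %*% W`
#' (clipped into [0, 1] against floating-point overshoot), reported in
#' ascending order. The number of angles is the smaller of the two
#' dimensions.
#'
#' Small angles are refined with the sine-based formula (singular values of
#' `W - U (U'W)`), which resolves angles far below the ~1e-8 floor of the
#' plain arccosine.
#'
#' @param U,W matrices with orthonormal columns over the same channel set
#'   (or `"ess_basis"` objects).
#' @return ascending numeric vector of angles in `[0, pi/2]` (radians).
#' @export
principal_angles <- function(U, W) {
  U <- as_orthonormal_basis(U, "U")
  W <- as_orthonormal_basis(W, "W")
  if (nrow(U) != nrow(W))
    stop("ambient dimensions differ (", nrow(U), " vs ", nrow(W), ")",
         call. = FALSE)
  if (ncol(U) < ncol(W)) { tmp <- U; U <- W; W <- tmp }
  C <- crossprod(U, W)
  theta <- sort(acos(pmin(pmax(svd(C)$d, 0), 1)))
  small <- theta < 1e-4
  if (any(small)) {
    # sin(theta_i) = singular values of the residual of W against span(U);
    # both lists are ascending, so ranks align
    sines <- sort(svd(W - U %*% C)$d)
    theta[small] <- asin(pmin(pmax(sines[small], 0), 1))
  }
  sort(theta)
}

#' Angle metric between equal-dimension subspaces
#'
#' The Euclidean norm of the principal-angle vector,
#' `d = sqrt(sum(theta_i^2))` -- a Grassmann geodesic distance. Only
#' meaningful between subspaces of equal dimension.
#'
#' @param angles numeric vector of principal angles (from
#'   [principal_angles()] of two equal-dimension subspaces).
#' @return nonnegative scalar.
#' @export
angle_metric <- function(angles) {
  if (length(angles) == 0L) stop("no angles supplied", call. = FALSE)
  if (any(angles < -1e-12 | angles > pi / 2 + 1e-12))
    stop("angles must lie in [0, pi/2]", call. = FALSE)
  sqrt(sum(angles^2))
}

#' Compare two subspaces
#'
#' Principal angle decomposition plus the scalar metric. The metric requires
#' equal dimensions; unequal-dimension comparisons return the angles but an
#' `NA` metric with a warning.
#'
#' @param U,W orthonormal bases (or `"ess_basis"` objects).
#' @return object of class `"subspace_comparison"`: `angles` (ascending) and
#'   `metric_d`.
#' @export
compare_subspaces <- function(U, W) {
  Ub <- as_orthonormal_basis(U, "U")
  Wb <- as_orthonormal_basis(W, "W")
  angles <- principal_angles(Ub, Wb)
  if (ncol(Ub) != ncol(Wb)) {
    warning("subspace dimensions differ (", ncol(Ub), " vs ", ncol(Wb),
            "); metric_d is NA")
    d <- NA_real_
  } else {
    d <- angle_metric(angles)
  }
  structure(list(angles = angles, metric_d = d),
            class = "subspace_comparison")
}

#' @export
print.subspace_comparison <- function(x, ...) {
  cat("subspace_comparison: angles =",
      paste(signif(x$angles, 4), collapse = ", "),
      "; d =", signif(x$metric_d, 4), "\n")
  invisible(x)
}
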