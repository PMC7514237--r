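# phi for a pre-fitted model, with optionally precomputed vertex rows.
# Residuals are of the duality-scale standardized vertex rows relative to the
# span of the first s eigenvectors; by Pythagoras the summed squared residual
# is total squared norm minus explained squared norm.
phi_model <- function(X, model, s, vrows = NULL) {
  if (is.null(vrows)) vrows <- vertex_matrix(X)$rows
  Vt <- standardize_wrt(vrows, model$stats)
  Ws <- model$eigvecs[, seq_len(s), drop = FALSE]
  sum(Vt^2) - sum((Vt %*% Ws)^2)
}

#' Vertex-to-subspace squared distance
#'
#' The distance criterion of the Best Point Distance method: fit correlation
#' PCA on the realization `Z`, standardize every vertex of the interval box
#' with respect to `Z`'s column statistics (duality scale), project onto the
#' span of the first `s` eigenvectors, and sum the squared Euclidean
#' residuals over all `N = sum_i 2^{m_i}` vertices.  Zero when `s = m`, or
#' whenever the standardized data (and vertices) lie in an s-dimensional
#' subspace.
#'
#' @param X an [interval_matrix].
#' @param Z a realization of `X`'s box (checked for membership).
#' @param s number of retained components, `1 <= s <= m`; default
#'   `min(2, m)`.
#' @return the nonnegative squared distance (numeric scalar).
#' @export
phi <- function(X, Z, s = NULL) {
  stopifnot(inherits(X, "interval_matrix"))
  Z <- as.matrix(Z)
  m <- ncol(X$lower)
  if (is.null(s)) s <- min(2L, m)
  if (s < 1L || s > m) stop("'s' must be between 1 and m")
  if (!in_box(X, Z)) stop("'Z' is not a realization of the interval box")
  model <- fit_pca(Z, s = s)
  phi_model(X, model, s)
}

#' Retained inertia of the leading components
#'
#' The variance criterion of the Best Point Variance method: the sum of the
#' top `s` eigenvalues of the correlation matrix of `Z`.  Ranges from 0 to
#' `m`, equals `m` at `s = m`.
#'
#' @param Z a numeric realization matrix, no constant column.
#' @param s number of leading components, `1 <= s <= m`; default `min(2, m)`.
#' @return the retained inertia (numeric scalar).
#' @export
lambda_sum <- function(Z, s = NULL) {
  Z <- as.matrix(Z)
  m <- ncol(Z)
  if (is.null(s)) s <- min(2L, m)
  if (s < 1L || s > m) stop("'s' must be between 1 and m")
  model <- fit_pca(Z, s = s)
  sum(model$eigvals[seq_len(s)])
}
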