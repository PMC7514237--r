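# Sign convention: flip each eigenvector so its largest-|entry| loading is
# positive; which.max resolves ties toward the lower index.  Idempotent.
fix_signs <- function(W) {
  for (k in seq_len(ncol(W))) {
    j <- which.max(abs(W[, k]))
    if (W[j, k] < 0) W[, k] <- -W[, k]
  }
  W
}

#' Correlation PCA of a realization matrix
#'
#' Fits classical principal component analysis to a point matrix `Z` on
#' standardized variables (correlation PCA): the eigendecomposition of the
#' Gram matrix of the `1/(sqrt(n) sd_j)`-standardized data, which equals the
#' correlation matrix of `Z`, so the eigenvalues are nonnegative and sum to
#' the number of variables `m`.  Correlation PCA is the single supported
#' mode because every standardization used by the interval projections and
#' duality relations divides by the column standard deviation.
#'
#' Component scores are reported on the conventional z-score scale,
#' `score_ik = sum_j (Z_ij - mean_j)/sd_j * w_kj`, which is `sqrt(n)` times
#' the projection of the duality-scale standardized rows.
#'
#' @param Z numeric n x m matrix (a realization of an interval box, e.g. the
#'   center matrix), n >= 2, no constant column.
#' @param s number of components to retain in downstream interval
#'   projections; defaults to `min(2, m)`.
#' @return An object of class `ipca_model`: list with `stats`
#'   ([column_stats]), `eigvals` (length m, non-increasing), `eigvecs`
#'   (m x m orthonormal, sign-fixed), `scores` (n x m, z-score scale), `s`,
#'   and `percent` (cumulative percent variance per component).
#' @examples
#' Z <- matrix(rnorm(40), 10, 4)
#' fit <- fit_pca(Z)
#' sum(fit$eigvals)  # == 4
#' @export
fit_pca <- function(Z, s = NULL) {
  Z <- as.matrix(Z)
  stats <- column_stats(Z)
  m <- ncol(Z)
  if (is.null(s)) s <- min(2L, m)
  if (s < 1L || s > m) stop("'s' must be between 1 and m")
  Zt <- standardize_wrt(Z, stats)            # crossprod(Zt) = correlation matrix
  e <- eigen(crossprod(Zt), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  W <- fix_signs(e$vectors)
  rownames(W) <- colnames(Z)
  colnames(W) <- paste0("PC", seq_len(m))
  scores <- sqrt(stats$n) * (Zt %*% W)
  dimnames(scores) <- list(rownames(Z), colnames(W))
  structure(list(stats = stats, eigvals = lam, eigvecs = W,
                 scores = scores, s = as.integer(s),
                 percent = cumsum(lam) / m * 100),
            class = "ipca_model")
}

#' @export
print.ipca_model <- function(x, ...) {
  m <- length(x$eigvals)
  cat(sprintf("correlation PCA on %d x %d data; s = %d retained\n",
              x$stats$n, m, x$s))
  cat("cumulative % variance:",
      paste0(sprintf("%.2f", x$percent), "%", collapse = " "), "\n")
  invisible(x)
}

#' Re-anchor component signs to chosen variables
#'
#' Printed tables in the interval-PCA literature fix component signs by
#' requiring a named anchor variable to load positively on each component
#' (e.g. the dominant facial distance on PC1).  This flips eigenvector
#' columns (and scores) so that the anchor variable's loading on each
#' anchored component is nonnegative.  For correlation PCA the sign of a
#' variable's loading equals the sign of its correlation with the component.
#'
#' @param model an [fit_pca()] model.
#' @param anchors character or integer vector; `anchors[k]` names the
#'   variable anchoring component k.  `NA` entries leave the default
#'   largest-|loading|-positive convention in place.
#' @return the model with flipped `eigvecs` and `scores` columns.
#' @export
anchor_signs <- function(model, anchors) {
  stopifnot(inherits(model, "ipca_model"))
  W <- model$eigvecs
  for (k in seq_along(anchors)) {
    a <- anchors[k]
    if (is.na(a)) next
    j <- if (is.character(a)) match(a, rownames(W)) else as.integer(a)
    if (is.na(j)) stop(sprintf("anchor variable '%s' not found", a))
    if (W[j, k] < 0) {
      W[, k] <- -W[, k]
      model$scores[, k] <- -model$scores[, k]
    }
  }
  model$eigvecs <- W
  model
}

#' Project supplementary points into a fitted PCA basis
#'
#' Supplementary points are projected into an existing basis without
#' influencing the fit.  The points must already be standardized with respect
#' to the model's column statistics (on whichever scale the caller works:
#' z-score for scores, duality scale for the Gram-side relations).
#'
#' @param points numeric matrix with m columns, already standardized.
#' @param model an [fit_pca()] model.
#' @return `points %*% eigvecs` (all m components).
#' @export
project_supplementary <- function(points, model) {
  stopifnot(inherits(model, "ipca_model"))
  points <- as.matrix(points)
  if (ncol(points) != nrow(model$eigvecs))
    stop("'points' must have one column per model variable")
  points %*% model$eigvecs
}

#' Row-side (dual) principal directions
#'
#' For the duality-scale standardized matrix `Zt` (columns of unit sum of
#' squares), the case-side Gram matrix `Zt %*% t(Zt)` and the variable-side
#' `t(Zt) %*% Zt` share their nonzero eigenvalues, and their eigenvectors are
#' linked by `u = t(Zt) v / sqrt(lambda)` and `v = Zt u / sqrt(lambda)`.
#' This returns the case-side eigenvectors `v` consistent in sign with the
#' model's variable-side eigenvectors, together with the variable-side
#' vectors recovered through the duality relation.
#'
#' @param model an [fit_pca()] model fitted on `Z`.
#' @param Z the fitted realization matrix.
#' @param s number of dual directions (all must have positive eigenvalue);
#'   default `model$s`.
#' @return An object of class `ipca_dual`: list with `v` (n x s), `u`
#'   (m x s, equal to the model eigenvectors on nonzero eigenvalues),
#'   `eigvals` (length s) and `stats`.
#' @export
dual_components <- function(model, Z, s = model$s) {
  stopifnot(inherits(model, "ipca_model"))
  lam <- model$eigvals[seq_len(s)]
  if (any(lam <= 1e-12))
    stop("dual direction requested for a zero eigenvalue")
  Zt <- standardize_wrt(as.matrix(Z), model$stats)
  Ws <- model$eigvecs[, seq_len(s), drop = FALSE]
  v <- sweep(Zt %*% Ws, 2L, sqrt(lam), "/")
  u <- sweep(crossprod(Zt, v), 2L, sqrt(lam), "/")
  structure(list(v = v, u = u, eigvals = lam, stats = model$stats),
            class = "ipca_dual")
}

#' Variable coordinates along dual directions
#'
#' `r_ij = sum_k Zt_ki v_kj`: the coordinate of variable i on dual component
#' j, i.e. its position in the correlation circle (for the fitted matrix this
#' equals the correlation of the variable with the component).
#'
#' @param Zt duality-scale standardized matrix (from [standardize_wrt()]).
#' @param v n x s matrix of dual directions (columns of `dual$v`).
#' @return m x s matrix of coordinates.
#' @export
dual_scores <- function(Zt, v) {
  crossprod(as.matrix(Zt), as.matrix(v))
}
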