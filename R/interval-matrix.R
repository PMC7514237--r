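#' Construct an interval matrix
#'
#' An interval matrix holds, for each of `n` cases and `m` variables, a closed
#' interval `[a_ij, b_ij]` with `a_ij <= b_ij`.  It describes the set of all
#' real n x m matrices `Z` whose entries satisfy `a_ij <= Z_ij <= b_ij`
#' (the "interval box"); any such `Z` is called a realization of the interval
#' matrix.
#'
#' @param lower,upper numeric n x m matrices of lower and upper bounds.
#' @param case_labels character vector of length n; defaults to rownames of
#'   `lower` or `case1..casen`.
#' @param var_names character vector of length m; defaults to colnames of
#'   `lower` or `X1..Xm`.
#'
#' @return An object of class `interval_matrix`: a list with elements
#'   `lower`, `upper` (numeric matrices), `case_labels` and `var_names`.
#' @examples
#' X <- interval_matrix(lower = rbind(c(1, 0), c(2, 2)),
#'                      upper = rbind(c(3, 1), c(2, 5)))
#' center_matrix(X)
#' @export
interval_matrix <- function(lower, upper, case_labels = NULL, var_names = NULL) {
  lower <- as.matrix(lower)
  upper <- as.matrix(upper)
  storage.mode(lower) <- "double"
  storage.mode(upper) <- "double"
  if (!identical(dim(lower), dim(upper)))
    stop("'lower' and 'upper' must have identical dimensions")
  n <- nrow(lower); m <- ncol(lower)
  if (n < 2L) stop("an interval matrix needs at least 2 cases (rows)")
  if (m < 1L) stop("an interval matrix needs at least 1 variable (column)")
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("all interval bounds must be finite")
  bad <- which(lower > upper, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("lower bound exceeds upper bound at row %d, column %d",
                 bad[1L, 1L], bad[1L, 2L]))
  if (is.null(case_labels)) case_labels <- rownames(lower)
  if (is.null(case_labels)) case_labels <- paste0("case", seq_len(n))
  if (is.null(var_names)) var_names <- colnames(lower)
  if (is.null(var_names)) var_names <- paste0("X", seq_len(m))
  if (length(case_labels) != n) stop("'case_labels' must have length n")
  if (length(var_names) != m) stop("'var_names' must have length m")
  dimnames(lower) <- dimnames(upper) <- list(case_labels, var_names)
  structure(list(lower = lower, upper = upper,
                 case_labels = as.character(case_labels),
                 var_names = as.character(var_names)),
            class = "interval_matrix")
}

#' @export
dim.interval_matrix <- function(x) dim(x$lower)

#' @export
print.interval_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("interval_matrix: %d cases x %d interval variables\n", d[1L], d[2L]))
  show <- min(d[1L], 5L)
  cells <- matrix(sprintf("[%.4g, %.4g]",
                          x$lower[seq_len(show), , drop = FALSE],
                          x$upper[seq_len(show), , drop = FALSE]),
                  nrow = show,
                  dimnames = list(x$case_labels[seq_len(show)], x$var_names))
  print(cells, quote = FALSE)
  if (d[1L] > show) cat(sprintf("... and %d more cases\n", d[1L] - show))
  invisible(x)
}

#' Interval widths of an interval matrix
#'
#' @param X an [interval_matrix].
#' @return numeric n x m matrix `upper - lower`.
#' @export
interval_widths <- function(X) {
  stopifnot(inherits(X, "interval_matrix"))
  X$upper - X$lower
}

#' Test whether a point matrix lies inside the interval box
#'
#' @param X an [interval_matrix].
#' @param Z a numeric matrix of the same dimension.
#' @param tol nonnegative slack allowed on each bound.
#' @return `TRUE` if `lower - tol <= Z <= upper + tol` everywhere.
#' @export
in_box <- function(X, Z, tol = 1e-9) {
  stopifnot(inherits(X, "interval_matrix"))
  Z <- as.matrix(Z)
  identical(dim(Z), dim(X$lower)) &&
    all(Z >= X$lower - tol) && all(Z <= X$upper + tol)
}

#' Center matrix of an interval matrix
#'
#' The center matrix replaces every interval by its midpoint
#' `(a_ij + b_ij) / 2`.  It is itself a realization of the interval box and is
#' the classical starting point for interval PCA (the "center method") as well
#' as the initial value for the Best Point optimizers.
#'
#' @param X an [interval_matrix].
#' @return a numeric n x m matrix with the case labels and variable names of
#'   `X` as dimnames.
#' @export
center_matrix <- function(X) {
  stopifnot(inherits(X, "interval_matrix"))
  (X$lower + X$upper) / 2
}

#' Vertex matrix of an interval matrix
#'
#' Each case of an interval matrix spans an axis-aligned hyper-rectangle in
#' m-dimensional space.  The vertex matrix stacks, case by case, all corners
#' of these hyper-rectangles.  A case with `m_i` nontrivial intervals
#' (`a_ij < b_ij`) contributes `2^m_i` rows; degenerate intervals contribute
#' their single value and are not duplicated, so the total row count is
#' `N = sum_i 2^{m_i}`.
#'
#' Rows of a case are ordered by binary counting over its nontrivial columns,
#' with the leftmost nontrivial column varying slowest and the lower bound
#' coded 0, the upper bound 1.
#'
#' @param X an [interval_matrix].
#' @return An object of class `vertex_matrix`: a list with `rows` (N x m
#'   numeric matrix), `case_of_row` (integer vector mapping each row to its
#'   case index), and `m_i` (per-case count of nontrivial intervals).
#' @export
vertex_matrix <- function(X) {
  stopifnot(inherits(X, "interval_matrix"))
  n <- nrow(X$lower); m <- ncol(X$lower)
  nontrivial <- X$lower < X$upper
  m_i <- rowSums(nontrivial)
  blocks <- vector("list", n)
  for (i in seq_len(n)) {
    free <- which(nontrivial[i, ])
    k <- length(free)
    rows <- matrix(X$lower[i, ], nrow = 2L^k, ncol = m, byrow = TRUE)
    if (k > 0L) {
      # binary counting: leftmost free column slowest, 0 -> a, 1 -> b
      grid <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
      for (c in seq_len(k)) {
        j <- free[c]
        rows[grid[, c] == 1L, j] <- X$upper[i, j]
      }
    }
    blocks[[i]] <- rows
  }
  rows <- do.call(rbind, blocks)
  colnames(rows) <- X$var_names
  structure(list(rows = rows,
                 case_of_row = rep.int(seq_len(n), 2L^m_i),
                 m_i = m_i,
                 N = nrow(rows),
                 case_labels = X$case_labels),
            class = "vertex_matrix")
}

#' @export
print.vertex_matrix <- function(x, ...) {
  cat(sprintf("vertex_matrix: %d rows from %d cases (m_i range %d..%d)\n",
              x$N, length(x$m_i), min(x$m_i), max(x$m_i)))
  invisible(x)
}

#' Column statistics of a realization matrix
#'
#' Means and population standard deviations (divisor n) of each column, the
#' quantities every standardization in the package is taken with respect to.
#' With the population divisor, standardizing a matrix by its own statistics
#' and the additional `1/sqrt(n)` factor gives columns with unit sum of
#' squares, so the Gram matrix of the standardized data is exactly the
#' correlation matrix.
#'
#' @param Z a numeric matrix with at least 2 rows.
#' @return An object of class `column_stats`: list with `mean`, `sd`
#'   (length-m numerics) and `n` (row count).
#' @export
column_stats <- function(Z) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n < 2L) stop("need at least 2 rows to compute column statistics")
  mu <- colMeans(Z)
  sd <- sqrt(colMeans(sweep(Z, 2L, mu, "-")^2))
  const <- which(sd <= 0 | !is.finite(sd))
  if (length(const) > 0L) {
    nm <- colnames(Z)[const[1L]]
    if (is.null(nm)) nm <- as.character(const[1L])
    stop(sprintf("column '%s' is constant (zero standard deviation)", nm))
  }
  structure(list(mean = mu, sd = sd, n = n), class = "column_stats")
}

#' Center and standardize with respect to column statistics
#'
#' Transforms each entry as `(x - mean_j) / (sqrt(n) * sd_j)`.  With this
#' scaling the standardized version of the statistics' own source matrix has
#' columns of mean zero and sum of squares one, which is the normalization the
#' row-column duality relations rely on.  For an [interval_matrix] both bound
#' matrices are transformed; since the scale factor is positive, interval
#' order is preserved.
#'
#' @param M a numeric matrix or an [interval_matrix].
#' @param stats a [column_stats] object (from some realization of the box).
#' @return an object of the same shape as `M`.
#' @export
standardize_wrt <- function(M, stats) {
  stopifnot(inherits(stats, "column_stats"))
  denom <- sqrt(stats$n) * stats$sd
  if (any(denom <= 0)) {
    j <- which(denom <= 0)[1L]
    stop(sprintf("column %d has zero standard deviation", j))
  }
  scale_mat <- function(A)
    sweep(sweep(as.matrix(A), 2L, stats$mean, "-"), 2L, denom, "/")
  if (inherits(M, "interval_matrix")) {
    interval_matrix(scale_mat(M$lower), scale_mat(M$upper),
                    case_labels = M$case_labels, var_names = M$var_names)
  } else {
    if (ncol(as.matrix(M)) != length(stats$mean))
      stop("column count of 'M' does not match 'stats'")
    scale_mat(M)
  }
}

# z-score version (x - mean)/sd: the scale component scores are reported on.
zscore_wrt <- function(M, stats) {
  sweep(sweep(as.matrix(M), 2L, stats$mean, "-"), 2L, stats$sd, "/")
}
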