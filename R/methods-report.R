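#' Run one interval-PCA method end to end
#'
#' The four methods share a pipeline: choose a fitted point matrix (the
#' interval midpoints for `"center"`, the stacked hyper-rectangle corners for
#' `"vertex"`, an optimized realization for `"bp-distance"` /
#' `"bp-variance"`), fit correlation PCA to it, and project the interval
#' bounds through the sign-split closed form to obtain interval component
#' scores.
#'
#' Variable-component correlations are computed at vertex level: every
#' vertex row is projected as a supplementary point into the fitted basis
#' and each original variable's vertex column is Pearson-correlated with the
#' projected component scores.  (For the vertex method the vertex rows are
#' the fitted rows themselves.)  This is the single-number summary that is
#' comparable across all four methods, since the vertex set is the same for
#' each.
#'
#' @param X an [interval_matrix].
#' @param method one of `"center"`, `"vertex"`, `"bp-distance"`,
#'   `"bp-variance"`.
#' @param s retained components for interval scores, the optimizers and
#'   [phi()]; default `min(2, m)`.
#' @param cfg a [bp_config()] for the Best Point methods.
#' @param anchors optional sign anchors passed to [anchor_signs()], e.g.
#'   `c("X4", "X3")` to force those variables to load positively on PC1 and
#'   PC2.
#' @return An object of class `ipca_method`: list with `method`, `model`
#'   ([fit_pca()] model on the fitted matrix), `Z_fit`, `scores`
#'   ([interval_scores()]), `percent` (cumulative percent variance, length
#'   m), `phi` (vertex-to-subspace squared distance of the method's fit at
#'   `s` components), `correlations` (m x s), and for the Best Point methods
#'   `best_point` (the optimizer result).
#' @examples
#' X <- synthesize_interval_matrix(8, 3, seed = 2)
#' res <- run_method(X, "center")
#' res$percent
#' @export
run_method <- function(X, method = c("center", "vertex", "bp-distance", "bp-variance"),
                       s = NULL, cfg = bp_config(), anchors = NULL) {
  stopifnot(inherits(X, "interval_matrix"))
  method <- match.arg(method)
  m <- ncol(X$lower)
  if (is.null(s)) s <- min(2L, m)
  vm <- vertex_matrix(X)
  bp <- NULL
  Z_fit <- switch(method,
    "center" = center_matrix(X),
    "vertex" = vm$rows,
    "bp-distance" = { bp <- optimize_distance(X, s = s, cfg = cfg); bp$Z_opt },
    "bp-variance" = { bp <- optimize_variance(X, s = s, cfg = cfg); bp$Z_opt })
  model <- fit_pca(Z_fit, s = s)
  if (!is.null(anchors)) model <- anchor_signs(model, anchors)
  vproj <- project_supplementary(zscore_wrt(vm$rows, model$stats), model)
  correlations <- stats::cor(vm$rows, vproj[, seq_len(s), drop = FALSE])
  colnames(correlations) <- paste0("PC", seq_len(s))
  structure(list(method = method, model = model, Z_fit = Z_fit,
                 scores = interval_scores(X, model, s = s),
                 percent = model$percent,
                 phi = phi_model(X, model, s, vrows = vm$rows),
                 correlations = correlations,
                 best_point = bp, s = as.integer(s)),
            class = "ipca_method")
}

#' @export
print.ipca_method <- function(x, ...) {
  cat(sprintf("interval PCA, %s method (s = %d)\n", x$method, x$s))
  cat("cumulative % variance:",
      paste0(sprintf("%.2f", x$percent), "%", collapse = " "), "\n")
  cat(sprintf("vertex-to-subspace squared distance (phi): %.4f\n", x$phi))
  invisible(x)
}

#' Run and collect all four methods
#'
#' @inheritParams run_method
#' @param methods methods to run.
#' @return a named list of [run_method()] results.
#' @export
run_comparison <- function(X, s = NULL, cfg = bp_config(), anchors = NULL,
                           methods = c("center", "vertex", "bp-distance",
                                       "bp-variance")) {
  res <- lapply(methods, function(mm)
    run_method(X, mm, s = s, cfg = cfg, anchors = anchors))
  names(res) <- methods
  res
}

#' Cumulative variance table (components x methods)
#'
#' @param results a named list of [run_method()] results.
#' @return data.frame of cumulative percent variance, rows `PC1..PCm`,
#'   one column per method; every column ends at 100.
#' @export
variance_table <- function(results) {
  cols <- lapply(results, function(r) r$percent)
  df <- as.data.frame(cols, check.names = FALSE)
  rownames(df) <- paste0("PC", seq_len(nrow(df)))
  df
}

#' Variable-component correlation table (methods x variables)
#'
#' One row per method: the Pearson correlation of each original variable
#' (vertex column) with the method's component scores of the projected
#' vertices, for the requested component.
#'
#' @param results a named list of [run_method()] results.
#' @param component which component to tabulate (default 1).
#' @return data.frame, rows = methods, columns = variables.
#' @export
correlation_table <- function(results, component = 1L) {
  rows <- lapply(results, function(r) r$correlations[, component])
  df <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  rownames(df) <- paste0(names(results), "-PC", component)
  df
}

#' Vertex distance table (one phi value per method)
#'
#' @param results a named list of [run_method()] results.
#' @return named numeric vector of [phi()] values at each method's fit.
#' @export
distance_table <- function(results) {
  vapply(results, function(r) r$phi, numeric(1))
}

#' Principal-plane plot of interval scores
#'
#' Draws each case as the axis-aligned rectangle spanned by its score
#' intervals on two components, labelled at the rectangle center.
#'
#' @param result a [run_method()] result (or an [interval_scores()] object).
#' @param components length-2 integer vector of component indices.
#' @param path optional output file (`.png`, `.svg`, `.pdf`); written with
#'   fixed 7 x 7 inch size for deterministic layout.
#' @return the ggplot object, invisibly if `path` is given.
#' @export
plot_principal_plane <- function(result, components = c(1L, 2L), path = NULL) {
  sc <- if (inherits(result, "ipca_method")) result$scores else result
  stopifnot(inherits(sc, "interval_scores"))
  k1 <- components[1L]; k2 <- components[2L]
  df <- data.frame(case = sc$case_labels,
                   xmin = sc$lo[, k1], xmax = sc$hi[, k1],
                   ymin = sc$lo[, k2], ymax = sc$hi[, k2])
  df$x <- (df$xmin + df$xmax) / 2
  df$y <- (df$ymin + df$ymax) / 2
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       fill = NA, colour = "steelblue", linewidth = 0.4) +
    ggplot2::geom_text(ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$case), size = 2.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = sprintf("PC%d", k1), y = sprintf("PC%d", k2)) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 7, height = 7, dpi = 150)
    return(invisible(p))
  }
  p
}
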