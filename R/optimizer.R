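#' Best Point optimizer configuration
#'
#' @param tol convergence tolerance on the change of the objective between
#'   iterations.
#' @param max_iter maximum number of optimizer iterations (quasi-Newton
#'   iterations, or full coordinate sweeps for the fallback method).
#' @param seed integer seed for the random extra starts (unused when
#'   `n_starts = 1`).
#' @param n_starts number of starts: the first is always the center matrix;
#'   additional starts are seeded random corner matrices of the box.  The
#'   best final objective wins, ties broken by start index.
#' @param method `"projected-quasi-newton"` (box-constrained L-BFGS-B with
#'   finite-difference gradients, the default) or `"coordinate-descent"`
#'   (cyclic golden-section line searches, slower but robust near eigenvalue
#'   crossings).
#' @return a list of class `bp_config`.
#' @export
bp_config <- function(tol = 1e-8, max_iter = 500L, seed = 20191019L,
                      n_starts = 1L,
                      method = c("projected-quasi-newton", "coordinate-descent")) {
  method <- match.arg(method)
  stopifnot(tol > 0, max_iter >= 1L, n_starts >= 1L)
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), n_starts = as.integer(n_starts),
                 method = method),
            class = "bp_config")
}

# One optimization run over t in [0,1]^n_free from a given start.
# 'fn' minimizes; returns list(t, value, trace, converged, iterations).
run_box_opt <- function(fn, t0, cfg) {
  evals <- numeric(0)
  wrapped <- function(t) {
    v <- fn(t)
    evals[[length(evals) + 1L]] <<- v
    v
  }
  if (cfg$method == "projected-quasi-newton") {
    res <- stats::optim(t0, wrapped, method = "L-BFGS-B", lower = 0, upper = 1,
                        control = list(maxit = cfg$max_iter,
                                       factr = cfg$tol / .Machine$double.eps))
    list(t = res$par, value = res$value, trace = cummin(evals),
         converged = res$convergence == 0L,
         iterations = unname(res$counts[1L]))
  } else {
    t <- t0
    f <- wrapped(t)
    sweeps <- 0L
    converged <- FALSE
    while (sweeps < cfg$max_iter) {
      f_before <- f
      for (j in seq_along(t)) {
        f1d <- function(tj) { tt <- t; tt[j] <- tj; wrapped(tt) }
        opt <- stats::optimize(f1d, c(0, 1), tol = 1e-6)
        if (opt$objective < f) { t[j] <- opt$minimum; f <- opt$objective }
      }
      sweeps <- sweeps + 1L
      if (f_before - f < cfg$tol) { converged <- TRUE; break }
    }
    list(t = t, value = f, trace = cummin(evals),
         converged = converged, iterations = sweeps)
  }
}

# Shared driver for both criteria.  'objective' maps Z -> value to MINIMIZE;
# 'natural' converts a minimized value to the reported scale.
optimize_box <- function(X, s, cfg, objective, criterion, natural = identity) {
  stopifnot(inherits(X, "interval_matrix"), inherits(cfg, "bp_config"))
  m <- ncol(X$lower)
  if (s < 1L || s > m) stop("'s' must be between 1 and m")
  wid <- interval_widths(X)
  free <- wid > 0
  Zc <- center_matrix(X)
  make_Z <- function(t) {
    Z <- X$lower
    # clamp: a + t*(b-a) can overshoot b by one ulp at t = 1
    Z[free] <- pmin(pmax(X$lower[free] + t * wid[free], X$lower[free]), X$upper[free])
    Z
  }
  # degenerate-column iterates are rejected through a large finite penalty
  fn <- function(t) {
    Z <- make_Z(t)
    v <- tryCatch(objective(Z), error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  f_center <- objective(Zc)   # errors here (e.g. constant column) are real

  if (!any(free)) {           # the box is a single point
    return(structure(list(Z_opt = Zc, objective = natural(f_center),
                          objective_trace = natural(f_center),
                          converged = TRUE, iterations = 0L,
                          criterion = criterion, s = as.integer(s),
                          start_index = 1L, cfg = cfg),
                     class = "best_point"))
  }

  n_free <- sum(free)
  starts <- vector("list", cfg$n_starts)
  starts[[1L]] <- rep(0.5, n_free)
  if (cfg$n_starts > 1L) {
    for (r in 2:cfg$n_starts) {
      set.seed(cfg$seed + r)
      starts[[r]] <- sample(c(0, 1), n_free, replace = TRUE)
    }
  }
  best <- NULL
  for (r in seq_len(cfg$n_starts)) {
    run <- run_box_opt(fn, starts[[r]], cfg)
    if (is.null(best) || run$value < best$value) { best <- run; best$start <- r }
  }
  # monotone improvement from the mandated center start, exactly
  if (best$value <= f_center) {
    Z_opt <- make_Z(best$t); f_opt <- best$value
  } else {
    Z_opt <- Zc; f_opt <- f_center
  }
  structure(list(Z_opt = Z_opt, objective = natural(f_opt),
                 objective_trace = natural(best$trace),
                 converged = best$converged, iterations = best$iterations,
                 criterion = criterion, s = as.integer(s),
                 start_index = best$start, cfg = cfg),
            class = "best_point")
}

#' @export
print.best_point <- function(x, ...) {
  cat(sprintf("Best Point (%s criterion, s = %d): objective %.6g after %d iterations%s\n",
              x$criterion, x$s, x$objective, x$iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Best Point with respect to vertex distance
#'
#' Searches the interval box for the realization matrix whose principal
#' subspace minimizes the vertex-to-subspace squared distance [phi()].  The
#' box is reparameterized as `Z = a + t * (b - a)` with `t` in the unit
#' hypercube (degenerate entries are fixed), the center matrix (`t = 1/2`)
#' is the mandated first start, and the final result is never worse than the
#' center start: `phi(Z_opt) <= phi(center)` holds exactly.
#'
#' @param X an [interval_matrix].
#' @param s number of retained components; default `min(2, m)`.
#' @param cfg a [bp_config()].
#' @return An object of class `best_point`: list with `Z_opt`, `objective`
#'   (the phi value at `Z_opt`), `objective_trace` (incumbent value per
#'   objective evaluation, weakly decreasing), `converged`, `iterations`,
#'   `criterion`, `s`, `start_index` and `cfg`.
#' @export
optimize_distance <- function(X, s = NULL, cfg = bp_config()) {
  m <- ncol(X$lower)
  if (is.null(s)) s <- min(2L, m)
  vrows <- vertex_matrix(X)$rows    # enumerate once, reuse per evaluation
  obj <- function(Z) phi_model(X, fit_pca(Z, s = s), s, vrows = vrows)
  optimize_box(X, s, cfg, obj, criterion = "distance")
}

#' Best Point with respect to retained inertia
#'
#' Searches the interval box for the realization matrix maximizing the
#' inertia retained by the first `s` components, [lambda_sum()].  Same
#' search scheme as [optimize_distance()]; internally minimizes the negated
#' criterion, so the reported `objective` and `objective_trace` are on the
#' Lambda scale and weakly increasing, with
#' `lambda_sum(Z_opt) >= lambda_sum(center)` exact.
#'
#' @inheritParams optimize_distance
#' @return a `best_point` object (`objective` is the retained inertia).
#' @export
optimize_variance <- function(X, s = NULL, cfg = bp_config()) {
  m <- ncol(X$lower)
  if (is.null(s)) s <- min(2L, m)
  obj <- function(Z) -sum(fit_pca(Z, s = s)$eigvals[seq_len(s)])
  optimize_box(X, s, cfg, obj, criterion = "variance", natural = function(v) -v)
}
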