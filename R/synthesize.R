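#' Generate a random interval matrix
#'
#' Draws interval centers from a correlated Gaussian model with a planted
#' two-factor loading structure (so that synthetic data have a meaningful
#' low-dimensional principal subspace, like the morphometric data the
#' package targets) and half-widths from a folded Gaussian.  The interval for
#' case i, variable j is `[c_ij - w_ij, c_ij + w_ij]`.
#'
#' @param n,m number of cases and variables.
#' @param center_spec list with `n_factors` (default 2), `factor_sd` (default
#'   1), `noise_sd` (default 0.3): centers are `F L' + E` with standard-normal
#'   factor scores `F` (n x n_factors), loadings `L` (m x n_factors) drawn
#'   once from N(0, factor_sd^2), and N(0, noise_sd^2) noise.
#' @param width_spec list with `sd` (default 0.5): half-widths are
#'   `|N(0, sd^2)|`; `sd = 0` gives fully degenerate (point) intervals.
#' @param seed integer seed; the draw is reproducible given the seed.
#' @return an [interval_matrix].
#' @examples
#' X <- synthesize_interval_matrix(5, 3, seed = 1)
#' @export
synthesize_interval_matrix <- function(n, m,
                                       center_spec = list(),
                                       width_spec = list(),
                                       seed = 1L) {
  cs <- utils::modifyList(list(n_factors = 2L, factor_sd = 1, noise_sd = 0.3),
                          center_spec)
  ws <- utils::modifyList(list(sd = 0.5), width_spec)
  if (cs$factor_sd < 0 || cs$noise_sd < 0 || ws$sd < 0)
    stop("distribution scale parameters must be nonnegative")
  if (cs$n_factors < 1L) stop("'n_factors' must be at least 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  L <- matrix(stats::rnorm(m * cs$n_factors, sd = cs$factor_sd), m, cs$n_factors)
  F <- matrix(stats::rnorm(n * cs$n_factors), n, cs$n_factors)
  centers <- F %*% t(L) + matrix(stats::rnorm(n * m, sd = cs$noise_sd), n, m)
  halfw <- abs(matrix(stats::rnorm(n * m, sd = ws$sd), n, m))
  interval_matrix(centers - halfw, centers + halfw)
}
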