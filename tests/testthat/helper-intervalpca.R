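# random small interval matrix with dimensions drawn from the seed
rand_interval <- function(seed, n_max = 6L, m_max = 8L) {
  set.seed(seed)
  n <- sample(2:n_max, 1L)
  m <- sample(1:m_max, 1L)
  synthesize_interval_matrix(n, m, seed = seed + 1000L)
}

# hand-built PCA model with prescribed loadings and column statistics,
# for checking projection formulas against enumerable cases
manual_model <- function(W, mean, sd, n) {
  W <- as.matrix(W)
  structure(list(stats = structure(list(mean = mean, sd = sd, n = n),
                                   class = "column_stats"),
                 eigvals = rep(NA_real_, ncol(W)), eigvecs = W,
                 scores = NULL, s = ncol(W)),
            class = "ipca_model")
}

# a random realization drawn uniformly inside the interval box
rand_realization <- function(X) {
  wid <- interval_widths(X)
  X$lower + matrix(stats::runif(length(wid)), nrow(wid)) * wid
}
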