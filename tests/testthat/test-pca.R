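test_that("correlation PCA has unit-trace-per-variable spectrum and orthonormal basis", {
  set.seed(11)
  Z <- matrix(rnorm(60), 12, 5)
  fit <- fit_pca(Z)
  expect_equal(sum(fit$eigvals), 5, tolerance = 1e-10)
  expect_true(all(diff(fit$eigvals) <= 1e-12))
  expect_lt(max(abs(crossprod(fit$eigvecs) - diag(5))), 1e-8)
  # perfectly correlated duplicate columns concentrate all inertia
  Z2 <- cbind(rnorm(10), 0)
  Z2[, 2] <- 2 * Z2[, 1] + 1
  expect_equal(fit_pca(Z2)$eigvals, c(2, 0), tolerance = 1e-10)
})

test_that("sign convention is deterministic and idempotent", {
  set.seed(12)
  Z <- matrix(rnorm(48), 8, 6)
  W <- fit_pca(Z)$eigvecs
  for (k in 1:6) expect_gte(W[which.max(abs(W[, k])), k], 0)
  expect_identical(intervalpca:::fix_signs(W), W)
  expect_identical(fit_pca(Z)$eigvecs, W)
})

test_that("scores reconstruct the z-scored data and agree with supplementary projection", {
  set.seed(13)
  Z <- matrix(rnorm(40), 10, 4)
  fit <- fit_pca(Z, s = 4)
  Zs <- sweep(sweep(Z, 2, fit$stats$mean), 2, fit$stats$sd, "/")
  expect_lt(max(abs(fit$scores %*% t(fit$eigvecs) - Zs)), 1e-8)
  expect_lt(max(abs(project_supplementary(Zs, fit) - fit$scores)), 1e-10)
  expect_equal(unname(project_supplementary(matrix(0, 1, 4), fit)),
               matrix(0, 1, 4))
})

test_that("supplementary projection equals direct dot products on a vertex row", {
  faces <- faces_dataset()
  fit <- fit_pca(center_matrix(faces))
  row <- vertex_matrix(faces)$rows[100, , drop = FALSE]
  rs <- sweep(sweep(row, 2, fit$stats$mean), 2, fit$stats$sd, "/")
  direct <- vapply(1:6, function(k) sum(rs * fit$eigvecs[, k]), numeric(1))
  expect_lt(max(abs(project_supplementary(rs, fit) - direct)), 1e-12)
})

test_that("row- and column-side eigenproblems share eigenvalues and eigenvectors map to each other", {
  set.seed(14)
  Z <- matrix(rnorm(15), 5, 3)
  fit <- fit_pca(Z, s = 3)
  dual <- dual_components(fit, Z, s = 3)
  Zt <- standardize_wrt(Z, fit$stats)
  gram_vals <- eigen(tcrossprod(Zt), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(sort(gram_vals, decreasing = TRUE)[1:3] - fit$eigvals)), 1e-8)
  # both duality identities hold simultaneously, and a round trip returns v
  for (l in 1:3) {
    expect_lt(max(abs(dual$u[, l] - crossprod(Zt, dual$v[, l]) / sqrt(dual$eigvals[l]))), 1e-8)
    expect_lt(max(abs(dual$v[, l] - Zt %*% dual$u[, l] / sqrt(dual$eigvals[l]))), 1e-8)
  }
  expect_lt(max(abs(crossprod(dual$v) - diag(3))), 1e-8)
  expect_lt(max(abs(dual$u - fit$eigvecs[, 1:3])), 1e-8)
})

test_that("dual coordinates are the variable-component correlations of the fitted matrix", {
  set.seed(15)
  Z <- matrix(rnorm(36), 12, 3)
  fit <- fit_pca(Z, s = 3)
  dual <- dual_components(fit, Z, s = 3)
  r <- dual_scores(standardize_wrt(Z, fit$stats), dual$v)
  expect_equal(unname(r), unname(cor(Z, fit$scores[, 1:3])), tolerance = 1e-8)
})

test_that("degenerate requests are refused", {
  Z2 <- cbind(rnorm(10), 0)
  Z2[, 2] <- 3 * Z2[, 1]
  fit <- fit_pca(Z2)
  expect_error(dual_components(fit, Z2, s = 2), "zero eigenvalue")
  expect_error(fit_pca(cbind(rnorm(5), 1)), "constant")
  expect_error(fit_pca(matrix(rnorm(10), 5, 2), s = 3), "between 1 and m")
})

test_that("anchoring flips the requested component signs only", {
  faces <- faces_dataset()
  fit <- fit_pca(center_matrix(faces), s = 2)
  anc <- anchor_signs(fit, c("X4", "X3"))
  expect_gte(anc$eigvecs["X4", 1], 0)
  expect_gte(anc$eigvecs["X3", 2], 0)
  expect_lt(max(abs(abs(anc$eigvecs) - abs(fit$eigvecs))), 1e-14)
  expect_identical(anchor_signs(anc, c("X4", "X3")), anc)
  expect_error(anchor_signs(fit, "nope"), "not found")
})
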