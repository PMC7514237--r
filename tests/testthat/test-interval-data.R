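test_that("interval matrix construction validates bounds and shape", {
  expect_error(interval_matrix(rbind(c(1, 3), c(2, 2)), rbind(c(3, 1), c(2, 5))),
               "lower bound exceeds upper bound at row 1, column 2")
  expect_error(interval_matrix(matrix(1, 1, 2), matrix(2, 1, 2)), "at least 2 cases")
  expect_error(interval_matrix(matrix(c(1, NA), 2, 1), matrix(2, 2, 1)), "finite")
  X <- interval_matrix(rbind(c(1, 0), c(2, 2)), rbind(c(3, 1), c(2, 5)))
  expect_equal(dim(X), c(2L, 2L))
  expect_equal(X$var_names, c("X1", "X2"))
})

test_that("center matrix is the interval midpoint and lies in the box", {
  X <- interval_matrix(rbind(c(1, 5), c(0, 5)), rbind(c(3, 5), c(4, 5)))
  Z <- center_matrix(X)
  expect_equal(unname(Z), rbind(c(2, 5), c(2, 5)))
  expect_true(in_box(X, Z))
  faces <- faces_dataset()
  expect_equal(center_matrix(faces)["FRA1", "X1"], 156.00)
})

test_that("vertex matrix enumerates corners in binary-counting order", {
  X <- interval_matrix(rbind(c(0, 0), c(9, 9)), rbind(c(1, 1), c(9, 9)))
  vm <- vertex_matrix(X)
  expect_equal(unname(vm$rows[1:4, ]),
               rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
  expect_equal(vm$N, 5L)                  # 2^2 + 2^0
  expect_equal(vm$m_i, c(2, 0), ignore_attr = TRUE)
  expect_equal(vm$case_of_row, c(1L, 1L, 1L, 1L, 2L))

  # degenerate column contributes its single value, no duplicated rows
  X2 <- interval_matrix(rbind(c(2, 0), c(5, 5)), rbind(c(2, 1), c(6, 7)))
  vm2 <- vertex_matrix(X2)
  expect_equal(unname(vm2$rows[vm2$case_of_row == 1L, ]), rbind(c(2, 0), c(2, 1)))
  expect_equal(vm2$m_i[1], 1, ignore_attr = TRUE)
})

test_that("vertex row count is sum of 2^m_i and rows use only the bounds", {
  for (seed in 1:8) {
    X <- rand_interval(seed)
    if (seed %% 2 == 0) X$upper[1, 1] <- X$lower[1, 1]   # force a degenerate cell
    vm <- vertex_matrix(X)
    expect_equal(vm$N, sum(2^vm$m_i))
    for (r in seq_len(vm$N)) {
      i <- vm$case_of_row[r]
      expect_true(all(vm$rows[r, ] == X$lower[i, ] | vm$rows[r, ] == X$upper[i, ]))
    }
  }
  expect_equal(vertex_matrix(faces_dataset())$N, 27L * 2L^6L)
})

test_that("standardizing a matrix by its own stats gives mean 0, sum sq 1", {
  set.seed(4)
  Z <- matrix(rnorm(35, sd = 3), 7, 5)
  S <- standardize_wrt(Z, column_stats(Z))
  expect_lt(max(abs(colMeans(S))), 1e-10)
  expect_lt(max(abs(colSums(S^2) - 1)), 1e-10)
})

test_that("standardization formula and interval handling are as documented", {
  st <- structure(list(mean = 0, sd = 1, n = 4), class = "column_stats")
  expect_equal(standardize_wrt(matrix(2), st), matrix(1))
  st1 <- structure(list(mean = 2, sd = 1, n = 1), class = "column_stats")
  Xi <- interval_matrix(matrix(c(1, 1), 2, 1), matrix(c(3, 3), 2, 1))
  Xs <- standardize_wrt(Xi, st1)
  expect_equal(unname(Xs$lower[1, 1]), -1)
  expect_equal(unname(Xs$upper[1, 1]), 1)
  Zc <- matrix(c(1, 1, 2, 3), 2, 2)
  expect_error(column_stats(Zc), "constant")
})

test_that("interval CSV round-trips losslessly in both dialects", {
  X <- synthesize_interval_matrix(9, 4, seed = 7)
  for (d in c("bracket", "paired")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_interval_csv(X, f, dialect = d)
    Y <- read_interval_csv(f, dialect = d)
    expect_equal(Y$lower, X$lower)
    expect_equal(Y$upper, X$upper)
    expect_equal(Y$case_labels, X$case_labels)
  }
})

test_that("interval CSV reader reports malformed input with positions", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("case,A", "c1,\"[1,2]\"", "c2,\"[3,1]\""), f)
  expect_error(read_interval_csv(f, "bracket"), "row 2, column 'A'")
  writeLines(c("case,A", "c1,\"[1;2]\"", "c2,\"[0,1]\""), f)
  expect_error(read_interval_csv(f, "bracket"), "malformed")
  writeLines(c("case,A.lo,A.hi", "c1,1,2", "c2,x,4"), f)
  expect_error(read_interval_csv(f, "paired"), "non-numeric")
  writeLines(c("case,A.lo,B.hi", "c1,1,2", "c2,3,4"), f)
  expect_error(read_interval_csv(f, "paired"), "matching")
})

test_that("faces dataset matches its published measurements", {
  faces <- faces_dataset()
  expect_equal(dim(faces), c(27L, 6L))
  expect_equal(unname(faces$lower["HUS1", "X1"]), 168.9)
  expect_equal(unname(faces$upper["HUS1", "X1"]), 172.84)
  expect_equal(unname(faces$lower["ROM3", "X6"]), 50.99)
  expect_equal(unname(faces$upper["ROM3", "X6"]), 60.46)
  expect_equal(unname(faces$lower["FRA2", "X1"]), 154.00)
  expect_equal(unname(faces$upper["FRA2", "X1"]), 160.01)
})

test_that("synthetic generator is seeded, valid, and honours zero widths", {
  A <- synthesize_interval_matrix(27, 6, seed = 1)
  B <- synthesize_interval_matrix(27, 6, seed = 1)
  expect_identical(A, B)
  expect_true(all(A$lower <= A$upper))
  expect_false(identical(A, synthesize_interval_matrix(27, 6, seed = 2)))
  D <- synthesize_interval_matrix(5, 3, width_spec = list(sd = 0), seed = 3)
  expect_true(all(D$lower == D$upper))
  expect_equal(vertex_matrix(D)$N, 5L)
  expect_error(synthesize_interval_matrix(5, 3, width_spec = list(sd = -1)),
               "nonnegative")
})
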