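test_that("pair kernel equals the brute-force loop oracle", {
  withr::local_seed(21)
  x <- matrix(rnorm(8 * 4), 8)            # 8 genes x 4 time points
  y <- array(rnorm(10 * 4 * 2), c(10, 4, 2))
  k <- build_pair_kernel(x, y)
  expect_equal(dim(k), c(4L, 2L, 4L, 2L))
  expect_equal(as_vector_plain(k), as.vector(pair_kernel_oracle(x, y)),
               tolerance = 1e-10)

  # single gene / single region stays exact
  k1 <- build_pair_kernel(matrix(1:4, 1), array(1:8, c(1, 4, 2)))
  expect_equal(as_vector_plain(k1),
               as.vector(pair_kernel_oracle(matrix(1:4, 1),
                                            array(1:8, c(1, 4, 2)))))
})

test_that("pair kernel is bilinear and flags shape mismatches", {
  withr::local_seed(22)
  x <- matrix(rnorm(12), 3)
  y <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  k <- build_pair_kernel(x, y)
  expect_equal(as_vector_plain(build_pair_kernel(2 * x, y)),
               4 * as_vector_plain(k), tolerance = 1e-10)
  expect_equal(as_vector_plain(build_pair_kernel(x, 3 * y)),
               9 * as_vector_plain(k), tolerance = 1e-10)
  expect_equal(max(abs(build_pair_kernel(x * 0, y))), 0)
  expect_error(build_pair_kernel(matrix(rnorm(9), 3),
                                 array(rnorm(40), c(5, 4, 2))),
               "time-mode")
})

test_that("dual kernel equals the loop oracle in both variants", {
  withr::local_seed(23)
  a <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  b <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  k <- build_dual_kernel(a, b)
  expect_equal(dim(k), c(4L, 2L, 2L, 4L, 2L, 2L))
  expect_equal(as_vector_plain(k), as.vector(dual_kernel_oracle(a, b)),
               tolerance = 1e-10)
  ks <- build_dual_kernel(a, b, strict_as_printed = TRUE)
  expect_equal(as_vector_plain(ks),
               as.vector(dual_kernel_oracle(a, b, strict = TRUE)),
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(as_vector_plain(k), as_vector_plain(ks))))

  # N = 1 toy with integer entries
  a1 <- array(1:8, c(1, 4, 2))
  b1 <- array(8:1, c(1, 4, 2))
  expect_equal(as_vector_plain(build_dual_kernel(a1, b1)),
               as.vector(dual_kernel_oracle(a1, b1)))
  expect_equal(max(abs(build_dual_kernel(a * 0, b * 0))), 0)
  expect_error(build_dual_kernel(a, array(rnorm(24), c(3, 4, 2))),
               "share feature count")
})

test_that("swapping the dual kernel's data sets relabels its modes", {
  withr::local_seed(24)
  a <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  b <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  kab <- as_plain(build_dual_kernel(a, b))
  kba <- as_plain(build_dual_kernel(b, a))
  # exchanging the data sets exchanges the primed/unprimed mode groups;
  # the k2/k'2 contraction-side conditions swap within each group
  expect_equal(aperm(kba, c(4, 6, 5, 1, 3, 2)), kab, tolerance = 1e-10)
})

test_that("feature back-projections match direct summation and basis cases", {
  withr::local_seed(25)
  x <- matrix(rnorm(5 * 4), 5)
  y <- array(rnorm(7 * 4 * 2), c(7, 4, 2))
  kern <- build_pair_kernel(x, y)
  h <- hosvd(kern)

  s <- project_matrix_features(h, 2, x)
  expect_equal(s, drop(x %*% h$factors[[1]][, 2]), tolerance = 1e-12)
  expect_equal(project_matrix_features(h, 1, x * 0), rep(0, 5))

  s2 <- project_tensor_features(h, 2, 1, y)
  direct <- numeric(7)
  for (j in 1:2) for (t in 1:4) {
    direct <- direct + h$factors[[2]][j, 2] * h$factors[[3]][t, 1] * y[, t, j]
  }
  expect_equal(s2, direct, tolerance = 1e-12)

  # with basis factors the projection extracts a slice
  h_basis <- h
  h_basis$factors[[2]] <- diag(2)
  h_basis$factors[[3]] <- diag(4)
  expect_equal(project_tensor_features(h_basis, 2, 3, y), y[, 3, 2])

  a <- array(rnorm(6 * 4 * 2), c(6, 4, 2))
  b <- array(rnorm(6 * 4 * 2), c(6, 4, 2))
  hd <- hosvd(build_dual_kernel(a, b))
  sa <- project_dual_features(hd, 1, 2, a, side = "first")
  directa <- numeric(6)
  for (j in 1:4) for (k in 1:2) {
    directa <- directa + a[, j, k] * hd$factors[[1]][j, 1] * hd$factors[[2]][k, 2]
  }
  expect_equal(sa, directa, tolerance = 1e-12)
  sb <- project_dual_features(hd, 2, 1, b, side = "second")
  directb <- numeric(6)
  for (j in 1:4) for (k in 1:2) {
    directb <- directb + b[, j, k] * hd$factors[[4]][j, 2] * hd$factors[[5]][k, 1]
  }
  expect_equal(sb, directb, tolerance = 1e-12)

  # projections are linear in the data
  expect_equal(project_dual_features(hd, 1, 1, 5 * a, side = "first"),
               5 * project_dual_features(hd, 1, 1, a, side = "first"),
               tolerance = 1e-12)
  expect_error(project_matrix_features(h, 9, x), "out of range")
})

test_that("condition-swap asymmetry is zero for symmetric kernels", {
  withr::local_seed(26)
  k <- array(rnorm(64), c(4, 2, 4, 2))
  sym <- (k + aperm(k, c(1, 4, 3, 2))) / 2
  expect_equal(kernel_condition_asymmetry(sym), 0, tolerance = 1e-12)
  expect_gt(kernel_condition_asymmetry(k), 0)
})
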