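test_that("gram PCA reproduces hand-computed small cases", {
  p1 <- pca_gram(diag(2))
  expect_equal(p1$eigenvalues, c(1, 1))

  x <- matrix(c(1, 2, 2, 4), 2)  # rank 1, gram [[5,10],[10,20]]
  p2 <- pca_gram(x)
  expect_equal(p2$eigenvalues, c(25, 0))
  expect_equal(p2$scores[, 1], c(1, 2) / sqrt(5))
  expect_equal(p2$loadings[, 1], c(sqrt(5), 2 * sqrt(5)))
})

test_that("PCA eigenvalues sum to the squared Frobenius norm and scores are
           orthonormal with loadings X^T u", {
  withr::local_seed(1)
  for (rep in 1:5) {
    x <- matrix(rnorm(40 * 4), 40)
    p <- pca_gram(x)
    expect_equal(sum(p$eigenvalues), sum(x^2), tolerance = 1e-6)
    expect_equal(crossprod(p$scores), diag(4), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(p$loadings, crossprod(x, p$scores), tolerance = 1e-8)
  }
})

test_that("gram PCA agrees with a dense eigendecomposition of XX^T", {
  withr::local_seed(2)
  x <- matrix(rnorm(30 * 4), 30)
  p <- pca_gram(x)
  e <- eigen(tcrossprod(x), symmetric = TRUE)
  expect_equal(p$eigenvalues, e$values[1:4], tolerance = 1e-8)
  for (l in 1:4) {
    expect_equal(abs(p$scores[, l]), abs(e$vectors[, l]), tolerance = 1e-7)
  }
})

test_that("PCA rejects degenerate input and supports centering", {
  expect_error(pca_gram(matrix(0, 3, 3)), "degenerate")
  expect_error(pca_gram(matrix(1, 3, 1)), "2 samples")
  x <- matrix(rnorm(20), 5) + 10
  pc <- pca_gram(x, center = TRUE)
  xc <- sweep(x, 2, colMeans(x))
  expect_equal(sum(pc$eigenvalues), sum(xc^2), tolerance = 1e-8)
})

test_that("scores permute identically with feature permutation", {
  withr::local_seed(3)
  x <- matrix(rnorm(20 * 4), 20)
  perm <- sample(20)
  p1 <- pca_gram(x)
  p2 <- pca_gram(x[perm, ])
  for (l in 1:4) {
    expect_equal(abs(p2$scores[, l]), abs(p1$scores[perm, l]),
                 tolerance = 1e-8)
  }
})

test_that("HOSVD of a rank-1 tensor concentrates the core in one entry", {
  a <- c(1, 2, 2) / 3
  b <- c(3, 4) / 5
  cc <- c(1, 1) / sqrt(2)
  x <- outer(outer(a, b), cc)
  h <- hosvd(x)
  g <- h$core
  expect_equal(abs(g[1, 1, 1]), 1, tolerance = 1e-10)
  g[1, 1, 1] <- 0
  expect_lt(max(abs(g)), 1e-10)
  # truncated to ranks (1,1,1) the reconstruction is still exact
  h1 <- hosvd(x, ranks = c(1, 1, 1))
  expect_equal(reconstruct(h1), x, tolerance = 1e-10)
})

test_that("full-rank HOSVD reconstructs exactly with orthonormal factors and
           an all-orthogonal core", {
  withr::local_seed(4)
  for (d in list(c(5, 4, 2), c(50, 4, 2), c(3, 3, 3), c(4, 3, 2, 2))) {
    x <- array(rnorm(prod(d)), d)
    h <- hosvd(x)
    expect_equal(reconstruct(h), x, tolerance = 1e-8)
    for (f in h$factors) {
      expect_equal(crossprod(f), diag(ncol(f)), tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
    # core slices at distinct indices of any mode are orthogonal
    for (m in seq_along(d)) {
      gm <- tensor_unfold(h$core, m)
      gram <- tcrossprod(gm)
      off <- gram - diag(diag(gram), nrow = nrow(gram))
      expect_lt(max(abs(off)) / sqrt(sum(x^2)), 1e-6)
    }
  }
})

test_that("HOSVD reconstruction of a small case matches the nested-sum oracle", {
  withr::local_seed(8)
  x <- array(rnorm(24), c(3, 4, 2))
  h <- hosvd(x)
  expect_equal(reconstruct_oracle_3(h$core, h$factors), x, tolerance = 1e-8)
})

test_that("order-2 HOSVD reproduces the SVD and rank errors are caught", {
  withr::local_seed(5)
  x <- matrix(rnorm(30), 6, 5)
  h <- hosvd(x)
  sv <- svd(x)$d
  core_sv <- sqrt(colSums(tensor_unfold(h$core, 2)^2))
  expect_equal(sort(core_sv, decreasing = TRUE), sv, tolerance = 1e-8)
  expect_error(hosvd(x, ranks = c(7, 2)), "rank exceeds")
})

test_that("truncation error is non-increasing as any rank grows", {
  withr::local_seed(6)
  x <- array(rnorm(5 * 4 * 3), c(5, 4, 3))
  err <- function(r) {
    h <- hosvd(x, ranks = r)
    sqrt(sum((reconstruct(h) - x)^2))
  }
  for (mode in 1:3) {
    ranks <- c(2, 2, 2)
    prev <- err(ranks)
    for (r in 3:dim(x)[mode]) {
      ranks[mode] <- r
      cur <- err(ranks)
      expect_lte(cur, prev + 1e-10)
      prev <- cur
    }
  }
})
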