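test_that("axis ranking orders components by |Pearson r| with the covariate", {
  fm <- cbind(c(0, 6, 12, 24), c(1, -1, 1, -1))
  rk <- rank_axes_by_correlation(fm, c(0, 6, 12, 24))
  expect_equal(rk$component[1], 1)
  expect_equal(rk$r[1], 1)

  fm2 <- cbind(rep(0.5, 4), c(-.67, -.25, .25, .67))
  expect_warning(rk2 <- rank_axes_by_correlation(fm2, c(0, 6, 12, 24)),
                 "zero-variance")
  expect_equal(rk2$component[1], 2)    # monotone outranks constant
  expect_true(is.na(rk2$r[rk2$component == 1]))
  expect_equal(rk2$rank[rk2$component == 1], 2)

  expect_error(rank_axes_by_correlation(fm, c(0, 6)), "one value per")
})

test_that("sign contrast and concordance find the lowest qualifying axis", {
  fm <- cbind(c(.7, .7), c(.7, -.7))
  expect_equal(sign_contrast_axis(fm), 2)
  expect_equal(sign_concordant_axis(fm), 1)
  expect_error(sign_contrast_axis(diag(2)), "no contrast axis")
  fm2 <- cbind(c(.6, .8), c(-.8, .6))  # both columns orthonormal
  expect_equal(sign_contrast_axis(fm2), 2)
  expect_equal(sign_concordant_axis(fm2), 1)
  fm3 <- cbind(c(-.6, .8), c(.8, .6))
  expect_equal(sign_contrast_axis(fm3), 1)  # lowest-index rule
})

test_that("core scan finds the dominant coupled component", {
  g <- array(0, c(3, 2, 2))
  g[2, 2, 2] <- 5
  sc <- scan_core(g, c(NA, 2, 2))
  expect_equal(sc$component, 2)
  expect_equal(sc$profile$core_value, c(0, 5, 0))

  g[1, 2, 2] <- -5  # tie in |G|: smallest index wins
  expect_equal(scan_core(g, c(NA, 2, 2))$component, 1)
  expect_error(scan_core(g, c(NA, 5, 2)), "out of range")
  expect_error(scan_core(g, c(NA, NA, 2)), "exactly one mode")
})

test_that("chi-squared attribution matches the two-sided normal tail and is
           scale- and sign-invariant", {
  withr::local_seed(11)
  u <- rnorm(200)
  p <- chi2_pvalues(u)
  sigma <- attr(p, "sigma")
  expect_equal(as.vector(p), 2 * (1 - pnorm(abs(u) / sigma)),
               tolerance = 1e-12)
  expect_equal(as.vector(chi2_pvalues(3.7 * u)), as.vector(p),
               tolerance = 1e-12)
  expect_equal(as.vector(chi2_pvalues(-u)), as.vector(p), tolerance = 1e-12)

  u0 <- c(0, 1, -1)
  expect_equal(as.vector(chi2_pvalues(u0))[1], 1)
  expect_error(chi2_pvalues(rep(2, 5)), "constant")
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  withr::local_seed(12)
  for (rep in 1:5) {
    p <- runif(sample(3:100, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("selection uses a strict threshold", {
  expect_equal(select_features(c(0.005, 0.01, 0.5), 0.01), c(TRUE, FALSE, FALSE))
  expect_equal(select_features(numeric(0)), logical(0))
  expect_error(select_features(0.5, alpha = 1), "in \\(0, 1\\)")
  adj <- c(0.005, 0.02, 0.04, 0.2)
  expect_gte(sum(select_features(adj, 0.05)), sum(select_features(adj, 0.01)))
})

test_that("a pure-noise matrix yields no selections in nearly all seeds", {
  zero_seeds <- 0
  for (s in 1:10) {
    sel <- withr::with_seed(s, {
      run_pca_workflow(matrix(rnorm(1000 * 4), 1000),
                       covariate = c(0, 6, 12, 24))
    })
    if (sum(sel$selected) == 0) zero_seeds <- zero_seeds + 1
  }
  expect_gte(zero_seeds, 9)
})

test_that("selection tables export as TSV with the expected columns", {
  sel <- feature_selection(c(5, 0.1, -0.2, 0.05), alpha = 0.01,
                           component = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selection(sel, path)
  back <- utils::read.delim(path)
  expect_equal(names(back),
               c("feature_id", "score", "p_value", "p_adjusted", "selected"))
  expect_equal(nrow(back), 4)
  g <- glance(sel)
  expect_equal(g$n_features, 4L)
  expect_equal(g$alpha, 0.01)
})
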