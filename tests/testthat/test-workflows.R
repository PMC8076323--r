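test_that("PCA workflow recovers planted covariate-tracking features", {
  withr::local_seed(51)
  n <- 1000
  covariate <- c(0, 6, 12, 24)
  x <- matrix(rnorm(n * 4, 0, 0.5), n)
  x[1:10, ] <- x[1:10, ] + rep(covariate / 4, each = 10)
  sel <- run_pca_workflow(x, covariate = covariate)
  expect_equal(which(sel$selected), 1:10)
  expect_gt(abs(attr(sel, "axis_r")), 0.9)

  # explicit axis override bypasses the ranking
  sel3 <- run_pca_workflow(x, covariate = covariate, axis = 3)
  expect_equal(attr(sel3, "component"), 3)
})

test_that("TD workflow recovers both branches on an asymmetric planted tensor", {
  withr::local_seed(52)
  fx <- asymmetric_planted_tensor()
  fit <- hosvd(fx$tensor)
  sel_c <- run_td_workflow(fx$tensor, condition = "concordant", fit = fit)
  sel_d <- run_td_workflow(fx$tensor, condition = "discordant", fit = fit)
  expect_equal(which(sel_c$selected), fx$truth_concordant)
  expect_equal(which(sel_d$selected), fx$truth_discordant)
  axes_c <- attr(sel_c, "axes")
  axes_d <- attr(sel_d, "axes")
  expect_false(axes_c[["condition"]] == axes_d[["condition"]])
  # the chosen time axis is strongly time-correlated
  expect_gt(abs(attr(sel_c, "axis_r")), 0.9)

  # feature-axis override is honored
  sel_o <- run_td_workflow(fx$tensor, condition = "concordant", fit = fit,
                           axes = list(feature = 5))
  expect_equal(attr(sel_o, "component"), 5)
})

test_that("KTD dual workflow recovers shared blocks and reports the overlap", {
  withr::local_seed(53)
  fa <- asymmetric_planted_tensor()
  fb <- asymmetric_planted_tensor()
  res <- run_ktd_workflow(fa$tensor, fb$tensor, condition = "concordant")
  expect_equal(which(res$selection_x$selected), fa$truth_concordant)
  expect_equal(which(res$selection_y$selected), fb$truth_concordant)
  expect_true(is.matrix(res$overlap$table))
  expect_equal(res$overlap$table[2, 2], length(fa$truth_concordant))

  res_d <- run_ktd_workflow(fa$tensor, fb$tensor, condition = "discordant")
  expect_equal(which(res_d$selection_x$selected), fa$truth_discordant)
  expect_equal(which(res_d$selection_y$selected), fb$truth_discordant)
})

test_that("KTD pair workflow scores genes and regions from one kernel", {
  withr::local_seed(54)
  n_genes <- 400
  n_regions <- 400
  times <- 1:4
  x <- matrix(rnorm(n_genes * 4, 0, 0.2), n_genes) + 2
  x[1:8, ] <- x[1:8, ] + rep(2 * times, each = 8)
  y <- array(rnorm(n_regions * 4 * 2, 0, 0.2), c(n_regions, 4, 2)) + 2
  # planted regions rise with time in the IP condition only
  y[1:10, , 2] <- y[1:10, , 2] + rep(2 * times, each = 10)
  res <- run_ktd_workflow(x, y)
  expect_equal(nrow(res$selection_x), n_genes)
  expect_equal(nrow(res$selection_y), n_regions)
  expect_true(all(1:8 %in% which(res$selection_x$selected)))
  expect_true(all(1:10 %in% which(res$selection_y$selected)))
  expect_gte(res$condition_asymmetry, 0)
  expect_null(res$overlap)
})

test_that("workflows are deterministic given identical inputs", {
  withr::local_seed(55)
  fx <- asymmetric_planted_tensor()
  a <- run_td_workflow(fx$tensor, condition = "concordant")
  b <- run_td_workflow(fx$tensor, condition = "concordant")
  expect_identical(a$p_value, b$p_value)
  expect_identical(attr(a, "axes"), attr(b, "axes"))
})

test_that("benchmark runner aggregates per-seed recovery and overlap tables", {
  bm <- run_benchmark(seeds = 1:2)
  expect_s3_class(bm$results, "tbl_df")
  # 2 TD branches + 4 KTD selections + 1 regression row per seed
  expect_equal(nrow(bm$results), 2 * 7)
  expect_true(all(c("true_neg", "false_pos", "false_neg", "true_pos",
                    "exact") %in% names(bm$results)))
  expect_equal(nrow(bm$overlap), 2)
  reg <- bm$results[bm$results$analysis == "regression_set1", ]
  expect_true(all(reg$n_selected == 0))

  path <- withr::local_tempfile(fileext = ".md")
  write_benchmark_report(bm, path)
  expect_true(any(grepl("Cross-data-set overlap", readLines(path))))
})
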