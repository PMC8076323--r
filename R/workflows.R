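#' PCA-based unsupervised feature extraction
#'
#' End-to-end workflow for a features-by-samples matrix: gram-matrix PCA,
#' automatic choice of the sample-side loading most correlated (in
#' absolute value) with the covariate, chi-squared P-value attribution to
#' the matching score vector, Benjamini-Hochberg adjustment and strict
#' thresholding.
#'
#' @param x Features-by-samples matrix or [omics_matrix()].
#' @param covariate Numeric per-sample covariate (e.g. hours); defaults
#'   to the matrix's covariate attribute, else `1..n_samples`.
#' @param alpha Adjusted-P threshold (default 0.01).
#' @param center Passed to [pca_gram()].
#' @param axis Optional explicit component index, bypassing the
#'   correlation ranking.
#' @return An `fe_selection` tibble; attributes `component` (the chosen
#'   axis), `axis_r` (its Pearson correlation with the covariate) and
#'   `ranking` (the full correlation table).
#' @export
run_pca_workflow <- function(x, covariate = NULL, alpha = 0.01,
                             center = FALSE, axis = NULL) {
  fit <- pca_gram(x, center = center)
  covariate <- covariate %||% fit$covariate %||% seq_along(fit$sample_labels)
  ranking <- rank_axes_by_correlation(fit$loadings, covariate)
  component <- axis %||% ranking$component[1]
  sel <- feature_selection(fit$scores[, component], alpha = alpha,
                           feature_ids = fit$feature_ids,
                           component = component)
  attr(sel, "axis_r") <- ranking$r[match(component, ranking$component)]
  attr(sel, "ranking") <- ranking
  sel
}

#' TD-based unsupervised feature extraction
#'
#' End-to-end workflow for a feature x time x condition tensor: HOSVD,
#' automatic choice of the time axis (largest |Pearson r| with the
#' covariate) and of the condition axis (sign-concordant column for the
#' `"concordant"` branch, sign-contrasting column for `"discordant"`),
#' core-tensor scan for the feature-mode component most strongly coupled
#' to that pair, then chi-squared / BH / threshold selection on the
#' matching feature factor.
#'
#' @param x 3-way array or [omics_tensor()], feature mode first.
#' @param covariate Numeric covariate over the time mode; defaults to
#'   `1..n_time`.
#' @param alpha Adjusted-P threshold (default 0.01).
#' @param condition `"concordant"` (condition-independent signal) or
#'   `"discordant"` (condition-flipped signal).
#' @param axes Optional named list overriding automatic choices: any of
#'   `time`, `condition`, `feature`.
#' @param fit Optional precomputed [hosvd()] of `x` (reused across the
#'   two branches).
#' @return An `fe_selection` tibble; attribute `axes` records the chosen
#'   `(feature, time, condition)` components, `core_scan` the scan.
#' @export
run_td_workflow <- function(x, covariate = NULL, alpha = 0.01,
                            condition = c("concordant", "discordant"),
                            axes = list(), fit = NULL) {
  condition <- match.arg(condition)
  h <- fit %||% hosvd(x)
  n_time <- h$dims[2]
  covariate <- covariate %||% seq_len(n_time)
  ranking <- rank_axes_by_correlation(h$factors[[2]], covariate)
  time_axis <- axes$time %||% ranking$component[1]
  condition_axis <- axes$condition %||% switch(condition,
    concordant = sign_concordant_axis(h$factors[[3]]),
    discordant = sign_contrast_axis(h$factors[[3]])
  )
  fixed <- c(NA, time_axis, condition_axis)
  scan <- scan_core(h, fixed)
  feature_axis <- axes$feature %||% scan$component
  ids <- (attr(x, "mode_labels") %||% list(NULL))[[1]]
  sel <- feature_selection(h$factors[[1]][, feature_axis], alpha = alpha,
                           feature_ids = if (is.null(ids)) NULL
                                         else as.character(ids),
                           component = feature_axis)
  attr(sel, "axes") <- c(feature = feature_axis, time = time_axis,
                         condition = condition_axis)
  attr(sel, "axis_r") <- ranking$r[match(time_axis, ranking$component)]
  attr(sel, "core_scan") <- scan
  sel
}

#' Kernel-TD unsupervised feature extraction (integration of two layers)
#'
#' Integrates two data sets through a sample-space kernel tensor,
#' decomposes it by HOSVD, back-projects the chosen sample-mode factors
#' onto each data set's features, and selects features per data set by
#' chi-squared / BH / threshold.
#'
#' Two input shapes are supported:
#' * matrix + 3-way tensor (e.g. expression and binned m6A coverage
#'   sharing time points): the 4-mode pair kernel; features of the matrix
#'   are scored with the mode-1 time factor, regions of the tensor with
#'   the mode-2 condition and mode-3 time factors;
#' * two feature-matched 3-way tensors: the 6-mode dual kernel; each
#'   side is scored with its own (time, condition) factor pair, and the
#'   overlap of the two selections is cross-tabulated with Fisher
#'   statistics.
#'
#' Time-like axes are chosen by largest |Pearson r| against the
#' covariate; condition axes by sign concordance/contrast according to
#' `condition`.
#'
#' @param x Matrix (pair case) or 3-way array (dual case).
#' @param y 3-way array.
#' @param covariate Numeric covariate over time (default `1..n_time`).
#' @param alpha Adjusted-P threshold (default 0.01).
#' @param condition Branch for the condition axes: `"concordant"` or
#'   `"discordant"` (dual case; for the pair case the m6A condition axis
#'   uses the contrast column, which separates input from
#'   immunoprecipitated coverage).
#' @param axes Optional named list of explicit component overrides
#'   (`time_x`, `cond_x`, `time_y`, `cond_y`).
#' @param strict_as_printed Passed to [build_dual_kernel()].
#' @return An object of class `ktd_result`: list with `selection_x`,
#'   `selection_y` (`fe_selection` tibbles), `axes`, `kernel_fit`, and -
#'   dual case - `overlap` ([overlap_fisher()] of the two masks); pair
#'   case instead records `condition_asymmetry`
#'   ([kernel_condition_asymmetry()]).
#' @export
run_ktd_workflow <- function(x, y, covariate = NULL, alpha = 0.01,
                             condition = c("concordant", "discordant"),
                             axes = list(), strict_as_printed = FALSE) {
  condition <- match.arg(condition)
  dual <- is.array(x) && length(dim(x)) == 3
  if (dual) {
    kern <- build_dual_kernel(x, y, strict_as_printed = strict_as_printed)
  } else {
    kern <- build_pair_kernel(x, y)
  }
  h <- hosvd(kern)
  pick_cond <- function(fm) switch(condition,
    concordant = sign_concordant_axis(fm),
    discordant = sign_contrast_axis(fm)
  )
  if (dual) {
    n_time <- dim(x)[2]
    covariate <- covariate %||% seq_len(n_time)
    time_x <- axes$time_x %||%
      rank_axes_by_correlation(h$factors[[1]], covariate)$component[1]
    cond_x <- axes$cond_x %||% pick_cond(h$factors[[2]])
    time_y <- axes$time_y %||%
      rank_axes_by_correlation(h$factors[[4]], covariate)$component[1]
    cond_y <- axes$cond_y %||% pick_cond(h$factors[[5]])
    sel_x <- feature_selection(
      project_dual_features(h, time_x, cond_x, x, side = "first"),
      alpha = alpha, component = c(time_x, cond_x))
    sel_y <- feature_selection(
      project_dual_features(h, time_y, cond_y, y, side = "second"),
      alpha = alpha, component = c(time_y, cond_y))
    overlap <- overlap_fisher(sel_x$selected, sel_y$selected)
    axes_out <- c(time_x = time_x, cond_x = cond_x,
                  time_y = time_y, cond_y = cond_y)
    extra <- list(overlap = overlap)
  } else {
    n_time <- ncol(x)
    covariate <- covariate %||% seq_len(n_time)
    time_x <- axes$time_x %||%
      rank_axes_by_correlation(h$factors[[1]], covariate)$component[1]
    time_y <- axes$time_y %||%
      rank_axes_by_correlation(h$factors[[3]], covariate)$component[1]
    cond_y <- axes$cond_y %||% sign_contrast_axis(h$factors[[2]])
    sel_x <- feature_selection(
      project_matrix_features(h, time_x, x),
      alpha = alpha, component = time_x,
      feature_ids = rownames(x))
    sel_y <- feature_selection(
      project_tensor_features(h, cond_y, time_y, y),
      alpha = alpha, component = c(cond_y, time_y))
    axes_out <- c(time_x = time_x, cond_y = cond_y, time_y = time_y)
    extra <- list(condition_asymmetry = kernel_condition_asymmetry(kern))
  }
  structure(
    c(list(selection_x = sel_x, selection_y = sel_y, axes = axes_out,
           kernel_fit = h, alpha = alpha), extra),
    class = "ktd_result"
  )
}

#' @export
print.ktd_result <- function(x, ...) {
  cat(sprintf("<ktd_result> axes: %s\n",
              paste(names(x$axes), x$axes, sep = "=", collapse = ", ")))
  cat(sprintf("selected: %d (x), %d (y)\n",
              sum(x$selection_x$selected), sum(x$selection_y$selected)))
  if (!is.null(x$overlap)) {
    cat(sprintf("overlap odds ratio %.3g (P = %.3g)\n",
                x$overlap$odds_ratio, x$overlap$p_value))
  }
  invisible(x)
}

#' Planted-signal benchmark of the TD / KTD / regression pipelines
#'
#' Regenerates the two synthetic benchmark sets for each seed, runs the
#' TD workflow (both condition branches) on set 1, the KTD workflow
#' (both branches, both sides) on set 2 plus the cross-data-set overlap
#' of the concordant selections, and the per-feature linear-regression
#' baseline on set 1; every selection is cross-tabulated against the
#' planted truth.
#'
#' @param seeds Integer vector of generator seeds (default `1:10`).
#' @param n_features,n_signal,noise_sd Generator parameters, defaults as
#'   in [simulate_planted_tensor()].
#' @param alpha Adjusted-P threshold (default 0.01).
#' @return An object of class `benchmark_report`: list with `results`
#'   (tibble, one row per seed x analysis branch: selection counts,
#'   confusion cells, exactness flags, chosen axes), `overlap` (tibble
#'   of per-seed cross-data-set tables), and the parameters.
#' @export
run_benchmark <- function(seeds = 1:10, n_features = 1000, n_signal = 10,
                          noise_sd = 0.5, alpha = 0.01) {
  rows <- list()
  olap <- list()
  for (s in seeds) {
    set1 <- simulate_planted_tensor(n_features, n_signal,
                                    noise_sd = noise_sd, seed = s)
    fit1 <- hosvd(set1$tensor)
    for (branch in c("concordant", "discordant")) {
      sel <- run_td_workflow(set1$tensor, alpha = alpha,
                             condition = branch, fit = fit1)
      truth <- if (branch == "concordant") set1$truth_concordant
               else set1$truth_discordant
      cm <- confusion_matrix(sel$selected, truth)
      rows[[length(rows) + 1]] <- benchmark_row(
        s, "td_set1", branch, sel, cm, attr(sel, "axes"))
    }

    set2 <- simulate_paired_tensors(n_features, n_signal,
                                    noise_sd = noise_sd, seed = s + 10000L)
    kres <- list(
      concordant = run_ktd_workflow(set2$x, set2$x_prime, alpha = alpha,
                                    condition = "concordant"),
      discordant = run_ktd_workflow(set2$x, set2$x_prime, alpha = alpha,
                                    condition = "discordant")
    )
    for (branch in names(kres)) {
      kr <- kres[[branch]]
      truths <- if (branch == "concordant") {
        list(set2$truth_x_concordant, set2$truth_xp_concordant)
      } else {
        list(set2$truth_x_discordant, set2$truth_xp_discordant)
      }
      for (i in 1:2) {
        sel <- if (i == 1) kr$selection_x else kr$selection_y
        cm <- confusion_matrix(sel$selected, truths[[i]])
        rows[[length(rows) + 1]] <- benchmark_row(
          s, if (i == 1) "ktd_set2_x" else "ktd_set2_xp", branch, sel, cm,
          kr$axes)
      }
    }
    ocm <- overlap_fisher(kres$concordant$selection_x$selected,
                          kres$concordant$selection_y$selected)
    olap[[length(olap) + 1]] <- tibble(
      seed = s,
      neither = ocm$table[1, 1], only_x = ocm$table[1, 2],
      only_xp = ocm$table[2, 1], both = ocm$table[2, 2]
    )

    reg <- linear_regression_select(as_plain_array(set1$tensor),
                                    regression_design("synthetic"),
                                    alpha = alpha)
    cmr <- confusion_matrix(reg$selected,
                            c(set1$truth_concordant, set1$truth_discordant))
    rows[[length(rows) + 1]] <- benchmark_row(
      s, "regression_set1", "linear", reg, cmr, NULL)
  }
  structure(
    list(
      results = dplyr::bind_rows(rows),
      overlap = dplyr::bind_rows(olap),
      seeds = seeds, n_features = n_features, n_signal = n_signal,
      noise_sd = noise_sd, alpha = alpha
    ),
    class = "benchmark_report"
  )
}

benchmark_row <- function(seed, analysis, branch, sel, cm, axes) {
  tibble(
    seed = seed, analysis = analysis, branch = branch,
    n_selected = sum(sel$selected),
    true_neg = cm[1, 1], false_pos = cm[1, 2],
    false_neg = cm[2, 1], true_pos = cm[2, 2],
    exact = cm[1, 2] == 0 && cm[2, 1] == 0,
    axes = paste(axes, collapse = ",")
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %d seeds, N = %d, N1 = %d, alpha = %g\n",
              length(x$seeds), x$n_features, x$n_signal, x$alpha))
  agg <- dplyr::summarise(
    dplyr::group_by(x$results, .data$analysis, .data$branch),
    exact_seeds = sum(.data$exact),
    median_selected = stats::median(.data$n_selected),
    .groups = "drop"
  )
  print(as.data.frame(agg))
  invisible(x)
}

#' Write a benchmark report as markdown
#'
#' @param x A `benchmark_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Planted-signal benchmark")
  w("")
  w("seeds: %s; N = %d, N1 = %d, noise sd %g, alpha = %g",
    paste(x$seeds, collapse = ", "), x$n_features, x$n_signal,
    x$noise_sd, x$alpha)
  w("")
  w("## Per-branch recovery (confusion cells vs planted truth)")
  w("")
  w("| seed | analysis | branch | TN | FP | FN | TP | exact | axes |")
  w("|---|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(x$results))) {
    r <- x$results[i, ]
    w("| %d | %s | %s | %d | %d | %d | %d | %s | %s |",
      r$seed, r$analysis, r$branch, r$true_neg, r$false_pos,
      r$false_neg, r$true_pos, r$exact, r$axes)
  }
  w("")
  w("## Cross-data-set overlap of concordant selections")
  w("")
  w("| seed | neither | only x | only x' | both |")
  w("|---|---|---|---|---|")
  for (i in seq_len(nrow(x$overlap))) {
    r <- x$overlap[i, ]
    w("| %d | %d | %d | %d | %d |", r$seed, r$neither, r$only_x,
      r$only_xp, r$both)
  }
  invisible(path)
}
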