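#' Rank decomposition components by correlation with a covariate
#'
#' Orders the columns of a sample-side factor matrix (PC loadings or an
#' HOSVD factor over time points) by the absolute Pearson correlation of
#' each component with a numeric covariate such as hours after treatment.
#' Components with zero variance have undefined correlation and are
#' ranked last with a warning.
#'
#' @param factor_matrix Numeric matrix, one row per level (e.g. time
#'   point), one column per component.
#' @param covariate Numeric vector, one value per level; at least 3
#'   levels are required for a meaningful correlation.
#' @return A tibble with columns `component`, `r`, `abs_r` and `rank`,
#'   sorted by decreasing `abs_r`.
#' @export
rank_axes_by_correlation <- function(factor_matrix, covariate) {
  factor_matrix <- as.matrix(factor_matrix)
  if (nrow(factor_matrix) != length(covariate)) {
    abort("`covariate` must have one value per factor level")
  }
  if (nrow(factor_matrix) < 3) {
    abort("need at least 3 levels for a meaningful correlation")
  }
  sds <- apply(factor_matrix, 2, stats::sd)
  r <- rep(NA_real_, ncol(factor_matrix))
  ok <- sds > 0
  if (any(!ok)) {
    warn("zero-variance component(s) have undefined correlation; ranked last")
  }
  if (any(ok)) {
    r[ok] <- as.vector(cor(factor_matrix[, ok, drop = FALSE], covariate))
  }
  out <- tibble(
    component = seq_len(ncol(factor_matrix)),
    r = r,
    abs_r = abs(r)
  )
  out <- out[order(-out$abs_r, out$component, na.last = TRUE), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' Find the condition axis by sign contrast
#'
#' For a two-level mode (e.g. input control vs immunoprecipitated
#' sample), returns the lowest component index whose factor entries have
#' opposite signs across the two levels, i.e. the component that encodes
#' the between-condition difference.
#'
#' @param factor_matrix Numeric matrix with exactly 2 rows (levels) and
#'   one column per component.
#' @return Integer component index.
#' @export
sign_contrast_axis <- function(factor_matrix) {
  factor_matrix <- as.matrix(factor_matrix)
  if (nrow(factor_matrix) != 2) abort("the mode must have exactly 2 levels")
  idx <- which(factor_matrix[1, ] * factor_matrix[2, ] < 0)
  if (length(idx) == 0) abort("no contrast axis")
  min(idx)
}

#' @rdname sign_contrast_axis
#' @details `sign_concordant_axis()` is the complement: the lowest
#'   component whose two entries share a sign (strictly positive
#'   product), encoding what the two conditions have in common.
#' @export
sign_concordant_axis <- function(factor_matrix) {
  factor_matrix <- as.matrix(factor_matrix)
  if (nrow(factor_matrix) != 2) abort("the mode must have exactly 2 levels")
  idx <- which(factor_matrix[1, ] * factor_matrix[2, ] > 0)
  if (length(idx) == 0) abort("no concordant axis")
  min(idx)
}

#' Scan the core tensor for the dominant free-mode component
#'
#' Given component choices for all modes but one, finds the free-mode
#' index maximizing the absolute core entry, i.e. the feature-mode
#' component most strongly coupled to the chosen sample-mode components.
#' Ties resolve to the smallest index.
#'
#' @param x An [hosvd()] fit or a plain core array.
#' @param fixed Named or positional integer vector assigning a component
#'   to every mode except one (use `NA` for the free mode, or omit names
#'   and supply `NA` at the free position).
#' @return An object of class `core_scan`: list with `component` (the
#'   argmax), `free_mode`, `fixed`, and `profile` (tibble of core values
#'   along the free mode).
#' @examples
#' g <- array(0, c(3, 2, 2)); g[2, 2, 2] <- 5
#' scan_core(g, c(NA, 2, 2))$component  # 2
#' @export
scan_core <- function(x, fixed) {
  g <- if (inherits(x, "hosvd")) x$core else as_plain_array(x)
  d <- dim(g)
  if (length(fixed) != length(d)) {
    abort("`fixed` must assign one entry per mode (NA marks the free mode)")
  }
  free <- which(is.na(fixed))
  if (length(free) != 1) abort("exactly one mode must be free (NA)")
  fx <- fixed[-free]
  if (any(fx < 1 | fx > d[-free])) abort("fixed component out of range")
  idx <- as.list(fixed)
  idx[[free]] <- seq_len(d[free])
  profile <- as.vector(do.call(`[`, c(list(g), idx)))
  structure(
    list(
      component = which.max(abs(profile)),
      free_mode = free,
      fixed = fixed,
      profile = tibble(component = seq_len(d[free]), core_value = profile)
    ),
    class = "core_scan"
  )
}

#' @export
print.core_scan <- function(x, ...) {
  cat(sprintf("<core_scan> free mode %d, argmax |G| at component %d\n",
              x$free_mode, x$component))
  invisible(x)
}

#' Chi-squared P-values for decomposition scores
#'
#' Attributes a P-value to every feature from one component score vector,
#' under the null hypothesis that the scores are Gaussian: each
#' standardized squared score \eqn{(u_i/\sigma)^2} is referred to the
#' upper tail of the chi-squared distribution with 1 degree of freedom.
#' \eqn{\sigma} is the standard deviation of the scores across all
#' features (denominator `n`, computed once; no iterative re-estimation).
#' The P-values are invariant to a global sign flip or positive rescaling
#' of the scores.
#'
#' @param u Numeric vector of per-feature scores (length >= 2).
#' @return Numeric vector of raw P-values with attribute `sigma`.
#' @export
chi2_pvalues <- function(u) {
  if (length(u) < 2) abort("need at least 2 features")
  if (!all(is.finite(u))) abort("`u` must be finite")
  sigma <- sqrt(mean((u - mean(u))^2))
  if (sigma == 0) abort("constant component")
  p <- pchisq((u / sigma)^2, df = 1, lower.tail = FALSE)
  attr(p, "sigma") <- sigma
  p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a family of raw P-values
#' (delegates to [stats::p.adjust()] with `method = "BH"` after
#' validating the input range).
#'
#' @param p Numeric vector of raw P-values in `[0, 1]`.
#' @return Adjusted P-values in input order, element-wise `>=` the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    abort("P-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Threshold adjusted P-values
#'
#' @param adjusted Numeric vector of adjusted P-values.
#' @param alpha Selection threshold in (0, 1); the comparison is the
#'   strict inequality `adjusted < alpha`.
#' @return Logical selection mask.
#' @export
select_features <- function(adjusted, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single value in (0, 1)")
  }
  adjusted < alpha
}

#' Build a feature-selection table from component scores
#'
#' Composite of [chi2_pvalues()], [bh_adjust()] and [select_features()]:
#' the per-feature end point of every workflow in the package.
#'
#' @param scores Numeric vector of per-feature scores.
#' @param alpha Adjusted-P threshold, default 0.01.
#' @param feature_ids Optional identifiers (default `feature_<i>`).
#' @param component Component annotation stored alongside the result
#'   (free-form; e.g. an index or index pair).
#' @return A tibble of class `fe_selection` with columns `feature_id`,
#'   `score`, `p_value`, `p_adjusted`, `selected`, and attributes
#'   `alpha`, `sigma`, `component`.
#' @export
feature_selection <- function(scores, alpha = 0.01, feature_ids = NULL,
                              component = NA) {
  p <- chi2_pvalues(scores)
  adj <- bh_adjust(as.vector(p))
  out <- tibble(
    feature_id = feature_ids %||% paste0("feature_", seq_along(scores)),
    score = as.vector(scores),
    p_value = as.vector(p),
    p_adjusted = adj,
    selected = select_features(adj, alpha)
  )
  attr(out, "alpha") <- alpha
  attr(out, "sigma") <- attr(p, "sigma")
  attr(out, "component") <- component
  class(out) <- c("fe_selection", class(out))
  out
}

#' @rdname feature_selection
#' @param x An `fe_selection` table.
#' @param ... Unused.
#' @method glance fe_selection
#' @export
glance.fe_selection <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_selected = sum(x$selected),
    alpha = attr(x, "alpha"),
    sigma = attr(x, "sigma"),
    component = paste(attr(x, "component"), collapse = ",")
  )
}

#' Write a selection table to TSV
#'
#' @param x An `fe_selection` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
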