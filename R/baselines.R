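#' Per-feature linear-regression design
#'
#' Builds the single-predictor design used by the regression baseline.
#' The predictor encodes how each flattened observation relates to the
#' experimental axis:
#' * `"expression"`: the measurement times themselves, one observation
#'   per time point;
#' * `"m6a"`: the product of time and the condition index `j` in
#'   `{1, 2}` (input vs immunoprecipitated), observations ordered time
#'   fastest within condition;
#' * `"synthetic"`: the product of the time index `j` in `1..n_time` and
#'   the condition index `k` in `{1, 2}`, same ordering.
#'
#' @param kind One of `"expression"`, `"m6a"`, `"synthetic"`.
#' @param times Numeric time values (default `c(0, 6, 12, 24)` hours);
#'   for `"synthetic"` the time index `1..length(times)` is used instead.
#' @param n_conditions Number of condition levels (default 2).
#' @return An object of class `regression_design`: list with `kind` and
#'   `predictor` (one value per flattened observation).
#' @export
regression_design <- function(kind = c("expression", "m6a", "synthetic"),
                              times = c(0, 6, 12, 24), n_conditions = 2) {
  kind <- match.arg(kind)
  predictor <- switch(kind,
    expression = as.numeric(times),
    m6a = as.vector(outer(as.numeric(times), seq_len(n_conditions))),
    synthetic = as.vector(outer(seq_along(times), seq_len(n_conditions)))
  )
  structure(list(kind = kind, predictor = predictor),
            class = "regression_design")
}

#' Linear-regression feature selection baseline
#'
#' Fits an ordinary least-squares line `value = a + b * predictor` to
#' every feature independently (closed form, vectorized over features),
#' tests the slope with a two-sided t-test on `n - 2` residual degrees
#' of freedom, adjusts across features by Benjamini-Hochberg, and
#' selects with a strict `< alpha` threshold. This is the conventional
#' supervised comparator for the decomposition-based selection.
#'
#' @param data Features-by-observations numeric matrix, or a 3-way
#'   feature x time x condition array (flattened time-fastest to match
#'   [regression_design()]).
#' @param design A [regression_design()] whose predictor length equals
#'   the number of observations per feature.
#' @param alpha Adjusted-P threshold, default 0.01.
#' @return An `fe_selection`-style tibble with columns `feature_id`,
#'   `intercept`, `slope`, `p_value`, `p_adjusted`, `selected`.
#' @export
linear_regression_select <- function(data, design, alpha = 0.01) {
  if (!inherits(design, "regression_design")) {
    abort("`design` must be a `regression_design`")
  }
  ids <- if (is.matrix(data)) rownames(data) else NULL
  x <- if (is.array(data) && length(dim(data)) == 3) {
    tensor_unfold(data, 1)
  } else {
    as_plain_array(as.matrix(data))
  }
  pred <- design$predictor
  n <- length(pred)
  if (ncol(x) != n) {
    abort("predictor length must equal observations per feature")
  }
  if (n < 3) abort("need at least 3 observations per feature")
  if (var(pred) == 0) abort("zero predictor variance")

  pc <- pred - mean(pred)
  sxx <- sum(pc^2)
  slope <- drop(x %*% pc) / sxx
  intercept <- rowMeans(x) - slope * mean(pred)
  fitted <- outer(slope, pred) + intercept
  rss <- rowSums((x - fitted)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tstat <- ifelse(se == 0, ifelse(slope == 0, 0, Inf), slope / se)
  p <- 2 * pt(-abs(tstat), df = n - 2)
  adj <- bh_adjust(p)
  out <- tibble(
    feature_id = ids %||% paste0("feature_", seq_len(nrow(x))),
    intercept = intercept,
    slope = slope,
    p_value = p,
    p_adjusted = adj,
    selected = select_features(adj, alpha)
  )
  attr(out, "alpha") <- alpha
  attr(out, "design") <- design$kind
  class(out) <- c("fe_selection", class(out))
  out
}
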