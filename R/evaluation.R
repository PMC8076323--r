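#' Confusion matrix of a selection against planted truth
#'
#' Cross-tabulates a feature selection against a known truth set. Rows
#' index truth membership (out / in), columns selection status (not
#' selected / selected), so a perfect recovery of a 10-feature truth set
#' in a 1000-feature universe reads `(990, 0; 0, 10)`.
#'
#' @param selected Logical selection mask over the feature universe, or
#'   integer indices (then `n_features` is required).
#' @param truth Integer indices of the true features (may be empty).
#' @param n_features Universe size; defaults to `length(selected)` for a
#'   logical mask.
#' @return A 2x2 integer matrix of class `confusion_2x2` with dimnames
#'   `truth` (out/in) x `selected` (no/yes).
#' @export
confusion_matrix <- function(selected, truth, n_features = NULL) {
  if (is.logical(selected)) {
    n_features <- n_features %||% length(selected)
    if (length(selected) != n_features) abort("mask length mismatch")
    sel <- selected
  } else {
    if (is.null(n_features)) {
      abort("`n_features` is required when `selected` gives indices")
    }
    if (length(selected) && (min(selected) < 1 || max(selected) > n_features)) {
      abort("selected index out of range")
    }
    sel <- seq_len(n_features) %in% selected
  }
  if (length(truth) && (min(truth) < 1 || max(truth) > n_features)) {
    abort("truth index out of range")
  }
  tr <- seq_len(n_features) %in% truth
  m <- matrix(
    c(sum(!tr & !sel), sum(!tr & sel), sum(tr & !sel), sum(tr & sel)),
    nrow = 2, byrow = TRUE,
    dimnames = list(truth = c("out", "in"), selected = c("no", "yes"))
  )
  class(m) <- c("confusion_2x2", class(m))
  m
}

#' @method tidy confusion_2x2
#' @export
tidy.confusion_2x2 <- function(x, ...) {
  tibble(
    truth = rep(rownames(x), each = 2),
    selected = rep(colnames(x), 2),
    n = as.integer(t(unclass(x)))
  )
}

#' Exact-test overlap statistics for two selections
#'
#' Builds the 2x2 contingency table of two selection masks over a shared
#' feature universe and runs Fisher's exact test: the reported odds ratio
#' is the conditional maximum-likelihood estimate under the noncentral
#' hypergeometric model with all margins fixed (the convention of
#' standard exact-test software, which differs slightly from the sample
#' cross-product ratio - both are reported), and the two-sided P-value
#' sums the probabilities of all tables no more probable than the one
#' observed.
#'
#' @param mask_a,mask_b Logical selection masks of equal length, or
#'   `NULL` when `table` is given directly.
#' @param table Optional 2x2 count matrix (rows: B not/selected, columns:
#'   A not/selected), bypassing the masks.
#' @return An object of class `overlap_stats`: list with `table`,
#'   `odds_ratio` (conditional MLE), `odds_ratio_sample` (cross-product),
#'   `p_value`, `conf_int`.
#' @examples
#' overlap_fisher(table = matrix(c(19773, 189, 45, 7), 2))$odds_ratio
#' @export
overlap_fisher <- function(mask_a = NULL, mask_b = NULL, table = NULL) {
  if (is.null(table)) {
    if (length(mask_a) != length(mask_b)) {
      abort("masks must have equal length")
    }
    table <- matrix(
      c(sum(!mask_b & !mask_a), sum(!mask_b & mask_a),
        sum(mask_b & !mask_a), sum(mask_b & mask_a)),
      nrow = 2, byrow = TRUE,
      dimnames = list(B = c("no", "yes"), A = c("no", "yes"))
    )
  } else {
    table <- as.matrix(table)
    if (!identical(dim(table), c(2L, 2L))) abort("`table` must be 2x2")
  }
  ft <- fisher.test(table)
  sample_or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  structure(
    list(
      table = table,
      odds_ratio = unname(ft$estimate),
      odds_ratio_sample = sample_or,
      p_value = ft$p.value,
      conf_int = unname(ft$conf.int)
    ),
    class = "overlap_stats"
  )
}

#' @export
print.overlap_stats <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio (conditional MLE) %.4g, sample %.4g, P = %.3g\n",
              x$odds_ratio, x$odds_ratio_sample, x$p_value))
  invisible(x)
}

#' @rdname overlap_fisher
#' @param x An `overlap_stats` object.
#' @param ... Unused.
#' @method glance overlap_stats
#' @export
glance.overlap_stats <- function(x, ...) {
  tibble(
    odds_ratio = x$odds_ratio,
    odds_ratio_sample = x$odds_ratio_sample,
    p_value = x$p_value,
    n = sum(x$table),
    both_selected = x$table[2, 2]
  )
}
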