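#' Feature-by-sample omics matrix
#'
#' A thin wrapper around a numeric matrix holding one row per feature
#' (gene, transcript, region) and one column per sample, with an optional
#' numeric sample covariate such as the measurement time in hours.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#' @param feature_ids Character vector of row identifiers. Defaults to the
#'   row names of `values`, or `feature_1 ...` when absent.
#' @param sample_labels Character vector of column labels. Defaults to the
#'   column names of `values`, or `sample_1 ...` when absent.
#' @param covariate Optional numeric vector with one value per sample,
#'   e.g. hours after treatment `c(0, 6, 12, 24)`.
#'
#' @return A numeric matrix of class `omics_matrix` with dimnames set and,
#'   when given, a `covariate` attribute.
#' @examples
#' m <- omics_matrix(matrix(1:8, 2), covariate = c(0, 6, 12, 24))
#' sample_covariate(m)
#' @export
omics_matrix <- function(values, feature_ids = NULL, sample_labels = NULL,
                         covariate = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  feature_ids <- feature_ids %||% rownames(values) %||%
    paste0("feature_", seq_len(nrow(values)))
  sample_labels <- sample_labels %||% colnames(values) %||%
    paste0("sample_", seq_len(ncol(values)))
  if (length(feature_ids) != nrow(values)) {
    abort("`feature_ids` must have one entry per row")
  }
  if (length(sample_labels) != ncol(values)) {
    abort("`sample_labels` must have one entry per column")
  }
  if (!is.null(covariate)) {
    if (!is.numeric(covariate) || length(covariate) != ncol(values)) {
      abort("`covariate` must be numeric with one value per sample")
    }
  }
  dimnames(values) <- list(as.character(feature_ids), as.character(sample_labels))
  attr(values, "covariate") <- covariate
  class(values) <- c("omics_matrix", class(values))
  values
}

#' @rdname omics_matrix
#' @param x An `omics_matrix`.
#' @export
sample_covariate <- function(x) attr(x, "covariate")

#' Named multi-way omics tensor
#'
#' Wraps a numeric array with named modes (e.g. region, time, condition)
#' and per-mode labels, the container for region-by-time-by-condition
#' coverage tensors and for sample-space kernel tensors.
#'
#' @param values Numeric array of any order >= 2.
#' @param mode_names Character vector naming each mode; length must equal
#'   the array order.
#' @param mode_labels Optional list of label vectors, one per mode, each
#'   matching that mode's extent.
#'
#' @return A numeric array of class `omics_tensor` with attributes
#'   `mode_names` and `mode_labels`.
#' @examples
#' x <- omics_tensor(array(1:24, c(3, 4, 2)), c("region", "time", "condition"))
#' mode_names(x)
#' @export
omics_tensor <- function(values, mode_names, mode_labels = NULL) {
  if (!is.array(values) || !is.numeric(values)) {
    abort("`values` must be a numeric array")
  }
  d <- dim(values)
  if (length(mode_names) != length(d)) {
    abort(sprintf("`mode_names` has %d names but the array has %d modes",
                  length(mode_names), length(d)))
  }
  if (is.null(mode_labels)) {
    mode_labels <- lapply(d, seq_len)
  }
  if (length(mode_labels) != length(d) ||
      !all(lengths(mode_labels) == d)) {
    abort("`mode_labels` must supply one label per level of every mode")
  }
  attr(values, "mode_names") <- as.character(mode_names)
  attr(values, "mode_labels") <- mode_labels
  class(values) <- c("omics_tensor", class(values))
  values
}

#' @rdname omics_tensor
#' @param x An `omics_tensor` (or plain array, for which positional names
#'   are invented).
#' @export
mode_names <- function(x) {
  attr(x, "mode_names") %||% paste0("mode_", seq_along(dim(x)))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %d features x %d samples\n", nrow(x), ncol(x)))
  cov <- sample_covariate(x)
  if (!is.null(cov)) cat("covariate:", paste(cov, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.omics_tensor <- function(x, ...) {
  cat(sprintf("<omics_tensor> %s [%s]\n",
              paste(mode_names(x), collapse = " x "),
              paste(dim(x), collapse = " x ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip container attributes, returning the plain numeric array/matrix
as_plain_array <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}
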