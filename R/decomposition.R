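#' Mode-m matricization of a tensor
#'
#' Unfolds an array along one mode: mode `m` indexes the rows and all the
#' remaining modes, in their original order, are flattened into columns
#' (first remaining mode varying fastest).
#'
#' @param x Numeric array.
#' @param mode Integer mode index.
#' @return A matrix with `dim(x)[mode]` rows.
#' @export
tensor_unfold <- function(x, mode) {
  d <- dim(x)
  if (mode < 1 || mode > length(d)) abort("`mode` out of range")
  perm <- c(mode, setdiff(seq_along(d), mode))
  matrix(aperm(as_plain_array(x), perm), d[mode])
}

# mode-m product: contract mode `mode` of `x` with matrix `mat`
# (rows of `mat` index the new mode extent, columns match dim(x)[mode])
ttm <- function(x, mat, mode) {
  d <- dim(x)
  res <- mat %*% tensor_unfold(x, mode)
  d_new <- d
  d_new[mode] <- nrow(mat)
  perm <- c(mode, setdiff(seq_along(d), mode))
  aperm(array(res, d_new[perm]), order(perm))
}

# deterministic sign convention: flip each column so that its
# largest-magnitude entry is positive
fix_signs <- function(u) {
  flip <- apply(u, 2, function(v) v[which.max(abs(v))] < 0)
  u[, flip] <- -u[, flip, drop = FALSE]
  u
}

#' Gram-matrix principal component analysis
#'
#' Computes PC scores over features and PC loadings over samples for a
#' features-by-samples matrix. Scores are the eigenvectors of the
#' feature-space gram matrix \eqn{XX^T}, obtained from the thin SVD of
#' \eqn{X} so the (possibly huge) gram matrix is never formed; loadings
#' are \eqn{v_\ell = X^T u_\ell} and eigenvalues are the squared singular
#' values. Each score vector is sign-fixed so its largest-magnitude entry
#' is positive; downstream P-value attribution squares the scores, so the
#' convention does not affect selections.
#'
#' @param x Numeric matrix (features x samples) or [omics_matrix()].
#' @param center If `TRUE`, subtract each sample's mean across features
#'   before decomposing. Default `FALSE`: profiles are decomposed as-is,
#'   so the first component typically tracks overall magnitude.
#' @return An object of class `gram_pca`: list with `scores` (features x
#'   components, orthonormal columns), `loadings` (samples x components),
#'   `eigenvalues` (non-increasing), `feature_ids`, `sample_labels`,
#'   `covariate`, `centered`.
#' @examples
#' x <- matrix(c(1, 2, 2, 4), 2)
#' pca_gram(x)$eigenvalues  # c(25, 0)
#' @export
pca_gram <- function(x, center = FALSE) {
  cov <- sample_covariate(x)
  feature_ids <- rownames(x) %||% paste0("feature_", seq_len(nrow(x)))
  sample_labels <- colnames(x) %||% paste0("sample_", seq_len(ncol(x)))
  x <- as_plain_array(as.matrix(x))
  if (!all(is.finite(x))) abort("`x` must be finite")
  if (ncol(x) < 2) abort("need at least 2 samples")
  if (all(x == 0)) abort("degenerate matrix: all entries are zero")
  if (center) x <- sweep(x, 2, colMeans(x))
  sv <- svd(x)
  scores <- fix_signs(sv$u)
  loadings <- crossprod(x, scores)
  structure(
    list(
      scores = scores,
      loadings = loadings,
      eigenvalues = sv$d^2,
      feature_ids = feature_ids,
      sample_labels = sample_labels,
      covariate = cov,
      centered = center
    ),
    class = "gram_pca"
  )
}

#' @export
print.gram_pca <- function(x, ...) {
  cat(sprintf("<gram_pca> %d features, %d samples, %d components\n",
              length(x$feature_ids), length(x$sample_labels),
              length(x$eigenvalues)))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Higher-order singular value decomposition
#'
#' Plain one-pass HOSVD: the factor matrix of every mode holds the left
#' singular vectors of that mode's unfolding, and the all-orthogonal core
#' is the tensor contracted with each factor transpose. No iterative
#' (HOOI) refinement is applied. Factor columns follow the SVD's
#' non-increasing singular-value order and are sign-fixed so the
#' largest-magnitude entry of each is positive; under exactly tied
#' singular values the factor basis is not unique.
#'
#' Ranks default to the effective maximum `min(dim(x)[m], prod(dim(x)[-m]))`
#' per mode, so for a tall feature mode only the components that can carry
#' signal are computed and the core stays small.
#'
#' @param x Numeric array (order >= 2) or [omics_tensor()].
#' @param ranks Optional integer vector of per-mode truncation ranks.
#' @return An object of class `hosvd`: list with `core` (array), `factors`
#'   (list of orthonormal matrices, one per mode), `mode_names`, `ranks`.
#' @examples
#' x <- array(rnorm(24), c(3, 4, 2))
#' h <- hosvd(x)
#' max(abs(reconstruct(h) - x)) < 1e-10
#' @export
hosvd <- function(x, ranks = NULL) {
  modes <- mode_names(x)
  x <- as_plain_array(x)
  d <- dim(x)
  n <- length(d)
  if (n < 2) abort("`x` must have order >= 2")
  if (!all(is.finite(x))) abort("`x` must be finite")
  max_rank <- pmin(d, prod(d) / d)
  if (is.null(ranks)) {
    ranks <- max_rank
  } else {
    if (length(ranks) != n) abort("`ranks` must give one rank per mode")
    if (any(ranks < 1) || any(ranks > d)) {
      abort("requested rank exceeds mode length")
    }
    ranks <- pmin(ranks, max_rank)
  }
  factors <- vector("list", n)
  for (m in seq_len(n)) {
    sv <- svd(tensor_unfold(x, m), nu = ranks[m], nv = 0)
    factors[[m]] <- fix_signs(sv$u)
  }
  core <- x
  for (m in seq_len(n)) core <- ttm(core, t(factors[[m]]), m)
  structure(
    list(core = core, factors = factors, mode_names = modes,
         ranks = as.integer(ranks), dims = d),
    class = "hosvd"
  )
}

#' @export
print.hosvd <- function(x, ...) {
  cat(sprintf("<hosvd> %s [%s], core [%s]\n",
              paste(x$mode_names, collapse = " x "),
              paste(x$dims, collapse = " x "),
              paste(dim(x$core), collapse = " x ")))
  invisible(x)
}

#' Reconstruct a tensor from its HOSVD
#'
#' Multilinear contraction of the core with every factor matrix. With
#' full (untruncated) ranks the reconstruction reproduces the input to
#' numerical precision.
#'
#' @param h An object returned by [hosvd()].
#' @return A numeric array of the original dimensions.
#' @export
reconstruct <- function(h) {
  if (!inherits(h, "hosvd")) abort("`h` must be a `hosvd` object")
  x <- h$core
  for (m in seq_along(h$factors)) {
    if (ncol(h$factors[[m]]) != dim(x)[m]) {
      abort("core/factor shape mismatch")
    }
    x <- ttm(x, h$factors[[m]], m)
  }
  x
}

#' @rdname pca_gram
#' @param x A `gram_pca` object (for `tidy`/`glance`).
#' @param matrix Which quantity to tidy: `"scores"` (per feature),
#'   `"loadings"` (per sample) or `"eigenvalues"`.
#' @param ... Unused.
#' @method tidy gram_pca
#' @export
tidy.gram_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                          ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = {
      m <- x$scores
      tibble(
        feature_id = rep(x$feature_ids, ncol(m)),
        component = rep(seq_len(ncol(m)), each = nrow(m)),
        score = as.vector(m)
      )
    },
    loadings = {
      m <- x$loadings
      tibble(
        sample = rep(x$sample_labels, ncol(m)),
        covariate = if (is.null(x$covariate)) NA_real_
                    else rep(x$covariate, ncol(m)),
        component = rep(seq_len(ncol(m)), each = nrow(m)),
        loading = as.vector(m)
      )
    },
    eigenvalues = tibble(
      component = seq_along(x$eigenvalues),
      eigenvalue = x$eigenvalues,
      proportion = x$eigenvalues / sum(x$eigenvalues)
    )
  )
}

#' @rdname pca_gram
#' @method glance gram_pca
#' @export
glance.gram_pca <- function(x, ...) {
  tibble(
    n_features = length(x$feature_ids),
    n_samples = length(x$sample_labels),
    n_components = length(x$eigenvalues),
    total_variance = sum(x$eigenvalues),
    centered = x$centered
  )
}

#' @rdname hosvd
#' @param mode Which mode's factor matrix to tidy (integer or mode name).
#' @param ... Unused.
#' @method tidy hosvd
#' @export
tidy.hosvd <- function(x, mode = 1, ...) {
  if (is.character(mode)) mode <- match(mode, x$mode_names)
  if (is.na(mode) || mode < 1 || mode > length(x$factors)) {
    abort("unknown mode")
  }
  m <- x$factors[[mode]]
  tibble(
    mode = x$mode_names[mode],
    level = rep(seq_len(nrow(m)), ncol(m)),
    component = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' @rdname hosvd
#' @method glance hosvd
#' @export
glance.hosvd <- function(x, ...) {
  tibble(
    order = length(x$dims),
    modes = paste(x$mode_names, collapse = " x "),
    dims = paste(x$dims, collapse = " x "),
    core_norm = sqrt(sum(x$core^2))
  )
}
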