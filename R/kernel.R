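#' Sample-space kernel tensor for a matrix/tensor pair
#'
#' Integrates a features-by-time expression matrix with a
#' region-by-time-by-condition coverage tensor into a small sample-space
#' tensor indexed only by sample modes,
#' \deqn{x_{tjt'j'} = \sum_{t''} \Big(\sum_i x_{it} x_{it''}\Big)
#'                    \Big(\sum_k x_{kt''j} x_{kt'j'}\Big),}
#' computed from the time-by-time expression gram matrix and the
#' sample-by-sample coverage gram matrix so that no feature-space
#' intermediate beyond the input data is materialized. The resulting
#' tensor is bilinear in each data set: scaling either input by `c`
#' scales the kernel by `c^2`.
#'
#' @param x Numeric matrix, features x time points.
#' @param y Numeric 3-way array, regions x time points x conditions; the
#'   time extent must match `ncol(x)`.
#' @return An [omics_tensor()] with modes
#'   `(time, condition, time2, condition2)` of shape `(T, J, T, J)`.
#' @export
build_pair_kernel <- function(x, y) {
  x <- as_plain_array(as.matrix(x))
  y <- as_plain_array(y)
  if (length(dim(y)) != 3) abort("`y` must be a 3-way array")
  n_time <- ncol(x)
  n_cond <- dim(y)[3]
  if (dim(y)[2] != n_time) {
    abort("time-mode lengths differ between the two data sets")
  }
  e_gram <- crossprod(x)                       # T x T over t, t''
  m_gram <- crossprod(tensor_unfold(y, 1))     # (T*J) x (T*J), col t + T(j-1)
  k <- array(0, c(n_time, n_cond, n_time, n_cond))
  for (j in seq_len(n_cond)) {
    rows <- (j - 1) * n_time + seq_len(n_time) # index t'' for condition j
    k[, j, , ] <- array(e_gram %*% m_gram[rows, , drop = FALSE],
                        c(n_time, n_time, n_cond))
  }
  omics_tensor(k, c("time", "condition", "time2", "condition2"))
}

#' Sample-space kernel tensor for two tensors over shared features
#'
#' Integrates two feature-matched 3-way tensors (features x time x
#' condition) into a 6-mode sample-space tensor
#' \deqn{x_{jk_1k_2j'k'_1k'_2} = \sum_{j''}
#'   \Big(\sum_i x_{ijk_1} x_{ij''k_2}\Big)
#'   \Big(\sum_i x'_{ij''k'_1} x'_{ij'k'_2}\Big),}
#' where the first parenthesis is a within-first-data-set product and the
#' second a within-second-data-set product. `strict_as_printed = TRUE`
#' instead takes the second factor as a cross product between the two
#' data sets (\eqn{\sum_i x'_{ij''k'_1} x_{ij'k'_2}}), for comparison.
#'
#' @param a,b Numeric 3-way arrays with identical dimensions
#'   (features x time x condition).
#' @param strict_as_printed Use the asymmetric cross-product variant of
#'   the second factor. Default `FALSE`.
#' @return An [omics_tensor()] with modes
#'   `(time, condition_a, condition_b, time2, condition_a2, condition_b2)`
#'   of shape `(T, J, J, T, J, J)`.
#' @export
build_dual_kernel <- function(a, b, strict_as_printed = FALSE) {
  a <- as_plain_array(a)
  b <- as_plain_array(b)
  if (length(dim(a)) != 3 || length(dim(b)) != 3) {
    abort("`a` and `b` must be 3-way arrays")
  }
  if (!identical(dim(a), dim(b))) {
    abort("`a` and `b` must share feature count and sample-mode shape")
  }
  n_time <- dim(a)[2]
  n_cond <- dim(a)[3]
  a1 <- tensor_unfold(a, 1)                    # N x (T*J), col j + T(k-1)
  b1 <- tensor_unfold(b, 1)
  c_gram <- crossprod(a1)                      # [j + T(k1-1), j'' + T(k2-1)]
  d_gram <- if (strict_as_printed) crossprod(b1, a1) else crossprod(b1)
  k <- array(0, c(n_time, n_cond, n_cond, n_time, n_cond, n_cond))
  for (k1 in seq_len(n_cond)) for (k2 in seq_len(n_cond)) {
    c_blk <- c_gram[(k1 - 1) * n_time + seq_len(n_time),
                    (k2 - 1) * n_time + seq_len(n_time), drop = FALSE]
    for (kp1 in seq_len(n_cond)) for (kp2 in seq_len(n_cond)) {
      d_blk <- d_gram[(kp1 - 1) * n_time + seq_len(n_time),
                      (kp2 - 1) * n_time + seq_len(n_time), drop = FALSE]
      k[, k1, k2, , kp1, kp2] <- c_blk %*% d_blk
    }
  }
  omics_tensor(k, c("time", "condition_a", "condition_b",
                    "time2", "condition_a2", "condition_b2"))
}

#' Back-project kernel factors onto matrix features
#'
#' Reproduces per-feature scores from a sample-space kernel
#' decomposition: \eqn{u_{\ell i} = \sum_t u_{\ell t} x_{it}}, i.e. the
#' data matrix contracted with one factor vector of the kernel's
#' first (time) mode.
#'
#' @param h [hosvd()] fit of a kernel tensor.
#' @param axis Component index on the time mode.
#' @param x Features-by-time data matrix.
#' @param mode Which kernel mode holds the time factor (default 1).
#' @return Numeric per-feature score vector.
#' @export
project_matrix_features <- function(h, axis, x, mode = 1) {
  u <- kernel_factor(h, mode, axis)
  x <- as_plain_array(as.matrix(x))
  if (ncol(x) != length(u)) abort("time extent mismatch")
  drop(x %*% u)
}

#' Back-project kernel factors onto tensor features
#'
#' Reproduces per-region scores from a pair-kernel decomposition:
#' \eqn{u_{\ell_2\ell_3 k} = \sum_j \sum_t u_{\ell_2 j} u_{\ell_3 t} x_{ktj}},
#' a double contraction of the coverage tensor with one condition-mode
#' and one time-mode factor vector of the kernel.
#'
#' @param h [hosvd()] fit of a pair kernel (modes time, condition, time2,
#'   condition2).
#' @param condition_axis,time_axis Component indices for the condition
#'   and time factors.
#' @param y Regions x time x condition data tensor.
#' @param condition_mode,time_mode Kernel modes holding those factors
#'   (defaults 2 and 3: the condition mode of the first data set and the
#'   time mode of the second, as the integration couples them).
#' @return Numeric per-region score vector.
#' @export
project_tensor_features <- function(h, condition_axis, time_axis, y,
                                    condition_mode = 2, time_mode = 3) {
  uj <- kernel_factor(h, condition_mode, condition_axis)
  ut <- kernel_factor(h, time_mode, time_axis)
  y <- as_plain_array(y)
  if (length(dim(y)) != 3) abort("`y` must be a 3-way array")
  if (dim(y)[2] != length(ut) || dim(y)[3] != length(uj)) {
    abort("factor lengths do not match the tensor's sample modes")
  }
  w <- as.vector(outer(ut, uj))                # col t + T(j-1) of unfold
  drop(tensor_unfold(y, 1) %*% w)
}

#' Back-project dual-kernel factors onto either data set's features
#'
#' For the 6-mode dual kernel, reproduces per-feature scores on the first
#' data set (`side = "first"`, factor pair on modes 1-2) or the second
#' (`side = "second"`, modes 4-5):
#' \eqn{u_{\ell_a\ell_b i} = \sum_j \sum_k x_{ijk} u_{\ell_a j} u_{\ell_b k}}.
#'
#' @param h [hosvd()] fit of a dual kernel.
#' @param time_axis,condition_axis Component indices of the time and
#'   condition factor vectors on the chosen side.
#' @param x The corresponding data tensor (features x time x condition).
#' @param side `"first"` or `"second"`.
#' @return Numeric per-feature score vector.
#' @export
project_dual_features <- function(h, time_axis, condition_axis, x,
                                  side = c("first", "second")) {
  side <- match.arg(side)
  modes <- if (side == "first") c(1L, 2L) else c(4L, 5L)
  uj <- kernel_factor(h, modes[1], time_axis)
  uk <- kernel_factor(h, modes[2], condition_axis)
  x <- as_plain_array(x)
  if (length(dim(x)) != 3) abort("`x` must be a 3-way array")
  if (dim(x)[2] != length(uj) || dim(x)[3] != length(uk)) {
    abort("factor lengths do not match the tensor's sample modes")
  }
  w <- as.vector(outer(uj, uk))
  drop(tensor_unfold(x, 1) %*% w)
}

kernel_factor <- function(h, mode, axis) {
  if (!inherits(h, "hosvd")) abort("`h` must be a `hosvd` object")
  if (mode < 1 || mode > length(h$factors)) abort("mode out of range")
  f <- h$factors[[mode]]
  if (axis < 1 || axis > ncol(f)) abort("component index out of range")
  f[, axis]
}

#' Relative asymmetry of a pair kernel under condition-index swap
#'
#' Measures \eqn{\|x_{tjt'j'} - x_{tj't'j}\| / \|x\|}: how far the
#' integrated kernel is from symmetric under exchanging the two
#' condition indices. Zero means the two condition modes are fully
#' exchangeable.
#'
#' @param k A pair kernel tensor (4-way, modes time, condition, time2,
#'   condition2).
#' @return Non-negative scalar.
#' @export
kernel_condition_asymmetry <- function(k) {
  k <- as_plain_array(k)
  if (length(dim(k)) != 4) abort("`k` must be a 4-way kernel")
  swapped <- aperm(k, c(1, 4, 3, 2))
  sqrt(sum((k - swapped)^2)) / sqrt(sum(k^2))
}
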