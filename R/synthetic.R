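#' Planted-signal benchmark tensor (single data set)
#'
#' Generates the single-data-set benchmark: a features x time x condition
#' tensor with two planted blocks of `n_signal` features each among
#' `n_features` total. Writing `j = 1..n_time` for the time index,
#' concordant features (`i <= n_signal`) have mean `j` under both
#' conditions; discordant features (`n_signal < i <= 2 n_signal`) have
#' mean `j` under condition 1 and `-j` under condition 2; all remaining
#' features are pure noise. Noise is i.i.d. Gaussian with mean 0 and
#' standard deviation `noise_sd` everywhere (the unplanted block is
#' assumed to be the same noise, which makes the "not selected" margins
#' of a perfect confusion matrix well defined).
#'
#' @param n_features Total features `N` (default 1000).
#' @param n_signal Block size `N1` (default 10); `2 * n_signal` must not
#'   exceed `n_features`.
#' @param n_time Number of time levels (default 4).
#' @param noise_sd Noise standard deviation (default 0.5). `0` is allowed
#'   as a deterministic test hook.
#' @param seed Optional integer seed; when given, generation is wrapped
#'   in [withr::with_seed()] so results are reproducible and the caller's
#'   RNG state is untouched.
#' @return An object of class `synthetic_set1`: list with `tensor`
#'   (an [omics_tensor()], modes feature/time/condition), integer index
#'   vectors `truth_concordant` and `truth_discordant`, and the
#'   generation parameters.
#' @export
simulate_planted_tensor <- function(n_features = 1000, n_signal = 10,
                                    n_time = 4, noise_sd = 0.5,
                                    seed = NULL) {
  check_planted_args(n_features, n_signal, 2)
  gen <- function() planted_block_tensor(n_features, n_signal, n_time, noise_sd)
  x <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  structure(
    list(
      tensor = omics_tensor(x, c("feature", "time", "condition")),
      truth_concordant = seq_len(n_signal),
      truth_discordant = as.integer(n_signal + seq_len(n_signal)),
      n_features = n_features,
      n_signal = n_signal,
      noise_sd = noise_sd,
      seed = seed
    ),
    class = "synthetic_set1"
  )
}

#' Planted-signal benchmark pair (two data sets with shared blocks)
#'
#' Generates the two-data-set benchmark: tensors `x` and `x_prime`, each
#' features x time x condition. Both carry an independent copy of the
#' single-data-set planted structure in features `1..2*n_signal`. In
#' addition, features `2*n_signal + 1 .. 4*n_signal` of `x` are an exact
#' (noise-included) duplicate of its features `1..2*n_signal`, and
#' features `4*n_signal + 1 .. 6*n_signal` of `x_prime` are an exact
#' duplicate of the same block of `x` - so the two data sets share
#' features with identical time-course dependence. All other features
#' are pure mean-zero noise.
#'
#' @inheritParams simulate_planted_tensor
#' @return An object of class `synthetic_set2`: list with `x`, `x_prime`
#'   (both [omics_tensor()]), truth index sets `truth_x_concordant`,
#'   `truth_x_discordant`, `truth_xp_concordant`, `truth_xp_discordant`,
#'   and the generation parameters. `6 * n_signal` must not exceed
#'   `n_features`.
#' @export
simulate_paired_tensors <- function(n_features = 1000, n_signal = 10,
                                    n_time = 4, noise_sd = 0.5,
                                    seed = NULL) {
  check_planted_args(n_features, n_signal, 6)
  gen <- function() {
    x <- planted_block_tensor(n_features, n_signal, n_time, noise_sd)
    xp <- planted_block_tensor(n_features, n_signal, n_time, noise_sd)
    blk <- seq_len(2 * n_signal)
    x[2 * n_signal + blk, , ] <- x[blk, , ]
    xp[4 * n_signal + blk, , ] <- x[blk, , ]
    list(x = x, xp = xp)
  }
  d <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  n1 <- n_signal
  structure(
    list(
      x = omics_tensor(d$x, c("feature", "time", "condition")),
      x_prime = omics_tensor(d$xp, c("feature", "time", "condition")),
      truth_x_concordant = as.integer(c(seq_len(n1), 2 * n1 + seq_len(n1))),
      truth_x_discordant = as.integer(c(n1 + seq_len(n1), 3 * n1 + seq_len(n1))),
      truth_xp_concordant = as.integer(c(seq_len(n1), 4 * n1 + seq_len(n1))),
      truth_xp_discordant = as.integer(c(n1 + seq_len(n1), 5 * n1 + seq_len(n1))),
      n_features = n_features,
      n_signal = n_signal,
      noise_sd = noise_sd,
      seed = seed
    ),
    class = "synthetic_set2"
  )
}

planted_block_tensor <- function(n_features, n_signal, n_time, noise_sd) {
  x <- array(rnorm(n_features * n_time * 2, 0, noise_sd),
             c(n_features, n_time, 2))
  for (j in seq_len(n_time)) {
    x[seq_len(n_signal), j, ] <- x[seq_len(n_signal), j, ] + j
    dis <- n_signal + seq_len(n_signal)
    x[dis, j, 1] <- x[dis, j, 1] + j
    x[dis, j, 2] <- x[dis, j, 2] - j
  }
  x
}

check_planted_args <- function(n_features, n_signal, mult) {
  if (n_signal <= 0) abort("`n_signal` must be positive")
  if (mult * n_signal > n_features) {
    abort(sprintf("`n_features` must be at least %d * n_signal", mult))
  }
}

#' @export
print.synthetic_set1 <- function(x, ...) {
  cat(sprintf(
    "<synthetic_set1> %d features (%d concordant + %d discordant planted), noise sd %g\n",
    x$n_features, x$n_signal, x$n_signal, x$noise_sd))
  invisible(x)
}

#' @export
print.synthetic_set2 <- function(x, ...) {
  cat(sprintf(
    "<synthetic_set2> paired tensors, %d features, %d planted per block, noise sd %g\n",
    x$n_features, x$n_signal, x$noise_sd))
  invisible(x)
}

#' Export truth labels of a synthetic benchmark set
#'
#' @param x A `synthetic_set1` or `synthetic_set2` object.
#' @return A tibble with one row per feature and logical truth columns.
#' @export
truth_labels <- function(x) {
  if (inherits(x, "synthetic_set1")) {
    tibble(
      feature = seq_len(x$n_features),
      concordant = seq_len(x$n_features) %in% x$truth_concordant,
      discordant = seq_len(x$n_features) %in% x$truth_discordant
    )
  } else if (inherits(x, "synthetic_set2")) {
    f <- seq_len(x$n_features)
    tibble(
      feature = f,
      x_concordant = f %in% x$truth_x_concordant,
      x_discordant = f %in% x$truth_x_discordant,
      xp_concordant = f %in% x$truth_xp_concordant,
      xp_discordant = f %in% x$truth_xp_discordant
    )
  } else {
    abort("`x` must be a synthetic benchmark set")
  }
}
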