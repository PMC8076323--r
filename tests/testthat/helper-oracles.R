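# Independent brute-force oracles used to check the package's fast paths.

# step-up FDR adjustment, O(m^2): for each p, take the smallest
# min(1, m * p_(k) / k) over all ranks k at or above its own rank
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    vals <- numeric(0)
    for (k in rank_i:m) {
      vals <- c(vals, min(1, m * p[ord[k]] / k))
    }
    adj[i] <- min(vals)
  }
  adj
}

# Eq.-style quadruple/quintuple loop for the pair kernel
pair_kernel_oracle <- function(x, y) {
  n_time <- ncol(x)
  n_cond <- dim(y)[3]
  k <- array(0, c(n_time, n_cond, n_time, n_cond))
  for (t in 1:n_time) for (j in 1:n_cond) {
    for (tp in 1:n_time) for (jp in 1:n_cond) {
      s <- 0
      for (tpp in 1:n_time) {
        s <- s + sum(x[, t] * x[, tpp]) * sum(y[, tpp, j] * y[, tp, jp])
      }
      k[t, j, tp, jp] <- s
    }
  }
  k
}

# six-index loop for the dual kernel; `strict` mirrors the asymmetric
# cross-product variant
dual_kernel_oracle <- function(a, b, strict = FALSE) {
  n_time <- dim(a)[2]
  n_cond <- dim(a)[3]
  k <- array(0, c(n_time, n_cond, n_cond, n_time, n_cond, n_cond))
  for (j in 1:n_time) for (k1 in 1:n_cond) for (k2 in 1:n_cond) {
    for (jp in 1:n_time) for (kp1 in 1:n_cond) for (kp2 in 1:n_cond) {
      s <- 0
      for (jpp in 1:n_time) {
        second <- if (strict) {
          sum(b[, jpp, kp1] * a[, jp, kp2])
        } else {
          sum(b[, jpp, kp1] * b[, jp, kp2])
        }
        s <- s + sum(a[, j, k1] * a[, jpp, k2]) * second
      }
      k[j, k1, k2, jp, kp1, kp2] <- s
    }
  }
  k
}

# conditional MLE of the odds ratio by direct 1-D maximization of the
# noncentral hypergeometric log-likelihood (margins fixed)
fisher_or_oracle <- function(tab) {
  x <- tab[2, 2]
  m1 <- sum(tab[, 2])   # column-A selected margin
  m2 <- sum(tab[, 1])
  n2 <- sum(tab[2, ])   # row-B selected margin
  support <- max(0, n2 - m2):min(n2, m1)
  if (x == min(support)) return(0)
  if (x == max(support)) return(Inf)
  loglik <- function(log_psi) {
    lp <- lchoose(m1, support) + lchoose(m2, n2 - support) +
      support * log_psi
    lp_x <- lchoose(m1, x) + lchoose(m2, n2 - x) + x * log_psi
    lp_x - (max(lp) + log(sum(exp(lp - max(lp)))))
  }
  exp(stats::optimize(loglik, c(-25, 25), maximum = TRUE)$maximum)
}

# two-sided exact P by enumerating all tables with the observed margins
# and summing central-hypergeometric probabilities <= the observed one
fisher_p_oracle <- function(tab) {
  x <- tab[2, 2]
  m1 <- sum(tab[, 2])
  m2 <- sum(tab[, 1])
  n2 <- sum(tab[2, ])
  support <- max(0, n2 - m2):min(n2, m1)
  probs <- stats::dhyper(support, m1, m2, n2)
  p_obs <- stats::dhyper(x, m1, m2, n2)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# full contraction of a core with its factors, written as plain nested
# sums over a (small) 3-way case
reconstruct_oracle_3 <- function(core, factors) {
  d <- vapply(factors, nrow, integer(1))
  r <- dim(core)
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    s <- 0
    for (a in 1:r[1]) for (b in 1:r[2]) for (cc in 1:r[3]) {
      s <- s + core[a, b, cc] * factors[[1]][i, a] *
        factors[[2]][j, b] * factors[[3]][k, cc]
    }
    out[i, j, k] <- s
  }
  out
}
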