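# Shared fixtures built in code at test time.

# Planted tensor with unequal block amplitudes. Unlike the benchmark
# generator (equal-strength blocks, whose leading factor pair is only
# determined up to rotation), the asymmetry makes the decomposition's
# block assignment deterministic, which is what workflow unit tests
# need.
asymmetric_planted_tensor <- function(n_features = 300, n_signal = 8,
                                      n_time = 4, noise_sd = 0.2,
                                      amp_concordant = 1.6,
                                      amp_discordant = 1) {
  x <- array(rnorm(n_features * n_time * 2, 0, noise_sd),
             c(n_features, n_time, 2))
  con <- seq_len(n_signal)
  dis <- n_signal + seq_len(n_signal)
  for (j in seq_len(n_time)) {
    x[con, j, ] <- x[con, j, ] + amp_concordant * j
    x[dis, j, 1] <- x[dis, j, 1] + amp_discordant * j
    x[dis, j, 2] <- x[dis, j, 2] - amp_discordant * j
  }
  list(tensor = x, truth_concordant = con, truth_discordant = dis)
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_intervals <- function(n, max_pos = 1e5) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  width <- sample.int(5e4, n, replace = TRUE)
  tibble::tibble(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start,
    end = start + width,
    value = round(stats::runif(n, 0, 10), 3)
  )
}

as_plain <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

as_vector_plain <- function(x) as.vector(as_plain(x))
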