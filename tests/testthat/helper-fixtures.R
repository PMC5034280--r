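# Shared fixtures, built in code.

# Small synthetic experiment reused across test files.
small_config <- function(seed = 42, n_genes = 30, ...) {
  sim_config(n_genes = n_genes, seed = seed, ...)
}

small_sim_cache <- new.env(parent = emptyenv())
small_sim <- function() {
  if (is.null(small_sim_cache$sim))
    small_sim_cache$sim <- simulate_mnase(small_config())
  small_sim_cache$sim
}

# Hand-built occupancy track from explicit per-chromosome vectors.
toy_track <- function(values, total_fragments = length(values) * 10,
                      condition = "toy", normalization = "genome_mean_one") {
  if (!is.list(values)) values <- list(chr1 = values)
  structure(list(cov = values,
                 chrom_sizes = vapply(values, length, numeric(1)),
                 condition = condition, bandwidth = 20,
                 normalization = normalization,
                 total_fragments = total_fragments,
                 genome_length = sum(vapply(values, length, numeric(1)))),
            class = "occ_track")
}

# A smooth Gaussian bump as a track segment.
bump <- function(len, center, height = 1, sd = 20) {
  height * exp(-((seq_len(len) - 1 - center)^2) / (2 * sd^2))
}

# BED6 fragment data.frame from starts/ends.
make_frags <- function(start, end, chrom = "chr1") {
  n <- length(start)
  data.frame(chrom = rep_len(chrom, n), start = as.integer(start),
             end = as.integer(end), name = sprintf("f%d", seq_len(n)),
             score = rep(0L, n), strand = rep("+", n),
             stringsAsFactors = FALSE)
}

# Independent brute-force oracles -------------------------------------------

# chi-square via expected counts, sum((O-E)^2 / E)
oracle_chisq <- function(a, b, c, d) {
  O <- matrix(as.numeric(c(a, b, c, d)), 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# BH by the min-over-suffix definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided rank-sum p by exhaustive enumeration over assignments
oracle_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(n, na)
  w_all <- apply(idx, 2, function(i) sum(r[i]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
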