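# Shared test utilities: canonical edge-set comparison, brute-force oracles,
# binomial confidence intervals.

# Canonical unordered representation of a stream's edge set.
edge_key <- function(mat) {
  if (nrow(mat) == 0L) return(character(0))
  paste(pmin(mat[, 1], mat[, 2]), pmax(mat[, 1], mat[, 2]), sep = "-")
}
edge_set <- function(stream) sort(edge_key(stream_edges(stream)))

# All unordered pairs of 0..n-1, lexicographic (independent enumeration).
all_pairs <- function(n) {
  if (n < 2) return(matrix(numeric(0), 0, 2))
  t(utils::combn(0:(n - 1), 2))
}

# Brute-force oracle: the unordered pairs that are NOT ring-lattice edges,
# by circular-distance enumeration (independent of the index bijection).
brute_nonlattice_pairs <- function(n, k) {
  ap <- all_pairs(n)
  d <- pmin((ap[, 2] - ap[, 1]) %% n, (ap[, 1] - ap[, 2]) %% n)
  ap[d > k / 2, , drop = FALSE]
}

# Half-width of the two-sided 99% normal-approximation CI for a proportion.
ci99_half <- function(p, reps) stats::qnorm(0.995) * sqrt(p * (1 - p) / reps)

expect_in_ci99 <- function(phat, p, reps) {
  expect_lt(abs(phat - p), ci99_half(p, reps))
}

# Chi-square goodness-of-fit of observed counts against Binomial(size, p),
# pooling tail bins so every expected count is at least 5.
chisq_binom_pvalue <- function(draws, size, p) {
  probs <- stats::dbinom(0:size, size, p)
  obs <- tabulate(draws + 1L, nbins = size + 1)
  reps <- length(draws)
  # pool consecutive bins until each pooled bin has expected count >= 5
  pooled_obs <- c(); pooled_exp <- c()
  acc_o <- 0; acc_e <- 0
  for (i in seq_along(probs)) {
    acc_o <- acc_o + obs[i]
    acc_e <- acc_e + probs[i] * reps
    if (acc_e >= 5) {
      pooled_obs <- c(pooled_obs, acc_o); pooled_exp <- c(pooled_exp, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0) {  # fold the remainder into the last bin
    pooled_obs[length(pooled_obs)] <- pooled_obs[length(pooled_obs)] + acc_o
    pooled_exp[length(pooled_exp)] <- pooled_exp[length(pooled_exp)] + acc_e
  }
  stat <- sum((pooled_obs - pooled_exp)^2 / pooled_exp)
  stats::pchisq(stat, df = length(pooled_obs) - 1, lower.tail = FALSE)
}

# Rebuild a stream over an already-materialized edge matrix.
stream_from_matrix_test <- function(n, mat) streamnet:::stream_from_matrix(n, mat)
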