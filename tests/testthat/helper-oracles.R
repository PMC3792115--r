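# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force truncated series via stats::dbinom,
# posterior grids normalized directly.

# Z = sum_n prod_i Binom(k_i | n, r_i), truncated where the geometric tail
# is far below the target precision.
brute_normalizer <- function(counts, fractions, tail = 1e-16) {
  x <- prod(1 - fractions)
  K <- sum(counts)
  k_max <- max(counts)
  n_hi <- k_max + qnbinom(tail, size = K + 1, prob = 1 - x, lower.tail = FALSE) + 50
  n <- k_max:n_hi
  lw <- rowSums(vapply(
    seq_along(counts),
    function(i) dbinom(counts[i], n, fractions[i], log = TRUE),
    numeric(length(n))
  ))
  sum(exp(lw))
}

# Product-then-normalize posterior on an explicit grid (with replacement).
brute_posterior_with <- function(counts, fractions, n) {
  lw <- rowSums(vapply(
    seq_along(counts),
    function(i) dbinom(counts[i], n, fractions[i], log = TRUE),
    numeric(length(n))
  ))
  w <- exp(lw - max(lw))
  w / sum(w)
}

# Seeded random probability vector on a contiguous support, as a minimal
# discrete_posterior-shaped data frame for the divergence functions.
random_pmf <- function(len, start = 0) {
  w <- stats::rexp(len)
  tibble::tibble(n = start:(start + len - 1), prob = w / sum(w))
}
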