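#' Exact semi-infinite normalizer under sampling with replacement
#'
#' Evaluates `Z = sum_{n >= max(k_i)} prod_i choose(n, k_i) r_i^{k_i}
#' (1 - r_i)^{n - k_i}` — the normalizing constant of the with-replacement
#' posterior in the unbounded-prior limit — without summing over `n`.
#'
#' The product of binomial coefficients is reduced to a linear combination of
#' single coefficients by repeated application of
#' `choose(n, a) * choose(n, b) =
#'   sum_j choose(n, a + b - j) * choose(a + b - j, b) * choose(b, j)`
#' for `j = 0..min(a, b)`. Every resulting order `c` satisfies
#' `max(k_i) <= c <= K`, so each term closes with the geometric-series
#' identity `sum_{n >= c} choose(n, c) x^(n - c) = (1 - x)^(-(c + 1))` where
#' `x = prod_i (1 - r_i)`. The cost is polynomial in `prod_i (k_i + 1)` and
#' independent of any support bound. Coefficients are accumulated in log
#' space.
#'
#' @param data A [sample_counts()] object with `with_replacement = TRUE`.
#' @param log Return `log(Z)` instead of `Z`?
#' @return The normalizing constant (a positive real), or its log.
#' @examples
#' # single measurement: the series is a negative binomial sum, Z = 1 / r
#' semiinf_normalizer(sample_counts(3, 0.25, with_replacement = TRUE))
#' @export
semiinf_normalizer <- function(data, log = FALSE) {
  data <- as_sample_counts(data, with_replacement = TRUE)
  counts <- data$count
  fractions <- data$fraction
  if (any(fractions == 1)) {
    # (1 - r_i)^(n - k_i) truncates the series at n = max(k_i)
    lz <- log_weights_with_replacement(max(counts), counts, fractions)
    return(if (log) lz else exp(lz))
  }
  lx <- sum(log1p(-fractions))                        # log x, x in (0, 1)
  coef <- list(c = counts[1], la = 0)                 # log-coefficients of choose(n, c)
  for (i in seq_along(counts)[-1]) {
    coef <- combine_log_coeffs(coef, counts[i])
  }
  lc0 <- sum(counts * log(fractions) - counts * log1p(-fractions))
  lz <- lc0 + logsumexp(coef$la + coef$c * lx - (coef$c + 1) * log1p(-exp(lx)))
  if (log) lz else exp(lz)
}

# Multiply a linear combination sum_c exp(la_c) choose(n, c) by choose(n, b),
# re-expressing the result in the same basis via the product identity.
combine_log_coeffs <- function(coef, b) {
  cs <- coef$c
  la <- coef$la
  pieces_c <- vector("list", length(cs))
  pieces_l <- vector("list", length(cs))
  for (i in seq_along(cs)) {
    a <- cs[i]
    j <- 0:min(a, b)
    pieces_c[[i]] <- a + b - j
    pieces_l[[i]] <- la[i] + lchoose(a + b - j, b) + lchoose(b, j)
  }
  all_c <- unlist(pieces_c)
  all_l <- unlist(pieces_l)
  agg <- vapply(split(all_l, all_c), logsumexp, numeric(1))
  out_c <- as.integer(names(agg))
  ord <- order(out_c)
  list(c = out_c[ord], la = unname(agg)[ord])
}
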