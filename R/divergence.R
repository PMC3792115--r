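#' Kullback-Leibler and Jensen-Shannon divergence between discrete posteriors
#'
#' `kl_divergence()` computes `sum_i p_i log2(p_i / q_i)` in bits, with the
#' conventions `0 * log(0 / q) = 0` and `+Inf` whenever `p_i > 0` where
#' `q_i = 0`; the two distributions must live on identical supports.
#' `js_divergence()` is the symmetrized, always-finite form
#' `JS = KL(p || a) / 2 + KL(q || a) / 2` with `a = (p + q) / 2`; in bits it
#' lies in `[0, 1]`, is zero iff the distributions are equal, and reaches 1
#' for disjoint supports. Posteriors on different grids are first aligned to
#' the contiguous union grid with zero padding.
#'
#' @param p,q `discrete_posterior` objects, or data frames with columns `n`
#'   and `prob`.
#' @return Divergence in bits.
#' @examples
#' a <- compute_posterior(sample_counts(5, 0.3), unbounded = TRUE)
#' b <- compute_posterior(sample_counts(5, 0.3, with_replacement = TRUE),
#'                        unbounded = TRUE)
#' js_divergence(a, b)
#' @export
kl_divergence <- function(p, q) {
  if (!identical(as.numeric(p$n), as.numeric(q$n))) {
    stop_domain("`p` and `q` must share an identical support; see js_divergence() for auto-alignment.")
  }
  pp <- p$prob
  qq <- q$prob
  pos <- pp > 0
  if (any(pos & qq == 0)) return(Inf)
  sum(pp[pos] * (log2(pp[pos]) - log2(qq[pos])))
}

#' @rdname kl_divergence
#' @export
js_divergence <- function(p, q) {
  al <- align_posteriors(p, q)
  a <- (al$p + al$q) / 2
  js <- kl_terms_bits(al$p, a) / 2 + kl_terms_bits(al$q, a) / 2
  # clamp fp noise; analytically 0 <= JS <= 1 bit
  min(max(js, 0), 1)
}

kl_terms_bits <- function(pp, aa) {
  pos <- pp > 0
  sum(pp[pos] * (log2(pp[pos]) - log2(aa[pos])))
}

#' Align two discrete posteriors on their union support
#'
#' @param p,q Data frames with columns `n` and `prob`.
#' @return A list with the contiguous union grid `n` and zero-padded
#'   probability vectors `p` and `q`.
#' @export
align_posteriors <- function(p, q) {
  n <- min(p$n, q$n):max(p$n, q$n)
  pad <- function(d) {
    v <- numeric(length(n))
    v[match(d$n, n)] <- d$prob
    v
  }
  list(n = n, p = pad(p), q = pad(q))
}

#' Kolmogorov-Smirnov statistic between two discrete posteriors
#'
#' The maximum absolute difference between the two posterior CDFs on the
#' aligned union grid. Reported for descriptive comparison only.
#'
#' @inheritParams kl_divergence
#' @return The KS statistic in `[0, 1]`.
#' @export
ks_statistic <- function(p, q) {
  al <- align_posteriors(p, q)
  max(abs(cumsum(al$p) - cumsum(al$q)))
}
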