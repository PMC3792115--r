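#' Summarize a discrete posterior
#'
#' Point estimate, credible interval, tail probabilities and moments of a
#' posterior distribution of the population size.
#'
#' The point estimate is the maximum a posteriori (MAP); exact ties of the
#' posterior mode (which occur whenever the mode ratio equals 1, e.g. a
#' single measurement with `k = 4`, `r = 0.1`) are broken toward the smallest
#' support value. The default credible interval is equal-tailed, read off the
#' discrete CDF with outward (conservative) rounding, so the covered mass is
#' always at least `level`; `interval = "hpd"` instead accumulates support
#' values by decreasing probability until `level` is reached and reports
#' their range. Reported tail probabilities are the realized posterior mass
#' strictly below and strictly above the interval.
#'
#' @param post A `discrete_posterior` (see [compute_posterior()]).
#' @param level Credibility level in `(0, 1)`; default `0.95`.
#' @param interval `"equal_tailed"` (default) or `"hpd"`.
#' @return A one-row tibble of class `posterior_summary` with columns `map`,
#'   `ci_lower`, `ci_upper`, `level`, `tail_lower`, `tail_upper`, `mean`,
#'   `variance`, plus the provenance columns `K`, `R`, `n1`, `n2`, `scheme`
#'   when the posterior carries them.
#' @examples
#' post <- compute_posterior(sample_counts(4, 0.1, with_replacement = TRUE),
#'                           unbounded = TRUE)
#' posterior_summary(post)
#' @export
posterior_summary <- function(post, level = 0.95,
                              interval = c("equal_tailed", "hpd")) {
  if (!inherits(post, "discrete_posterior")) {
    stop_domain("`post` must be a discrete_posterior.")
  }
  interval <- match.arg(interval)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop_domain("`level` must be a single number in (0, 1).")
  }
  n <- post$n
  p <- post$prob

  # mode, ties (within fp noise of the max) broken toward the smallest n
  p_max <- max(p)
  map <- n[which(p >= p_max * (1 - 1e-9))][1]

  alpha <- 1 - level
  below <- cumsum(p) - p                    # P(X < n_i)
  above <- rev(cumsum(rev(p))) - p          # P(X > n_i)
  eps <- 1e-12
  if (interval == "equal_tailed") {
    i_lo <- max(which(below <= alpha / 2 + eps))
    i_hi <- min(which(above <= alpha / 2 + eps))
  } else {
    ord <- order(p, n, decreasing = c(TRUE, FALSE), method = "radix")
    take <- ord[seq_len(which(cumsum(p[ord]) >= level - eps)[1])]
    i_lo <- min(take)
    i_hi <- max(take)
  }
  # keep the MAP inside the interval (can matter for heavily tied pmfs)
  i_lo <- min(i_lo, which(n == map))
  i_hi <- max(i_hi, which(n == map))

  mu <- sum(p * n)
  out <- tibble(
    map = map,
    ci_lower = n[i_lo],
    ci_upper = n[i_hi],
    level = level,
    tail_lower = below[i_lo],
    tail_upper = above[i_hi],
    mean = mu,
    variance = sum(p * (n - mu)^2)
  )
  out$K <- attr(post, "K") %||% NA_real_
  out$R <- attr(post, "R") %||% NA_real_
  out$n1 <- attr(post, "n1") %||% NA_real_
  out$n2 <- attr(post, "n2") %||% NA_real_
  out$scheme <- attr(post, "scheme") %||% NA_character_
  class(out) <- c("posterior_summary", class(out))
  out
}

#' @method glance discrete_posterior
#' @export
glance.discrete_posterior <- function(x, level = 0.95, ...) {
  posterior_summary(x, level = level)
}

#' Posterior mean and variance
#'
#' @param post A `discrete_posterior`.
#' @return A length-2 numeric vector `c(mean, variance)` computed from the
#'   probability vector.
#' @export
posterior_moments <- function(post) {
  mu <- sum(post$prob * post$n)
  c(mean = mu, variance = sum(post$prob * (post$n - mu)^2))
}
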