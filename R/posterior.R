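#' Binomial probability of a count given population size and fraction
#'
#' The count model: sampling a fraction `r` of a volume containing `n`
#' homogeneously dispersed objects yields `k` of them with probability
#' `choose(n, k) r^k (1 - r)^(n - k)` (zero for `k > n`). Evaluated in log
#' space internally.
#'
#' @param k Non-negative integer count(s).
#' @param n Non-negative integer population size(s).
#' @param r Sampling fraction(s) in `[0, 1]`.
#' @param log Return log probabilities?
#' @return Numeric vector of (log) probabilities.
#' @examples
#' binomial_pmf(4, 50, 0.1)
#' @export
binomial_pmf <- function(k, n, r, log = FALSE) {
  if (any(r < 0 | r > 1, na.rm = TRUE)) {
    stop_domain("sampling fraction `r` must lie in [0, 1].")
  }
  if (any(k < 0, na.rm = TRUE) || any(n < 0, na.rm = TRUE)) {
    stop_domain("`k` and `n` must be non-negative.")
  }
  dbinom(k, size = n, prob = r, log = log)
}

new_discrete_posterior <- function(n, prob, log_prob, scheme, K = NA_real_,
                                   R = NA_real_, n1 = NA_real_, n2 = NA_real_) {
  out <- tibble(n = as.numeric(n), prob = prob, log_prob = log_prob)
  class(out) <- c("discrete_posterior", class(out))
  attr(out, "scheme") <- scheme
  attr(out, "K") <- K
  attr(out, "R") <- R
  attr(out, "n1") <- n1
  attr(out, "n2") <- n2
  out
}

#' @export
print.discrete_posterior <- function(x, ...) {
  cat(sprintf(
    "# Posterior of the population size n (%s), support [%g, %g]\n",
    gsub("_", " ", attr(x, "scheme") %||% "unknown scheme"),
    min(x$n), max(x$n)
  ))
  print(as_tibble(unclass_posterior(x)), ...)
  invisible(x)
}

unclass_posterior <- function(x) {
  class(x) <- setdiff(class(x), "discrete_posterior")
  x
}

#' @method tidy discrete_posterior
#' @export
tidy.discrete_posterior <- function(x, ...) {
  as_tibble(unclass_posterior(x))
}

# Tail mass allowed to fall off the materialized grid when the prior support
# is unbounded. Kept an order of magnitude below the 1e-12 the results
# guarantee so that skipping grid renormalization (the exact semi-infinite
# normalizer is used instead) cannot push sums or elementwise values past
# their documented tolerances.
GRID_TAIL <- 1e-13

log_weights_with_replacement <- function(n, counts, fractions) {
  lw <- numeric(length(n))
  for (i in seq_along(counts)) {
    k <- counts[i]
    r <- fractions[i]
    if (r == 1) {
      lw <- lw + ifelse(n == k, 0, -Inf)
    } else {
      lw <- lw + lchoose(n, k) + k * log(r) + (n - k) * log1p(-r)
    }
  }
  lw
}

log_weights_without_replacement <- function(n, K, R) {
  if (R == 1) {
    ifelse(n == K, 0, -Inf)
  } else {
    lchoose(n, K) + K * log(R) + (n - K) * log1p(-R)
  }
}

#' Posterior distribution of the population size
#'
#' Computes the exact posterior of the population size `n` given count
#' measurements on known sampling fractions, under a discrete uniform prior
#' on `[n1, n2]` and a binomial count likelihood.
#'
#' Under sampling **with replacement** each measurement contributes its own
#' binomial factor, so the unnormalized posterior is
#' `prod_i choose(n, k_i) r_i^{k_i} (1 - r_i)^{n - k_i}`. On a bounded support
#' the normalizer is a finite log-space sum; on an unbounded support it is
#' evaluated exactly by [semiinf_normalizer()], which reduces the series over
#' `n` to nested sums over the counts. For a single measurement the unbounded
#' posterior is a negative binomial with parameters `(k + 1, r)` shifted by
#' `k` units.
#'
#' Under sampling **without replacement** the posterior depends on the data
#' only through the total count `K = sum(k_i)` and total fraction
#' `R = sum(r_i)`:
#' `P(n | K, R) proportional to choose(n, K) R^K (1 - R)^(n - K)`; with
#' unbounded support the normalized form is the negative binomial with
#' parameters `(K + 1, R)` shifted by `K`. Any permutation of the
#' measurements, or merging them into a single measurement of `(K, R)`,
#' yields the identical posterior.
#'
#' Unbounded supports are materialized on a finite grid that carries all but
#' less than `1e-12` of the posterior mass.
#'
#' @param data A [sample_counts()] object, or a data frame with columns
#'   `count` and `fraction` (then treated as sampled without replacement).
#' @param support A [prior_support()]; defaults to
#'   [default_prior_support()] applied to `data`.
#' @param n1,n2 Optional scalar overrides of the support ends (`n2 = Inf`
#'   allowed).
#' @param unbounded If `TRUE`, force `n2 = Inf`.
#' @return A tibble of class `discrete_posterior` with columns `n`, `prob`
#'   and `log_prob` (the log-space values are authoritative), carrying
#'   attributes `scheme`, `K`, `R`, `n1`, `n2`.
#' @examples
#' compute_posterior(sample_counts(4, 0.1, with_replacement = TRUE),
#'                   unbounded = TRUE)
#' compute_posterior(sample_counts(c(2, 3), c(0.1, 0.2)))
#' @export
compute_posterior <- function(data, support = NULL, n1 = NULL, n2 = NULL,
                              unbounded = FALSE) {
  data <- as_sample_counts(data, with_replacement = with_replacement(data))
  support <- resolve_support(data, support, n1, n2, unbounded)
  if (with_replacement(data)) {
    posterior_with_replacement(data, support)
  } else {
    posterior_without_replacement(data, support)
  }
}

resolve_support <- function(data, support, n1, n2, unbounded) {
  if (!is.null(support)) {
    if (!inherits(support, "prior_support")) {
      stop_domain("`support` must be a prior_support object.")
    }
    return(support)
  }
  default <- default_prior_support(data)
  lo <- n1 %||% default$n1
  hi <- if (isTRUE(unbounded)) Inf else n2 %||% default$n2
  prior_support(lo, hi)
}

#' Posterior under sampling with replacement
#'
#' @inheritParams compute_posterior
#' @return A `discrete_posterior` tibble.
#' @export
posterior_with_replacement <- function(data, support = NULL) {
  data <- as_sample_counts(data, with_replacement = TRUE)
  support <- support %||% default_prior_support(data)
  counts <- data$count
  fractions <- data$fraction
  k_max <- max(counts)
  K <- total_count(data)
  R <- total_fraction(data)

  if (!is_unbounded(support)) {
    if (support$n2 < k_max) {
      stop_domain(paste0(
        "the prior support lies entirely below max(k_i) = ", k_max,
        ": the posterior is identically zero."
      ))
    }
    n <- support$n1:support$n2
    lw <- log_weights_with_replacement(n, counts, fractions)
    lz <- logsumexp(lw)
    if (!is.finite(lz)) {
      stop_domain("posterior normalizer underflowed; shrink the prior support.")
    }
    lp <- lw - lz
    return(new_discrete_posterior(n, exp(lp), lp, "with_replacement",
                                  K, R, support$n1, support$n2))
  }

  # Unbounded support: exact semi-infinite normalizer, grid carrying all but
  # < GRID_TAIL of the mass. n1 > k_max would re-truncate the series the
  # normalizer already summed, so only n1 <= k_max is supported here.
  if (support$n1 > k_max) {
    stop_domain(paste0(
      "with an unbounded support the lower end must not exceed max(k_i) = ",
      k_max, "; use a bounded support to truncate from below."
    ))
  }
  if (any(fractions == 1)) {
    # the series truncates: (1 - r_i)^(n - k_i) kills every n > k_i
    lw <- log_weights_with_replacement(k_max, counts, fractions)
    if (!is.finite(lw)) {
      stop_domain("measurements with r = 1 disagree; the posterior is identically zero.")
    }
    return(new_discrete_posterior(k_max, 1, 0, "with_replacement",
                                  K, R, support$n1, Inf))
  }
  lz <- semiinf_normalizer(data, log = TRUE)
  x <- exp(sum(log1p(-fractions)))
  n_hi <- k_max + qnbinom(GRID_TAIL / 10, size = K + 1, prob = 1 - x,
                          lower.tail = FALSE) + 10
  repeat {
    n <- k_max:n_hi
    lp <- log_weights_with_replacement(n, counts, fractions) - lz
    mass <- sum(exp(lp))
    if (mass >= 1 - GRID_TAIL) break
    n_hi <- ceiling(n_hi * 1.5) + 50
  }
  new_discrete_posterior(n, exp(lp), lp, "with_replacement",
                         K, R, support$n1, Inf)
}

#' Posterior under sampling without replacement
#'
#' @inheritParams compute_posterior
#' @return A `discrete_posterior` tibble.
#' @export
posterior_without_replacement <- function(data, support = NULL) {
  data <- as_sample_counts(data, with_replacement = FALSE)
  support <- support %||% default_prior_support(data)
  K <- total_count(data)
  R <- total_fraction(data)

  if (!is_unbounded(support)) {
    if (support$n2 < K) {
      stop_domain(paste0(
        "the prior support lies entirely below K = ", K,
        ": the posterior is identically zero."
      ))
    }
    n <- support$n1:support$n2
    lw <- log_weights_without_replacement(n, K, R)
    lz <- logsumexp(lw)
    if (!is.finite(lz)) {
      stop_domain("posterior normalizer underflowed; shrink the prior support.")
    }
    lp <- lw - lz
    return(new_discrete_posterior(n, exp(lp), lp, "without_replacement",
                                  K, R, support$n1, support$n2))
  }

  if (R >= 1) {
    if (R > 1) stop_domain("R > 1 is impossible without replacement.")
    # R == 1: the whole volume was sampled, n = K with certainty
    return(new_discrete_posterior(K, 1, 0, "without_replacement",
                                  K, R, support$n1, Inf))
  }
  if (support$n1 > K) {
    stop_domain(paste0(
      "with an unbounded support the lower end must not exceed K = ", K,
      "; use a bounded support to truncate from below."
    ))
  }
  # normalized closed form: negative binomial (K + 1, R) shifted by K
  n_hi <- K + qnbinom(GRID_TAIL, size = K + 1, prob = R, lower.tail = FALSE)
  n <- K:n_hi
  lp <- dnbinom(n - K, size = K + 1, prob = R, log = TRUE)
  new_discrete_posterior(n, exp(lp), lp, "without_replacement",
                         K, R, support$n1, Inf)
}

#' Sequential-update oracle for sampling without replacement
#'
#' An independently constructed reference implementation used to validate
#' [posterior_without_replacement()]: starting from the uniform prior on the
#' (bounded) support, measurements are absorbed one at a time. Measurement
#' `i` removes a fraction `r_i` of the original volume, i.e. samples a
#' fraction `r_i / (1 - sum_{j<i} r_j)` of the residual volume containing the
#' `n - sum_{j<i} k_j` objects not yet removed; the posterior is multiplied
#' by that binomial likelihood and renormalized. By induction this sequential
#' update collapses to the closed form in `K` and `R`, which the test suite
#' verifies elementwise.
#'
#' @inheritParams compute_posterior
#' @param support A bounded [prior_support()].
#' @return A `discrete_posterior` tibble.
#' @export
sequential_posterior_oracle <- function(data, support) {
  data <- as_sample_counts(data, with_replacement = FALSE)
  if (!inherits(support, "prior_support") || is_unbounded(support)) {
    stop_domain("the sequential oracle requires a bounded prior support.")
  }
  n <- support$n1:support$n2
  lp <- rep(-log(length(n)), length(n))
  removed_k <- 0
  removed_r <- 0
  for (i in seq_len(nrow(data))) {
    k_i <- data$count[i]
    rho_i <- data$fraction[i] / (1 - removed_r)
    if (rho_i >= 1 && !(rho_i == 1 && i == nrow(data))) {
      stop_domain("residual sampling fraction reached 1 before the last measurement.")
    }
    if (rho_i > 1) stop_domain("residual sampling fraction exceeds 1.")
    size <- n - removed_k
    ll <- rep(-Inf, length(n))
    ok <- size >= k_i
    ll[ok] <- dbinom(k_i, size = size[ok], prob = rho_i, log = TRUE)
    lp <- lp + ll
    lz <- logsumexp(lp)
    if (!is.finite(lz)) {
      stop_domain("sequential posterior underflowed on this support.")
    }
    lp <- lp - lz
    removed_k <- removed_k + k_i
    removed_r <- removed_r + data$fraction[i]
  }
  new_discrete_posterior(n, exp(lp), lp, "without_replacement",
                         total_count(data), total_fraction(data),
                         support$n1, support$n2)
}
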