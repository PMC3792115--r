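#' Simulate count measurements from a known population
#'
#' Generates measurements with exactly the statistical structure the
#' inference assumes: `n_true` identical objects homogeneously dispersed in a
#' unit volume, from which fractions are sampled and the objects therein
#' counted.
#'
#' With replacement every `k_i` is an independent
#' `Binomial(n_true, r_i)` draw. Without replacement the draws are
#' sequential: `k_i` is binomial with the `n_true - sum_{j<i} k_j` remaining
#' objects as trials and the residual fraction `r_i / (1 - sum_{j<i} r_j)` as
#' success probability — equivalently (and by default) the whole vector
#' `(k_1, ..., k_m)` is one multinomial allocation of `n_true` objects to the
#' cells `(r_1, ..., r_m, 1 - R)`. Both constructions are implemented and
#' agree in distribution.
#'
#' @param n_true True population size (positive integer).
#' @param fractions Sampling fractions in `(0, 1]`; must sum to at most 1
#'   without replacement.
#' @param with_replacement Sampling scheme; default `FALSE`.
#' @param replicates Number of independent measurement sets.
#' @param seed Optional integer seed for reproducibility.
#' @param method Without-replacement construction: `"multinomial"` (default)
#'   or `"sequential"`.
#' @return A tibble with columns `replicate`, `count`, `fraction`, carrying
#'   attributes `n_true` and `with_replacement`. Use [counts_for_replicate()]
#'   to extract one replicate as a [sample_counts()] object.
#' @examples
#' simulate_counts(500, c(0.01, 0.01), replicates = 3, seed = 1)
#' @export
simulate_counts <- function(n_true, fractions, with_replacement = FALSE,
                            replicates = 1, seed = NULL,
                            method = c("multinomial", "sequential")) {
  method <- match.arg(method)
  if (!is_whole(n_true) || n_true < 1) stop_domain("`n_true` must be a positive integer.")
  if (any(fractions <= 0 | fractions > 1)) stop_domain("fractions must lie in (0, 1].")
  R <- sum(fractions)
  if (!with_replacement && R > 1 + 1e-12) {
    stop_domain("without replacement the fractions must sum to at most 1.")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- length(fractions)

  if (with_replacement) {
    k <- vapply(fractions, function(r) rbinom(replicates, n_true, r),
                numeric(replicates))
  } else if (method == "multinomial") {
    cells <- c(fractions, max(0, 1 - R))
    k <- t(rmultinom(replicates, n_true, cells))[, seq_len(m), drop = FALSE]
  } else {
    k <- matrix(0, replicates, m)
    left_k <- rep(n_true, replicates)
    left_r <- 1
    for (i in seq_len(m)) {
      rho <- min(fractions[i] / left_r, 1)
      k[, i] <- rbinom(replicates, left_k, rho)
      left_k <- left_k - k[, i]
      left_r <- left_r - fractions[i]
    }
  }
  k <- matrix(k, nrow = replicates)

  out <- tibble(
    replicate = rep(seq_len(replicates), each = m),
    count = as.numeric(t(k)),
    fraction = rep(fractions, times = replicates)
  )
  attr(out, "n_true") <- n_true
  attr(out, "with_replacement") <- with_replacement
  out
}

#' @rdname simulate_counts
#' @param sims A tibble from [simulate_counts()].
#' @param i Replicate index.
#' @export
counts_for_replicate <- function(sims, i) {
  rows <- sims[sims$replicate == i, , drop = FALSE]
  if (nrow(rows) == 0) stop_domain("no such replicate.")
  sample_counts(rows$count, rows$fraction,
                with_replacement = isTRUE(attr(sims, "with_replacement")))
}

#' Credible-interval coverage under repeated sampling
#'
#' Simulates `replicates` measurement sets from a known `n_true`, runs the
#' full inference pipeline on each (default prior support, matching-scheme
#' posterior, equal-tailed interval) and reports how often the
#' `level`-credible interval contains the truth. Because the discrete
#' intervals are rounded outward, realized coverage is at least nominal up to
#' Monte Carlo error.
#'
#' @inheritParams simulate_counts
#' @param level Credibility level of the interval.
#' @return A one-row tibble with `n_true`, `level`, `replicates`, `covered`
#'   (count) and `coverage` (rate), plus the median MAP across replicates.
#' @examples
#' coverage_experiment(500, c(0.01, 0.01), replicates = 50, seed = 1)
#' @export
coverage_experiment <- function(n_true, fractions, with_replacement = FALSE,
                                level = 0.95, replicates = 2000, seed = NULL) {
  sims <- simulate_counts(n_true, fractions, with_replacement,
                          replicates = replicates, seed = seed)
  m <- length(fractions)
  counts <- matrix(sims$count, nrow = m)
  covered <- logical(replicates)
  maps <- numeric(replicates)
  for (i in seq_len(replicates)) {
    dat <- sample_counts(counts[, i], fractions,
                         with_replacement = with_replacement)
    post <- compute_posterior(dat)
    s <- posterior_summary(post, level = level)
    covered[i] <- s$ci_lower <= n_true && n_true <= s$ci_upper
    maps[i] <- s$map
  }
  n_covered <- sum(covered)
  tibble(
    n_true = n_true,
    scheme = if (with_replacement) "with_replacement" else "without_replacement",
    level = level,
    replicates = replicates,
    covered = n_covered,
    coverage = n_covered / replicates,
    median_map = stats::median(maps)
  )
}

#' Synthetic dilution-series time course
#'
#' Emulates a plate-count survival experiment: a population decaying
#' exponentially from `n0` at rate `decay_rate` per day is enumerated at each
#' time point by plating `replicates` technical replicates at one dilution of
#' a log10 ladder, chosen as the largest fraction keeping the expected count
#' at or below `max_expected` (the countable-plate convention). Late time
#' points therefore land in the low-count / high-sampling-fraction regime.
#' Sampling is without replacement within a time point.
#'
#' @param n0 Initial population size at inoculation.
#' @param decay_rate Exponential decay rate per day.
#' @param times Sampling days.
#' @param replicates Technical replicates per time point.
#' @param max_expected Target upper bound on the expected plate count.
#' @param seed Optional integer seed.
#' @return A tibble with columns `time`, `replicate`, `count`, `fraction`,
#'   and a `truth` attribute holding the tibble of true sizes per time point.
#' @examples
#' dilution_series(seed = 1)
#' @export
dilution_series <- function(n0 = 1e6, decay_rate = 0.39,
                            times = c(0, 3, 7, 14, 21, 28),
                            replicates = 5, max_expected = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ladder <- c(10^-(7:1), 0.19)   # 0.19 keeps 5 replicates below R = 1
  rows <- purrr::map(times, function(t) {
    n_t <- max(1, round(n0 * exp(-decay_rate * t)))
    ok <- ladder[n_t * ladder <= max_expected]
    r <- if (length(ok) > 0) max(ok) else min(ladder)
    sims <- simulate_counts(n_t, rep(r, replicates), with_replacement = FALSE,
                            replicates = 1)
    tibble(time = t, replicate = seq_len(replicates),
           count = sims$count, fraction = sims$fraction, n_true = n_t)
  })
  out <- dplyr::bind_rows(rows)
  truth <- dplyr::distinct(out[c("time", "n_true")])
  out$n_true <- NULL
  attr(out, "truth") <- truth
  out
}
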