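#' Discrete uniform prior support
#'
#' The prior on the population size `n` is the discrete uniform distribution
#' on the integer interval `[n1, n2]` — the maximum-entropy prior on a finite
#' discrete support (principle of indifference). `n2 = Inf` denotes the
#' improper limit of a sequence of widening uniform priors; the resulting
#' posterior is still proper whenever the likelihood decays geometrically,
#' which holds with replacement whenever all `r_i < 1` and without
#' replacement whenever `R < 1`.
#'
#' @param n1,n2 Non-negative integers with `n1 <= n2`; `n2` may be `Inf` for
#'   the unbounded (improper-prior) limit.
#' @return A list of class `prior_support` with elements `n1` and `n2`.
#' @examples
#' prior_support(0, 500)
#' prior_support(4, Inf)
#' @export
prior_support <- function(n1, n2) {
  if (length(n1) != 1L || length(n2) != 1L || is.na(n1) || is.na(n2)) {
    stop_domain("`n1` and `n2` must be single non-missing values.")
  }
  if (!is_whole(n1) || n1 < 0) stop_domain("`n1` must be a non-negative integer.")
  if (!is.infinite(n2) && (!is_whole(n2) || n2 < 0)) {
    stop_domain("`n2` must be a non-negative integer or Inf.")
  }
  if (n2 < n1) stop_domain("`n1 <= n2` is required.")
  structure(list(n1 = as.numeric(round(n1)), n2 = if (is.infinite(n2)) Inf else as.numeric(round(n2))),
            class = "prior_support")
}

#' @rdname prior_support
#' @param x Object to test.
#' @export
is_unbounded <- function(x) {
  stopifnot(inherits(x, "prior_support"))
  is.infinite(x$n2)
}

#' @export
print.prior_support <- function(x, ...) {
  cat(sprintf("<prior_support> discrete uniform on [%g, %s]\n",
              x$n1, if (is_unbounded(x)) "Inf" else format(x$n2)))
  invisible(x)
}

#' Default prior support for a measurement set
#'
#' Chooses a support interval for the discrete uniform prior wide enough that
#' the truncation is immaterial: the lower end is the smallest population
#' size with non-zero likelihood (`K` without replacement, `max(k_i)` with
#' replacement), the upper end is ten times the maximum likelihood estimate
#' `n_ML = round(K / R)`. Posterior mass beyond `10 * n_ML` is negligible for
#' any `K >= 0`. When no object was observed (`K = 0`) the support is
#' `[0, ceiling(10 / R)]`. The upper end is never closer than 10 to the lower
#' end. Users can override the defaults with explicit `n1` / `n2` in
#' [compute_posterior()].
#'
#' @param data A [sample_counts()] object (or coercible data frame).
#' @return A [prior_support()].
#' @examples
#' default_prior_support(sample_counts(c(5, 3), c(0.01, 0.02)))
#' @export
default_prior_support <- function(data) {
  data <- as_sample_counts(data, with_replacement = with_replacement(data))
  K <- total_count(data)
  R <- total_fraction(data)
  if (R <= 0) stop_domain("total sampling fraction R must be positive.")
  if (K == 0) {
    n1 <- 0
    n2 <- ceiling(10 / R)
  } else {
    n1 <- if (with_replacement(data)) max(data$count) else K
    n_ml <- round(K / R)
    n2 <- ceiling(10 * n_ml)
  }
  prior_support(n1, max(n2, n1 + 10))
}
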