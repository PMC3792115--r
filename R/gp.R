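#' Gamma-Poisson (GP) reference posterior
#'
#' The conjugate alternative to the discrete-uniform framework: counts are
#' modelled as Poisson with rate `lambda = r * n` and the prior on `n` is
#' `Gamma(kappa, rho)`. The posterior is then `Gamma(kappa + K, rho + R)`
#' with `K = sum(k_i)` and `R = sum(r_i)` — a continuous approximation to the
#' integer population size. `rho = 0` is the improper limit, which yields a
#' proper posterior whenever `R > 0`; as `R -> 0` with `kappa = 1`, `rho = 0`
#' this posterior converges to the discrete without-replacement posterior.
#'
#' @param K Total count (non-negative).
#' @param R Total sampling fraction (positive).
#' @param kappa Prior shape (> 0); default 1.
#' @param rho Prior rate (>= 0); default `1e-6`, a near-flat prior.
#' @return An object of class `gamma_posterior`: a list with `shape` and
#'   `rate` (posterior mean `shape / rate`, variance `shape / rate^2`).
#' @examples
#' gamma_posterior(K = 5, R = 0.25, kappa = 1, rho = 0)
#' @export
gamma_posterior <- function(K, R, kappa = 1, rho = 1e-6) {
  if (!is.numeric(K) || length(K) != 1L || K < 0 || !is_whole(K)) {
    stop_domain("`K` must be a single non-negative integer.")
  }
  if (!is.numeric(R) || length(R) != 1L || R < 0) {
    stop_domain("`R` must be a single non-negative number.")
  }
  if (kappa <= 0) stop_domain("prior shape `kappa` must be positive.")
  if (rho < 0) stop_domain("prior rate `rho` must be non-negative.")
  if (rho == 0 && R == 0) {
    stop_domain("with an improper prior (rho = 0) a positive total fraction R is required.")
  }
  structure(
    list(shape = kappa + K, rate = rho + R, kappa = kappa, rho = rho, K = K, R = R),
    class = "gamma_posterior"
  )
}

#' @export
print.gamma_posterior <- function(x, ...) {
  cat(sprintf(
    "<gamma_posterior> Gamma(shape = %g, rate = %g); mean %g, variance %g\n",
    x$shape, x$rate, x$shape / x$rate, x$shape / x$rate^2
  ))
  invisible(x)
}

#' @method glance gamma_posterior
#' @export
glance.gamma_posterior <- function(x, ...) {
  tibble(
    shape = x$shape, rate = x$rate,
    mean = x$shape / x$rate, variance = x$shape / x$rate^2,
    kappa = x$kappa, rho = x$rho, K = x$K, R = x$R
  )
}

#' Discretize a Gamma posterior onto an integer grid
#'
#' Evaluates the Gamma density at each integer of `support` and renormalizes
#' to a probability vector. Needed because the GP posterior is continuous
#' while divergence comparisons require a common discrete support.
#'
#' @param gp A [gamma_posterior()].
#' @param support Integer vector (ascending) on which to discretize; defaults
#'   to a grid carrying all but `1e-13` of the Gamma mass.
#' @return A `discrete_posterior` tibble with attribute
#'   `scheme = "gamma_poisson"`.
#' @examples
#' discretize_gamma(gamma_posterior(5, 0.25, rho = 0), 0:500)
#' @export
discretize_gamma <- function(gp, support = NULL) {
  stopifnot(inherits(gp, "gamma_posterior"))
  if (is.null(support)) {
    hi <- ceiling(qgamma(GRID_TAIL, gp$shape, gp$rate, lower.tail = FALSE))
    support <- 0:max(hi, 10)
  }
  if (length(support) == 0) stop_domain("`support` must be non-empty.")
  ld <- dgamma(support, shape = gp$shape, rate = gp$rate, log = TRUE)
  lz <- logsumexp(ld)
  if (!is.finite(lz)) {
    stop_domain("the Gamma density underflows everywhere on this grid; widen the support.")
  }
  lp <- ld - lz
  new_discrete_posterior(support, exp(lp), lp, "gamma_poisson",
                         K = gp$K, R = gp$R,
                         n1 = min(support), n2 = max(support))
}
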