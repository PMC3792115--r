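#' Divergence between the two sampling schemes across (K, R)
#'
#' For each pair of a total count `K` and a total sampling fraction `R`, the
#' scan splits the data into `m` measurements with equal fractions `R / m`
#' and near-equal counts (differing by at most 1, ordered descending),
#' computes the posterior of `n` under sampling with and without replacement
#' on unbounded supports, and records their Jensen-Shannon divergence in
#' bits. The with-replacement posterior depends on the individual `k_i`, so
#' the split matters there; alternative splits can be supplied.
#'
#' The divergence grows with `R`: when the total sampled fraction is small
#' the two schemes are indistinguishable for any practical purpose (below
#' `R = 1/32` the maximum JS divergence over counts drops under `1e-4` bits),
#' while large `R` separates them.
#'
#' @param K_values Integer vector of total counts; default
#'   `c(0, 1, 2, 5, 10, 20, 50, 100)`.
#' @param R_values Numeric vector of total fractions in `(0, 1]`; default
#'   `1/256` to `1/2` by octaves.
#' @param m Number of measurements each total is split into (>= 2).
#' @param split Either `"near_equal"` or a function `(K, m) -> integer
#'   vector` of `m` counts summing to `K`.
#' @return A tibble of class `divergence_grid` with columns `K`, `R`,
#'   `js_bits` and `comparison = "replacement"`.
#' @seealso [max_js_by_R()] for the per-R maximum over counts.
#' @export
scan_replacement_effect <- function(K_values = c(0, 1, 2, 5, 10, 20, 50, 100),
                                    R_values = 2^-(8:1),
                                    m = 2,
                                    split = "near_equal") {
  if (m < 2) stop_domain("`m` must be at least 2 (the schemes coincide at m = 1).")
  if (any(R_values <= 0 | R_values > 1)) stop_domain("all R values must lie in (0, 1].")
  split_fun <- if (is.function(split)) split else split_near_equal
  grid <- tidyr::expand_grid(K = as.numeric(K_values), R = as.numeric(R_values))
  grid$js_bits <- purrr::map2_dbl(grid$K, grid$R, function(K, R) {
    k <- split_fun(K, m)
    stopifnot(sum(k) == K, length(k) == m)
    r <- rep(R / m, m)
    p_with <- posterior_with_replacement(
      sample_counts(k, r, with_replacement = TRUE), prior_support(min(k), Inf)
    )
    p_without <- posterior_without_replacement(
      sample_counts(k, r, with_replacement = FALSE), prior_support(K, Inf)
    )
    js_divergence(p_with, p_without)
  })
  grid$comparison <- "replacement"
  class(grid) <- c("divergence_grid", class(grid))
  grid
}

split_near_equal <- function(K, m) {
  base <- K %/% m
  sort(base + (seq_len(m) <= K %% m), decreasing = TRUE)
}

#' Divergence between the discrete-uniform and Gamma-Poisson methods
#'
#' For each `(K, R)` pair, compares the without-replacement posterior of `n`
#' (unbounded support, materialized) with the discretized Gamma-Poisson
#' posterior `Gamma(kappa + K, rho + R)` on a shared integer grid, via the
#' Jensen-Shannon divergence in bits. Sweeping `rho` probes the sensitivity
#' of the GP method to its prior rate.
#'
#' @inheritParams scan_replacement_effect
#' @param kappa,rho GP prior shape and rate; defaults `kappa = 1`,
#'   `rho = 1e-6` (near-flat prior). Vectors of `rho` are swept.
#' @return A tibble of class `divergence_grid` with columns `K`, `R`, `rho`,
#'   `js_bits` and `comparison = "gamma_poisson"`.
#' @export
scan_gp_divergence <- function(K_values = c(0, 1, 2, 5, 10, 20, 50, 100),
                               R_values = 2^-(8:1),
                               kappa = 1, rho = 1e-6) {
  if (any(R_values <= 0 | R_values >= 1)) {
    stop_domain("all R values must lie in (0, 1) for the unbounded posterior.")
  }
  grid <- tidyr::expand_grid(K = as.numeric(K_values), R = as.numeric(R_values),
                             rho = as.numeric(rho))
  grid$js_bits <- purrr::pmap_dbl(grid[c("K", "R", "rho")], function(K, R, rho) {
    p <- posterior_without_replacement(
      sample_counts(K, R), prior_support(K, Inf)
    )
    gp <- gamma_posterior(K, R, kappa = kappa, rho = rho)
    q <- discretize_gamma(gp)
    js_divergence(p, q)
  })
  grid$comparison <- "gamma_poisson"
  class(grid) <- c("divergence_grid", class(grid))
  grid
}

#' Maximum divergence per total sampling fraction
#'
#' @param grid A `divergence_grid` from [scan_replacement_effect()] or
#'   [scan_gp_divergence()].
#' @return A tibble with one row per `R` and the maximum `js_bits` over `K`.
#' @export
max_js_by_R <- function(grid) {
  dplyr::summarise(dplyr::group_by(grid, .data$R),
                   max_js_bits = max(.data$js_bits), .groups = "drop")
}
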