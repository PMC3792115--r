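test_that("noiseless power-law data are recovered to optimizer precision", {
  t <- c(3, 7, 14, 21, 28)
  s <- tibble::tibble(time = t, map = 1e6 * t^(-0.5))
  fit <- fit_power_law(s)
  expect_true(fit$converged)
  expect_equal(fit$amplitude, 1e6, tolerance = 1e-6)
  expect_equal(fit$exponent, 0.5, tolerance = 1e-6)
  # the floor is weakly identified on noiseless power-law data: judge it and
  # the residual scale relative to the amplitude
  expect_lt(abs(fit$offset) / fit$amplitude, 1e-6)
  expect_lt(fit$residual_se / fit$amplitude, 1e-6)
  expect_equal(fit$df, 2)

  g <- glance(fit)
  expect_equal(g$exponent, fit$exponent)
  expect_equal(nrow(tidy(fit)), 3)
})

test_that("the exponent survives multiplicative noise", {
  set.seed(13)
  t <- c(3, 7, 14, 21, 28)
  s <- tibble::tibble(time = t, map = 1e6 * t^(-0.5) * exp(rnorm(5, 0, 0.01)))
  fit <- fit_power_law(s)
  expect_lt(abs(fit$exponent - 0.5) / 0.5, 0.2)
})

test_that("fit is invariant to rescaling up to the amplitude", {
  t <- c(3, 7, 14, 21, 28)
  s <- tibble::tibble(time = t, map = 2e5 * t^(-0.35))
  f1 <- fit_power_law(s, two_param = TRUE)
  f2 <- fit_power_law(dplyr::mutate(s, map = map * 10), two_param = TRUE)
  expect_equal(f2$exponent, f1$exponent, tolerance = 1e-6)
  expect_equal(f2$amplitude, 10 * f1$amplitude, tolerance = 1e-6)
  expect_equal(f1$df, 3)
})

test_that("degenerate inputs are flagged or rejected", {
  const <- tibble::tibble(time = c(3, 7, 14, 21), map = rep(100, 4))
  f <- fit_power_law(const)
  expect_false(f$converged)
  expect_equal(f$exponent, 0)

  expect_warning(
    fit_power_law(tibble::tibble(time = c(0, 3, 7, 14, 21), map = c(5, 4, 3, 2, 1) * 10)),
    "singular"
  )
  expect_error(fit_power_law(tibble::tibble(time = c(3, 7), map = c(2, 1))),
               class = "popsize_domain_error")
  expect_error(fit_power_law(tibble::tibble(time = c(3, 7, 14, 21), map = c(1, 2, 0, 4))),
               class = "popsize_domain_error")
})

test_that("the pipeline estimates a survival curve from a simulated time course", {
  d <- dilution_series(seed = 8)
  series <- estimate_survival_series(d)
  expect_s3_class(series, "survival_series")
  expect_equal(nrow(series), 6)
  expect_true(all(series$ci_lower <= series$map & series$map <= series$ci_upper))
  # MAPs should track the (decaying) truth within the credible intervals
  truth <- attr(d, "truth")
  hits <- mean(series$ci_lower <= truth$n_true & truth$n_true <= series$ci_upper)
  expect_gte(hits, 0.5)
  # t = 0 is present in the series and is dropped for the power-law fit
  expect_warning(fit <- fit_power_law(series), "singular")
  expect_true(fit$converged)
  expect_gt(fit$exponent, 0)
})
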