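test_that("binomial_pmf matches closed-form values and rejects bad fractions", {
  expect_equal(binomial_pmf(1, 2, 0.5), 0.5)
  expect_equal(binomial_pmf(5, 3, 0.2), 0)          # k > n is impossible
  # choose(50, 4) * 0.1^4 * 0.9^46 evaluated at high precision
  expect_equal(binomial_pmf(4, 50, 0.1), 0.180904500875754, tolerance = 1e-12)
  expect_error(binomial_pmf(1, 2, 1.5), class = "popsize_domain_error")
  expect_error(binomial_pmf(1, 2, -0.1), class = "popsize_domain_error")
})

test_that("every posterior sums to one and respects its support", {
  cases <- list(
    compute_posterior(sample_counts(c(2, 3), c(0.1, 0.2))),
    compute_posterior(sample_counts(c(2, 3), c(0.1, 0.2)), unbounded = TRUE),
    compute_posterior(sample_counts(c(2, 3), c(0.1, 0.2), with_replacement = TRUE)),
    compute_posterior(sample_counts(c(2, 3), c(0.1, 0.2), with_replacement = TRUE),
                      unbounded = TRUE),
    compute_posterior(sample_counts(0, 0.5), unbounded = TRUE)
  )
  for (p in cases) {
    expect_equal(sum(p$prob), 1, tolerance = 1e-12)
    expect_true(all(p$prob >= 0))
    expect_true(all(diff(p$n) == 1))
    expect_gte(min(p$n), 0)
  }
})

test_that("with-replacement posterior matches closed forms on unbounded support", {
  # k = 0: geometric decay P(n) = r (1-r)^n -> 0.5^(n+1) at r = 0.5
  p0 <- compute_posterior(sample_counts(0, 0.5, with_replacement = TRUE),
                          unbounded = TRUE)
  expect_equal(p0$prob[p0$n == 0], 0.5, tolerance = 1e-13)
  expect_equal(p0$prob[p0$n == 1], 0.25, tolerance = 1e-13)

  # single measurement: shifted negative binomial (k + 1, r)
  p4 <- compute_posterior(sample_counts(4, 0.1, with_replacement = TRUE),
                          unbounded = TRUE)
  expect_lt(max(abs(p4$prob - dnbinom(p4$n - 4, size = 5, prob = 0.1))), 1e-12)
})

test_that("with-replacement posterior equals product-then-normalize on a bounded grid", {
  n <- 1:50
  p <- posterior_with_replacement(
    sample_counts(c(1, 1), c(0.5, 0.5), with_replacement = TRUE),
    prior_support(1, 50)
  )
  expect_lt(max(abs(p$prob - brute_posterior_with(c(1, 1), c(0.5, 0.5), n))), 1e-12)

  p2 <- posterior_with_replacement(
    sample_counts(c(2, 3), c(0.1, 0.2), with_replacement = TRUE),
    prior_support(0, 200)
  )
  expect_lt(max(abs(p2$prob - brute_posterior_with(c(2, 3), c(0.1, 0.2), 0:200))), 1e-12)
})

test_that("without-replacement posterior matches its closed forms", {
  # counts (2), r = 0.5: P(n) = choose(n, 2) 0.5^3 0.5^(n-2)
  p <- compute_posterior(sample_counts(2, 0.5), unbounded = TRUE)
  expect_equal(p$prob[p$n == 2], 0.125, tolerance = 1e-13)
  expect_equal(p$prob[p$n == 3], 0.1875, tolerance = 1e-13)
  expect_equal(p$prob[p$n == 4], 0.1875, tolerance = 1e-13)
  expect_equal(posterior_summary(p)$map, 3)  # tie with 4 broken downward

  # zero count: geometric
  g <- compute_posterior(sample_counts(0, 0.5), unbounded = TRUE)
  expect_lt(max(abs(g$prob - 0.5^(g$n + 1))), 1e-13)
})

test_that("(K, R) is sufficient: permutations and merging leave the posterior unchanged", {
  sup <- prior_support(5, 300)
  a <- posterior_without_replacement(sample_counts(c(2, 3), c(0.1, 0.2)), sup)
  b <- posterior_without_replacement(sample_counts(c(3, 2), c(0.2, 0.1)), sup)
  c_ <- posterior_without_replacement(sample_counts(5, 0.3), sup)
  expect_identical(a$prob, b$prob)
  expect_equal(a$prob, c_$prob, tolerance = 1e-14)
})

test_that("sequential residual-volume updates agree with the closed form", {
  sup <- prior_support(5, 200)
  seq_post <- sequential_posterior_oracle(sample_counts(c(2, 3), c(0.1, 0.2)), sup)
  closed <- posterior_without_replacement(sample_counts(c(2, 3), c(0.1, 0.2)), sup)
  expect_lt(max(abs(seq_post$prob - closed$prob)), 1e-10)

  sup3 <- prior_support(3, 100)
  seq3 <- sequential_posterior_oracle(sample_counts(c(1, 0, 2), c(0.2, 0.3, 0.4)), sup3)
  closed3 <- posterior_without_replacement(sample_counts(3, 0.9), sup3)
  expect_lt(max(abs(seq3$prob - closed3$prob)), 1e-10)

  # single measurement: identical by construction
  seq1 <- sequential_posterior_oracle(sample_counts(4, 0.25), prior_support(4, 100))
  cl1 <- posterior_without_replacement(sample_counts(4, 0.25), prior_support(4, 100))
  expect_equal(seq1$prob, cl1$prob, tolerance = 1e-14)
})

test_that("degenerate supports and fractions are handled", {
  # support entirely below the smallest feasible n
  expect_error(
    posterior_without_replacement(sample_counts(5, 0.3), prior_support(0, 4)),
    class = "popsize_domain_error"
  )
  expect_error(
    posterior_with_replacement(
      sample_counts(5, 0.3, with_replacement = TRUE), prior_support(0, 4)),
    class = "popsize_domain_error"
  )
  # R = 1 without replacement: the whole volume was counted
  p <- posterior_without_replacement(sample_counts(c(3, 4), c(0.5, 0.5)),
                                     prior_support(0, 20))
  expect_equal(p$prob[p$n == 7], 1)
  # r = 1 with replacement collapses onto k
  pw <- posterior_with_replacement(
    sample_counts(c(3, 1), c(1, 0.5), with_replacement = TRUE),
    prior_support(0, Inf)
  )
  expect_equal(pw$n, 3)
  expect_equal(pw$prob, 1)
})
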