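test_that("edge fractions behave deterministically", {
  s1 <- simulate_counts(100, 1, with_replacement = TRUE, replicates = 20, seed = 1)
  expect_true(all(s1$count == 100))                 # r = 1 counts everything
  # exhaustive sampling without replacement allocates every object
  s2 <- simulate_counts(50, c(0.4, 0.6), replicates = 20, seed = 1)
  tot <- tapply(s2$count, s2$replicate, sum)
  expect_true(all(tot == 50))
})

test_that("identical seeds reproduce identical count sets", {
  a <- simulate_counts(500, c(0.01, 0.02), replicates = 10, seed = 99)
  b <- simulate_counts(500, c(0.01, 0.02), replicates = 10, seed = 99)
  expect_identical(a, b)
  expect_s3_class(counts_for_replicate(a, 3), "sample_counts")
})

test_that("simulated counts match binomial moments", {
  reps <- 10000
  s <- simulate_counts(1000, 0.1, with_replacement = TRUE, replicates = reps,
                       seed = 11)
  se <- sqrt(1000 * 0.1 * 0.9 / reps)
  expect_lt(abs(mean(s$count) - 100), 3 * se)

  # marginals and total of the multinomial construction
  m <- simulate_counts(1000, c(0.1, 0.3), replicates = reps, seed = 12)
  k1 <- m$count[m$fraction == 0.1]
  se1 <- sqrt(1000 * 0.1 * 0.9 / reps)
  expect_lt(abs(mean(k1) - 100), 3 * se1)
  K <- tapply(m$count, m$replicate, sum)
  seK <- sqrt(1000 * 0.4 * 0.6 / reps)
  expect_lt(abs(mean(K) - 400), 3 * seK)
})

test_that("sequential and multinomial constructions agree in distribution", {
  # exact joint pmf oracle for tiny n: multinomial over (r1, r2, rest)
  n_true <- 6
  r <- c(0.3, 0.5)
  cells <- expand.grid(k1 = 0:n_true, k2 = 0:n_true)
  cells <- cells[cells$k1 + cells$k2 <= n_true, ]
  cells$p <- mapply(function(a, b) {
    dmultinom(c(a, b, n_true - a - b), prob = c(r, 1 - sum(r)))
  }, cells$k1, cells$k2)

  reps <- 4000
  for (method in c("multinomial", "sequential")) {
    s <- simulate_counts(n_true, r, replicates = reps, seed = 21, method = method)
    k <- matrix(s$count, nrow = 2)
    obs <- table(factor(paste(k[1, ], k[2, ]),
                        levels = paste(cells$k1, cells$k2)))
    expected <- reps * cells$p
    keep <- expected >= 5
    chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep]) +
      (sum(obs[!keep]) - sum(expected[!keep]))^2 / max(sum(expected[!keep]), 1e-12)
    df <- sum(keep)  # merged remainder adds one cell, minus one constraint
    expect_lt(chi2, qchisq(0.999, df))
  }
})

test_that("credible intervals achieve nominal coverage and MAPs track the truth", {
  cov <- coverage_experiment(500, c(0.01, 0.01), level = 0.95,
                             replicates = 200, seed = 31)
  expect_gte(cov$coverage, 0.9)    # 3 sigma below nominal at 200 replicates
  expect_lte(cov$coverage, 1)
  expect_equal(cov$covered, cov$coverage * cov$replicates)
  expect_lt(abs(cov$median_map - 500) / 500, 0.25)

  half <- coverage_experiment(100, c(0.05, 0.05), level = 0.5,
                              replicates = 200, seed = 32)
  expect_gte(half$coverage, 0.5)   # outward rounding over-covers
  expect_lte(half$coverage, 1)
})

test_that("the MAP is consistent: the median estimate tracks a large population", {
  r <- coverage_experiment(1e4, c(0.005, 0.005), replicates = 500, seed = 7)
  expect_lt(abs(r$median_map - 1e4) / 1e4, 0.05)
})

test_that("the dilution-series preset spans high-count and low-count regimes", {
  d <- dilution_series(seed = 5)
  expect_equal(sort(unique(d$time)), c(0, 3, 7, 14, 21, 28))
  expect_equal(nrow(d), 6 * 5)
  truth <- attr(d, "truth")
  expect_true(all(diff(truth$n_true) < 0))
  # late time points use large fractions (the extreme regime)
  expect_gte(max(d$fraction[d$time == 28]), 0.1)
  expect_lte(max(d$fraction[d$time == 0]), 1e-4)
  # without replacement within a time point: fractions stay below 1 in total
  tot <- tapply(d$fraction, d$time, sum)
  expect_true(all(tot <= 1))
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_counts(0, 0.1), class = "popsize_domain_error")
  expect_error(simulate_counts(10, c(0.7, 0.7)), class = "popsize_domain_error")
  expect_error(simulate_counts(10, 1.4, with_replacement = TRUE),
               class = "popsize_domain_error")
})
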