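test_that("constant-size expectation matches the closed forms", {
  expect_identical(expected_haf_constant(demography(48, 200)), 4776)
  expect_equal(expected_haf_constant(demography(7.3, 2)), 7.3 / 2)
  expect_identical(expected_haf_constant(demography(48, 200), ell = 2),
                   48 * 199 * 399 / 6)
  expect_error(expected_haf_constant(demography(48, 200, alpha = 80)),
               "expected_haf_exponential")
})

test_that("epoch/clade machinery reproduces the closed forms exactly", {
  # E[l-HAF] = (1/n) sum_k k * E[M_{k,i}] * E[W^(l+1)], with
  # E[M_{k,i}] = theta / (k (k-1)) for constant size
  epoch_machinery <- function(theta, n, ell) {
    ks <- 2:n
    sum(ks * theta / (ks * (ks - 1)) *
          vapply(ks, function(k) expected_clade_moment(n, k, ell + 1),
                 numeric(1))) / n
  }
  set.seed(5)
  for (i in 1:20) {
    theta <- runif(1, 1, 100)
    n <- sample(3:60, 1)
    for (ell in 1:2) {
      expect_equal(epoch_machinery(theta, n, ell),
                   expected_haf_constant(demography(theta, n), ell),
                   tolerance = 1e-12)
    }
  }
})

test_that("rising factorials follow the defining product", {
  expect_identical(rising_factorial(3, 2), 12)
  expect_identical(rising_factorial(7, 0), 1)
  expect_identical(rising_factorial(1, 5), 120)
  expect_equal(rising_factorial(c(2, 3), 3), c(2 * 3 * 4, 3 * 4 * 5))
})

test_that("Stirling numbers match a brute-force set-partition counter", {
  expect_identical(stirling2(3, 2), 3)
  expect_identical(stirling2(4, 2), 7)
  expect_identical(stirling2(5, 0), 0)
  expect_identical(stirling2(0, 0), 1)
  for (l in 1:5) {
    for (q in 0:l) {
      expect_identical(stirling2(l, q),
                       as.numeric(count_set_partitions(l, q)),
                       info = paste("S(", l, ",", q, ")"))
    }
  }
})

test_that("clade-size moments match exhaustive topology enumeration", {
  expect_equal(expected_clade_rising(6, 2, 1), 3)   # n/k
  expect_equal(expected_clade_rising(9, 9, 1), 1)   # each lineage = 1 leaf
  expect_equal(expected_clade_rising(4, 2, 1), 2)
  expect_error(expected_clade_rising(5, 1, 1), "2 <= k <= n")

  for (n in 3:5) {
    for (ell in 1:3) {
      oracle <- enumerate_clade_expectation(
        n, function(w) prod(w + 0:(ell - 1)))
      for (k in 2:n) {
        expect_equal(expected_clade_rising(n, k, ell),
                     unname(oracle[as.character(k)]),
                     tolerance = 1e-12,
                     info = paste("n", n, "k", k, "ell", ell))
      }
    }
  }
})

test_that("ordinary clade moments agree with Eq-style closed form and MC", {
  expect_equal(expected_clade_moment(6, 2, 2), 6 * (12 - 2 + 1) / (2 * 3))
  for (n in c(5, 12)) {
    for (k in c(2, 3, n)) {
      expect_equal(expected_clade_moment(n, k, 1),
                   expected_clade_rising(n, k, 1))
      expect_equal(expected_clade_moment(n, k, 2),
                   n * (2 * n - k + 1) / (k * (k + 1)))
    }
  }
  # mean clade sizes over lineages partition the sample
  for (n in c(4, 9)) {
    for (k in 2:n) {
      expect_equal(k * expected_clade_rising(n, k, 1), n)
    }
  }
  # third moment vs direct topology simulation
  set.seed(99)
  reps <- 20000
  cubes <- replicate(reps, mean(simulate_clade_sizes(5, 3)^3))
  se <- sd(cubes) / sqrt(reps)
  expect_lt(abs(mean(cubes) - expected_clade_moment(5, 3, 3)), 3 * se)
})
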