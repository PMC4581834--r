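test_that("scaled exponential integral is accurate over the full range", {
  skip_if_not_installed("pracma")
  xs <- c(1e-4, 0.01, 0.3, 0.999, 1, 1.001, 2, 10, 100, 500)
  for (x in xs) {
    expect_equal(expE1(x), exp(x) * pracma::expint_E1(x),
                 tolerance = 1e-10, info = paste("x =", x))
  }
  # beyond where exp(x)*E1(x) can be formed naively: 1/(x+1) < e^x E1(x) < 1/x
  for (x in c(800, 1e4, 1e8)) {
    v <- expE1(x)
    expect_true(is.finite(v) && v >= 1 / (x + 1) && v < 1 / x)
  }
  expect_error(expE1(-1))
})

test_that("closed-form epoch times match numerical quadrature of Eq form", {
  params <- demography(48, 20, alpha = 40, N = 20000)
  r <- params$alpha / (2 * params$N)
  et <- epoch_times_exponential(params)
  for (row in c(1, 5, 10, nrow(et))) {
    k <- et$k[row]
    tau <- et$tau[row]
    c_fac <- params$alpha * exp(-r * tau) / (k * (k - 1))
    quad <- stats::integrate(function(u) log1p(-c_fac * log(u)), 0, 1,
                             rel.tol = 1e-10)$value / r
    expect_equal(et$t[row], quad, tolerance = 1e-7)
  }
})

test_that("epoch times recover the neutral limit and decrease with k", {
  n <- 30
  N <- 20000
  et <- epoch_times_exponential(demography(10, n, alpha = 1e-6, N = N))
  expect_equal(et$t, 2 * N / (et$k * (et$k - 1)), tolerance = 1e-4)

  et80 <- epoch_times_exponential(demography(48, 200, alpha = 80))
  expect_true(all(et80$t > 0))
  # ordered n..2: durations grow as lineages get fewer
  expect_true(all(diff(et80$t) > 0))
  expect_true(all(diff(et80$tau) > 0))
  expect_error(epoch_times_exponential(demography(48, 200)), "alpha")
})

test_that("epoch times track direct growth-coalescent simulation", {
  # the recursion plugs expectations into later epochs, so it carries a
  # small systematic bias; require close relative agreement, not SE-level
  set.seed(17)
  n <- 20
  alpha <- 40
  N0 <- 20000
  r <- alpha / (2 * N0)
  reps <- 20000
  tm <- matrix(0, reps, n)
  for (rep in seq_len(reps)) {
    tau <- 0
    for (k in n:2) {
      dt <- log1p(rexp(1) * alpha * exp(-r * tau) / (k * (k - 1))) / r
      tm[rep, k] <- dt
      tau <- tau + dt
    }
  }
  et <- epoch_times_exponential(demography(10, n, alpha = alpha, N = N0))
  sim_mean <- colMeans(tm)[n:2]
  expect_true(all(abs(sim_mean - et$t) / et$t < 0.03))
})

test_that("growth expectation reproduces the validated value and limits", {
  v <- expected_haf_exponential(demography(48, 200, alpha = 80))
  expect_equal(v, 126.9, tolerance = 0.1 / 126.9)
  # independent of N0 (alpha is the only scale)
  expect_equal(expected_haf_exponential(
    demography(48, 200, alpha = 80, N = 5000)), v, tolerance = 1e-10)
  # alpha -> 0 recovers the constant-size closed form
  expect_equal(expected_haf_exponential(demography(48, 200, alpha = 1e-6)),
               48 * 199 / 2, tolerance = 1e-3)
  expect_equal(expected_haf_exponential(demography(20, 50, alpha = 1e-6),
                                        ell = 2),
               expected_haf_constant(demography(20, 50), ell = 2),
               tolerance = 1e-3)
  # much lower than the constant-size expectation under fast growth
  expect_lt(v, 4776 / 10)
})

test_that("sweep-phase expectations obey their algebraic structure", {
  params <- demography(48, 200)
  thn <- 48 * 200
  expect_equal(expected_haf_carrier(1, params), thn / 2)
  expect_equal(expected_haf_carrier(0.5, params),
               thn * (0.5 + 0.5 - 1 / 101))
  expect_equal(expected_haf_noncarrier(0, params),
               thn * (1 / 2 + 1 / 400 - 1 / 201))
  nu <- seq(0, 0.9, by = 0.1)
  diff_cn <- expected_haf_carrier(nu, params) -
    expected_haf_noncarrier(nu, params)
  expect_equal(diff_cn, thn * (nu - 1 / 400))
  expect_true(all(diff(diff_cn) > 0))
  nu_star <- 1 / (2 * 200)
  expect_equal(expected_haf_carrier(nu_star, params),
               expected_haf_noncarrier(nu_star, params))
  expect_warning(expected_haf_noncarrier(0.999, params), "non-carriers")
  expect_warning(expected_haf_carrier(0.5, demography(48, 200, N = 100),
                                      s = 0.01), "strong-selection")
})

test_that("the sweep peak is theta*n*(1 - 1/(2n))^2, approaching theta*n", {
  expect_equal(haf_peak(demography(48, 200)), 9600 * 0.9975^2)
  expect_equal(haf_peak(demography(48, 200)), 9552.06, tolerance = 1e-6)
  ratio <- vapply(c(10, 100, 1000, 10000), function(n) {
    haf_peak(demography(1, n)) / n
  }, numeric(1))
  expect_true(all(diff(ratio) > 0))
  expect_gt(ratio[4], 0.999)
})
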