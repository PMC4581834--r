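test_that("identical seeds give bit-identical samples", {
  params <- demography(10, 15)
  a <- sim_neutral(params, reps = 3, seed = 42)
  b <- sim_neutral(params, reps = 3, seed = 42)
  expect_identical(a, b)
  c1 <- sim_neutral(params, reps = 3, seed = 43)
  expect_false(identical(a, c1))
})

test_that("segregating sites match the Watterson expectation", {
  params <- demography(5, 10)
  set.seed(7)
  reps <- 2000
  S <- vapply(sim_neutral(params, reps), ncol, integer(1))
  expected <- 5 * sum(1 / (1:9))
  se <- sd(S) / sqrt(reps)
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("pairwise coalescence time has mean N generations", {
  set.seed(8)
  params <- demography(1, 2, N = 5000)
  reps <- 4000
  tmrca <- vapply(sim_neutral(params, reps, keep_genealogy = TRUE),
                  function(s) attr(s, "genealogy")$epoch_t[2], numeric(1))
  se <- sd(tmrca) / sqrt(reps)
  expect_lt(abs(mean(tmrca) - 5000), 3 * se)
})

test_that("neutral site frequency spectrum follows theta / w", {
  set.seed(9)
  n <- 8
  theta <- 10
  reps <- 3000
  counts <- matrix(0, reps, n - 1)
  samples <- sim_neutral(demography(theta, n), reps)
  for (i in seq_len(reps)) counts[i, ] <- site_spectrum(samples[[i]])$xi
  # per-frequency z-test with Bonferroni at overall alpha = 0.01
  z_crit <- qnorm(1 - 0.01 / (2 * (n - 1)))
  for (w in seq_len(n - 1)) {
    se <- sd(counts[, w]) / sqrt(reps)
    expect_lt(abs(mean(counts[, w]) - theta / w), z_crit * se)
  }
})

test_that("epoch decomposition reconstructs every haplotype's score", {
  set.seed(10)
  samples <- sim_neutral(demography(8, 12), reps = 40,
                         keep_genealogy = TRUE)
  for (s in samples) {
    g <- attr(s, "genealogy")
    dec <- genealogy_epoch_decomposition(g)
    # clades partition the sample in every epoch
    expect_equal(as.vector(tapply(dec$w, dec$k, sum)),
                 rep(12, 11))
    # total mutations across epochs/lineages = segregating sites
    expect_equal(sum(dec$m), ncol(s))
    for (ell in 1:3) {
      expect_equal(haf_from_genealogy(g, ell), haf_score(s, ell)$score,
                   info = paste("ell", ell))
    }
  }
})

test_that("growth simulator collapses to constant size as alpha -> 0", {
  set.seed(12)
  reps <- 2000
  t2_const <- vapply(
    sim_neutral(demography(1, 2, N = 10000), reps, keep_genealogy = TRUE),
    function(s) attr(s, "genealogy")$epoch_t[2], numeric(1))
  t2_growth <- vapply(
    sim_neutral(demography(1, 2, alpha = 1e-7, N = 10000), reps,
                keep_genealogy = TRUE),
    function(s) attr(s, "genealogy")$epoch_t[2], numeric(1))
  expect_gt(suppressWarnings(ks.test(t2_const, t2_growth)$p.value), 0.01)
})

test_that("growth epoch durations track the conditional-expectation theory", {
  set.seed(13)
  n <- 10
  params <- demography(5, n, alpha = 40, N = 20000)
  reps <- 4000
  em <- matrix(0, reps, n)
  samples <- sim_neutral(params, reps, keep_genealogy = TRUE)
  for (i in seq_len(reps)) {
    em[i, ] <- attr(samples[[i]], "genealogy")$epoch_t
  }
  et <- epoch_times_exponential(params)
  sim_mean <- colMeans(em)[n:2]
  # plug-in recursion: close relative agreement expected, not exactness
  expect_true(all(abs(sim_mean - et$t) / et$t < 0.05))
})

test_that("recombination backend yields valid, reproducible samples", {
  params <- demography(10, 12, rho = 8)
  a <- sim_neutral(params, reps = 2, seed = 77)
  b <- sim_neutral(params, reps = 2, seed = 77)
  expect_identical(a, b)
  for (s in a) {
    expect_s3_class(s, "hap_matrix")
    expect_equal(nrow(s), 12)
    w <- colSums(s)
    expect_true(all(w >= 1 & w <= 11))
    expect_true(all(diff(attr(s, "positions")) > 0))
  }
  expect_error(sim_neutral(params, reps = 1, keep_genealogy = TRUE),
               "recombination")
})
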