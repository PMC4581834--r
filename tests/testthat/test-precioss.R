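test_that("EM recovers well-separated clusters at their exact means", {
  scores <- c(0, 0, 1, 10, 10, 11)
  fit <- fit_gmm_em(scores, seed = 1)
  expect_equal(sort(fit$means), c(1 / 3, 31 / 3), tolerance = 1e-4)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-4)
  lab <- fit$responsibilities[, 2] >= 0.5
  expect_equal(lab, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_true(fit$converged)
  expect_false(fit$low_confidence)
})

test_that("EM log-likelihood is monotone in the iteration budget", {
  set.seed(2)
  scores <- c(rnorm(20, 0), rnorm(20, 3))
  lls <- vapply(1:12, function(k) {
    suppressWarnings(
      fit_gmm_em(scores, max_iter = k, tol = 0, restarts = 1))$loglik
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-8))
})

test_that("degenerate inputs are rejected or flagged", {
  expect_error(fit_gmm_em(rep(3, 10)), "identical")
  expect_error(fit_gmm_em(c(1, 2, 3)), "at least 4")
  expect_error(fit_gmm_em(c(1, 2, NA, 4)), "finite")
  set.seed(3)
  fit <- fit_gmm_em(rnorm(30, 0, 1), seed = 4)  # one true cluster
  expect_true(fit$low_confidence)
})

test_that("well-separated synthetic mixtures are classified near-perfectly", {
  set.seed(5)
  miscl <- vapply(1:100, function(i) {
    truth <- rep(c(FALSE, TRUE), each = 25)
    scores <- c(rnorm(25, 0, 1), rnorm(25, 8, 1))  # 8 pooled SD apart
    fit <- fit_gmm_em(scores)
    lab <- fit$responsibilities[, 2] >= 0.5
    mean(lab != truth)
  }, numeric(1))
  expect_lt(mean(miscl), 0.01)
})

test_that("EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(6)
  scores <- c(rnorm(60, 0, 1), rnorm(40, 5, 1.5))
  fit <- fit_gmm_em(scores, seed = 7)
  mc <- mclust::Mclust(scores, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("predict_carriers labels the higher-mean component as carrier", {
  set.seed(8)
  m <- rbind(matrix(rbinom(15 * 40, 1, 0.85), 15),
             matrix(rbinom(15 * 40, 1, 0.10), 15))
  h <- hap_matrix(m, carrier_truth = rep(c(TRUE, FALSE), each = 15))
  p <- predict_carriers(h, seed = 9)
  expect_s3_class(p, "precioss")
  car_mean <- mean(p$score[p$label == "carrier"])
  non_mean <- mean(p$score[p$label == "non-carrier"])
  expect_gt(car_mean, non_mean)
  expect_gt(evaluate_prediction(p)$balanced_accuracy, 0.9)
  # permutation of haplotypes permutes labels identically
  perm <- sample(30)
  p2 <- predict_carriers(h[perm, ], seed = 9)
  expect_equal(p2$label, p$label[perm])
  expect_error(predict_carriers(hap_matrix(matrix(1, 5, 2))),
               "no polymorphic sites")
})

test_that("tidy/glance/autoplot expose the mixture fit", {
  set.seed(10)
  h <- hap_matrix(rbind(matrix(rbinom(80, 1, 0.9), 8),
                        matrix(rbinom(80, 1, 0.1), 8)))
  p <- predict_carriers(h, seed = 11)
  fit <- attr(p, "fit")
  td <- generics::tidy(fit)
  expect_equal(td$component, c("non-carrier", "carrier"))
  expect_true(all(diff(td$mean) > 0))
  gl <- generics::glance(fit)
  expect_true(gl$converged)
  expect_s3_class(ggplot2::autoplot(p), "ggplot")
})

test_that("balanced accuracy follows its definition and symmetries", {
  lab <- rep(c(TRUE, FALSE, TRUE, FALSE), c(90, 10, 20, 80))
  tru <- rep(c(TRUE, FALSE), c(100, 100))
  ba <- balanced_accuracy(lab, tru)
  expect_equal(ba$balanced_accuracy, 0.85)
  expect_equal(c(ba$tp, ba$fn, ba$fp, ba$tn), c(90, 10, 20, 80))
  expect_equal(balanced_accuracy(tru, tru)$balanced_accuracy, 1)
  # constant carrier guess with both classes present
  expect_equal(
    balanced_accuracy(rep(TRUE, 200), tru)$balanced_accuracy, 0.5)
  # swapping class labels consistently leaves it unchanged
  expect_equal(balanced_accuracy(!lab, !tru)$balanced_accuracy,
               ba$balanced_accuracy)
  expect_warning(ba1 <- balanced_accuracy(lab, rep(TRUE, 200)),
                 "single class")
  expect_equal(ba1$balanced_accuracy, 110 / 200)
  # character encoding round-trips
  expect_equal(balanced_accuracy(
    ifelse(lab, "carrier", "non-carrier"),
    ifelse(tru, "carrier", "non-carrier"))$balanced_accuracy, 0.85)
})

test_that("rank-sum separation matches exact enumeration and wilcox.test", {
  sc <- c(1, 2, 3, 10, 11, 12)
  tr <- rep(c(FALSE, TRUE), each = 3)
  res <- carrier_separation_test(sc, tr)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, exact_ranksum_p(sc[4:6], sc[1:3]))
  set.seed(12)
  for (i in 1:5) {
    a <- rnorm(7)
    b <- rnorm(5, 1)
    res <- carrier_separation_test(c(a, b), c(rep(FALSE, 7), rep(TRUE, 5)))
    expect_equal(res$p_value, exact_ranksum_p(b, a), tolerance = 1e-12)
  }
  expect_error(carrier_separation_test(1:4, rep(TRUE, 4)), "non-empty")
})

test_that("rank percentiles use mid-ranks and ignore monotone transforms", {
  expect_equal(rank_percentile(c(3, 7, 9, 20)), c(12.5, 37.5, 62.5, 87.5))
  expect_equal(rank_percentile(rep(4, 5)), rep(50, 5))
  x <- c(5, 1, 9, 9, 2)
  expect_equal(rank_percentile(x), rank_percentile(exp(x / 3)))
  expect_equal(rank_percentile(numeric(0)), numeric(0))
})
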