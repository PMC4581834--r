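#' Fit a two-component Gaussian mixture to scores by EM
#'
#' One-dimensional two-component Gaussian mixture fitted by
#' expectation-maximization: posteriors in the E-step, weighted means,
#' variances and mixing weights in the M-step, stopping when the relative
#' log-likelihood change drops below `tol` or after `max_iter` iterations.
#' The best of `restarts` runs by final log-likelihood is kept: the first
#' run is initialized deterministically by splitting the scores at the
#' median, the rest from random responsibility draws. A variance floor of
#' `1e-6` times the sample variance keeps components from collapsing onto
#' duplicated scores.
#'
#' @param scores Numeric vector of at least 4 finite values, not all equal.
#' @param seed Optional integer seed (`NULL` = current RNG state).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param restarts Number of EM restarts.
#' @return An object of class `gmm1d`: list with `means`, `variances`,
#'   `weights` (each length 2, component 1 = lower mean), `responsibilities`
#'   (n x 2, columns in the same order), `loglik`, `n_iter`, `converged`,
#'   `low_confidence` (TRUE when the means differ by less than twice the
#'   larger component SD) and `restart_used`.
#' @export
fit_gmm_em <- function(scores, seed = NULL, max_iter = 500, tol = 1e-6,
                       restarts = 5) {
  if (!is.numeric(scores) || any(!is.finite(scores))) {
    stop("scores must be finite numeric values", call. = FALSE)
  }
  n <- length(scores)
  if (n < 4) {
    stop("need at least 4 scores to fit a two-component mixture",
         call. = FALSE)
  }
  if (stats::sd(scores) == 0) {
    stop("all scores are identical: no two-cluster structure to fit",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  var_floor <- 1e-6 * stats::var(scores)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1) init_median_split(scores) else init_random(scores)
    fit <- em_run(scores, init, max_iter, tol, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$restart_used <- r
    }
  }
  # order components by mean (component 2 = higher mean = carrier side)
  o <- order(best$means)
  best$means <- best$means[o]
  best$variances <- best$variances[o]
  best$weights <- best$weights[o]
  best$responsibilities <- best$responsibilities[, o, drop = FALSE]
  best$low_confidence <-
    diff(best$means) < 2 * sqrt(max(best$variances))
  best$scores <- scores
  class(best) <- "gmm1d"
  best
}

init_median_split <- function(scores) {
  md <- stats::median(scores)
  lo <- scores[scores <= md]
  hi <- scores[scores > md]
  if (!length(hi)) {  # heavy ties at the median
    hi <- max(scores)
    lo <- scores[scores < max(scores)]
  }
  list(means = c(mean(lo), mean(hi)),
       variances = pmax(c(stats::var(lo), stats::var(hi)),
                        stats::var(scores) / 100, 1e-12),
       weights = c(length(lo), length(hi)) / length(scores))
}

init_random <- function(scores) {
  n <- length(scores)
  resp <- stats::runif(n)
  resp <- cbind(resp, 1 - resp)
  m_step(scores, resp, 1e-12)
}

m_step <- function(scores, resp, var_floor) {
  nk <- colSums(resp)
  means <- colSums(resp * scores) / nk
  variances <- pmax(
    colSums(resp * (outer(scores, means, "-"))^2) / nk, var_floor)
  list(means = means, variances = variances,
       weights = nk / length(scores))
}

em_run <- function(scores, par, max_iter, tol, var_floor) {
  ll_old <- -Inf
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:2, function(k) {
      par$weights[k] * stats::dnorm(scores, par$means[k],
                                    sqrt(par$variances[k]))
    }, numeric(length(scores)))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    par <- m_step(scores, resp, var_floor)
  }
  list(means = par$means, variances = par$variances,
       weights = par$weights, responsibilities = resp,
       loglik = ll_old, n_iter = it, converged = converged)
}

#' @export
print.gmm1d <- function(x, ...) {
  cat("<gmm1d> two-component Gaussian mixture\n")
  cat(sprintf("  component 1: mean %.4g sd %.4g weight %.3f\n",
              x$means[1], sqrt(x$variances[1]), x$weights[1]))
  cat(sprintf("  component 2: mean %.4g sd %.4g weight %.3f\n",
              x$means[2], sqrt(x$variances[2]), x$weights[2]))
  cat(sprintf("  loglik %.4f after %d iterations (%s)%s\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "not converged",
              if (x$low_confidence) "; LOW CONFIDENCE separation" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy gmm1d
#' @export
tidy.gmm1d <- function(x, ...) {
  tibble::tibble(component = c("non-carrier", "carrier"),
                 mean = x$means, sd = sqrt(x$variances),
                 weight = x$weights)
}

#' @method glance gmm1d
#' @export
glance.gmm1d <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged,
                 low_confidence = x$low_confidence,
                 restart_used = x$restart_used)
}

#' Predict carriers of an ongoing sweep (PreCIOSS)
#'
#' The PreCIOSS algorithm: compute every haplotype's l-HAF score, fit a
#' two-component Gaussian mixture to the scores by EM, assign each
#' haplotype to its maximum-posterior component, and label the
#' higher-mean component "carrier" (carriers of the favored allele
#' accumulate high-frequency hitchhiking variants and hence high scores).
#' Posterior ties go to the carrier component. When the fitted component
#' means are separated by less than twice the larger component SD the
#' two-cluster assumption is unsupported and the prediction is flagged
#' low-confidence (labels are still returned).
#'
#' @param x A [hap_matrix()].
#' @param ell Positive integer l for the score (default 1).
#' @param seed Optional integer seed for the EM restarts.
#' @param ... Passed to [fit_gmm_em()].
#' @return An object of class `precioss`: a tibble with columns
#'   `sample_id`, `score`, `percentile`, `posterior_carrier`, `label`
#'   (and `carrier_truth` when available), with the `gmm1d` fit in
#'   attribute `"fit"`, plus `ell` and `low_confidence` attributes.
#' @examples
#' set.seed(7)
#' m <- rbind(matrix(rbinom(50, 1, 0.9), 5), matrix(rbinom(50, 1, 0.1), 5))
#' predict_carriers(hap_matrix(m), seed = 1)
#' @export
predict_carriers <- function(x, ell = 1L, seed = NULL, ...) {
  stopifnot(inherits(x, "hap_matrix"))
  sc <- haf_score(x, ell = ell)
  if (all(sc$score == 0) && ncol(filter_polymorphic(x)) == 0L) {
    stop("no polymorphic sites: cannot score haplotypes", call. = FALSE)
  }
  fit <- fit_gmm_em(sc$score, seed = seed, ...)
  post_car <- fit$responsibilities[, 2]
  out <- tibble::tibble(
    sample_id = sc$sample_id,
    score = sc$score,
    percentile = rank_percentile(sc$score),
    posterior_carrier = post_car,
    label = ifelse(post_car >= 0.5, "carrier", "non-carrier"))
  if (!is.null(sc[["carrier_truth"]])) {
    out$carrier_truth <- sc[["carrier_truth"]]
  }
  attr(out, "fit") <- fit
  attr(out, "ell") <- ell
  attr(out, "low_confidence") <- fit$low_confidence
  class(out) <- c("precioss", class(out))
  out
}

#' In-sample percentile rank
#'
#' Percentile rank of each score within the sample, with mean-rank (mid
#' rank) tie handling: `100 * (rank - 1/2) / n`. Invariant under monotone
#' transforms of the scores.
#'
#' @param scores Numeric vector.
#' @return Vector of percentiles in `[0, 100]`.
#' @export
rank_percentile <- function(scores) {
  n <- length(scores)
  if (n == 0L) return(numeric(0))
  100 * (rank(scores, ties.method = "average") - 0.5) / n
}
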