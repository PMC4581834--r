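#' HAF vectors of a haplotype sample
#'
#' The HAF (haplotype allele frequency) vector of a haplotype replaces every
#' derived allele it carries with that allele's derived count in the sample,
#' and every ancestral allele with 0. Frequencies are integer counts within
#' the sample, not population proportions, so all downstream score
#' arithmetic is exact.
#'
#' @param x A [hap_matrix()], already restricted to polymorphic sites (use
#'   [filter_polymorphic()]).
#' @return An `n x S` integer matrix; entry `(v, j)` is the derived count of
#'   site `j` if haplotype `v` carries the derived allele, else 0.
#' @examples
#' h <- hap_matrix(rbind(c(1, 1, 0), c(1, 0, 1), c(1, 0, 0), c(0, 0, 0)))
#' haf_vectors(h)
#' @export
haf_vectors <- function(x) {
  stopifnot(inherits(x, "hap_matrix"))
  n <- nrow(x)
  if (ncol(x) == 0L) {
    m <- matrix(0L, n, 0L)
    rownames(m) <- attr(x, "sample_ids")
    return(m)
  }
  w <- colSums(x)
  if (any(w == 0L | w == n)) {
    stop("matrix contains monomorphic sites; run filter_polymorphic() first",
         call. = FALSE)
  }
  m <- matrix(as.integer(x), n, ncol(x)) * rep(as.integer(w), each = n)
  dimnames(m) <- list(attr(x, "sample_ids"), NULL)
  m
}

#' l-HAF scores of a haplotype sample
#'
#' The l-HAF score of a haplotype is the sum of the l-th powers of its HAF
#' vector entries; for l = 1 (the default used throughout) it is the sum of
#' the sample frequencies of the derived alleles the haplotype carries.
#' During a selective sweep, carriers of the favored allele accumulate
#' high-frequency hitchhiking alleles and hence high 1-HAF scores.
#'
#' @param x A [hap_matrix()]; monomorphic sites are removed first.
#' @param ell Positive integer exponent l.
#' @return A tibble with columns `sample_id`, `score` and — when the input
#'   has simulation truth attached — `carrier_truth`.
#' @examples
#' h <- hap_matrix(rbind(c(1, 1, 0), c(1, 0, 1), c(1, 0, 0), c(0, 0, 0)))
#' haf_score(h)            # 1-HAF: 4, 4, 3, 0
#' haf_score(h, ell = 2)   # 2-HAF: 10, 10, 9, 0
#' @export
haf_score <- function(x, ell = 1L) {
  ell <- check_ell(ell)
  x <- filter_polymorphic(x)
  n <- nrow(x)
  if (ncol(x) == 0L) {
    sc <- numeric(n)
  } else {
    w <- colSums(x)
    # score[v] = sum_j x[v,j] * w_j^ell; entries of x are 0/1
    sc <- as.vector(unclass(x) %*% (as.numeric(w)^ell))
  }
  out <- tibble::tibble(sample_id = attr(x, "sample_ids"), score = sc)
  ct <- attr(x, "carrier_truth")
  if (!is.null(ct)) out$carrier_truth <- ct
  out
}

#' Site frequency spectrum of a sample
#'
#' Counts of polymorphic sites at each derived-allele count `w = 1 .. n-1`.
#'
#' @inheritParams haf_vectors
#' @return A tibble with columns `w` (derived count) and `xi` (number of
#'   sites at that count), one row per `w` in `1:(n-1)`.
#' @export
site_spectrum <- function(x) {
  stopifnot(inherits(x, "hap_matrix"))
  x <- filter_polymorphic(x)
  n <- nrow(x)
  if (n < 2L) {
    return(tibble::tibble(w = integer(0), xi = integer(0)))
  }
  xi <- tabulate(colSums(x), nbins = n - 1L)
  tibble::tibble(w = seq_len(n - 1L), xi = xi)
}

#' Mean l-HAF score from the site frequency spectrum
#'
#' The mean over haplotypes of the l-HAF score depends on the data only
#' through the site frequency spectrum: each of the `xi_w` sites at derived
#' count `w` contributes `w^l` to each of its `w` carriers, so the sample
#' mean is `(1/n) * sum_w xi_w * w^(l+1)`. This identity is the bridge from
#' per-haplotype scores to coalescent expectations.
#'
#' @param spectrum A tibble as returned by [site_spectrum()] (columns `w`,
#'   `xi`).
#' @param n Sample size (number of haplotypes).
#' @param ell Positive integer exponent l.
#' @return The mean l-HAF score (a single number).
#' @export
mean_haf_from_spectrum <- function(spectrum, n, ell = 1L) {
  ell <- check_ell(ell)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive sample size", call. = FALSE)
  }
  stopifnot(all(c("w", "xi") %in% names(spectrum)))
  sum(spectrum$xi * spectrum$w^(ell + 1)) / n
}

#' Normalized l-HAF (l-th root)
#'
#' Convenience transform `score^(1/l)`, putting scores for different `l` on
#' a comparable scale (upper range approaching `n - 1`).
#'
#' @param score Numeric vector of l-HAF scores.
#' @param ell The exponent the scores were computed with.
#' @return `score^(1/ell)`.
#' @export
haf_root <- function(score, ell = 1L) {
  ell <- check_ell(ell)
  score^(1 / ell)
}

check_ell <- function(ell) {
  if (!is.numeric(ell) || length(ell) != 1L || ell < 1 ||
      ell != round(ell)) {
    stop("ell must be a positive integer", call. = FALSE)
  }
  as.integer(ell)
}
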