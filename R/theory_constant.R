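#' Expected l-HAF score, neutral constant-size population
#'
#' Under the standard neutral coalescent with constant population size, the
#' expected number of sites at derived count `w` is `theta / w`, so the
#' expected l-HAF score of a random haplotype is
#' `(theta / n) * sum_{w=1}^{n-1} w^l`. For l = 1 this is
#' `theta * (n - 1) / 2`, and for l = 2 it is
#' `theta * (n - 1) * (2n - 1) / 6`.
#'
#' @param params A [demography()] with `alpha = 0`.
#' @param ell Positive integer exponent l.
#' @return The expected l-HAF score.
#' @examples
#' expected_haf_constant(demography(theta = 48, n = 200))  # 4776
#' @export
expected_haf_constant <- function(params, ell = 1L) {
  ell <- check_ell(ell)
  stopifnot(inherits(params, "demography"))
  if (params$alpha != 0) {
    stop("alpha > 0: use expected_haf_exponential() for a growing population",
         call. = FALSE)
  }
  n <- params$n
  params$theta / n * sum(as.numeric(seq_len(n - 1))^ell)
}

#' Rising factorial
#'
#' `w^(l) = w (w+1) ... (w + l - 1)`, with `w^(0) = 1`.
#'
#' @param w Base (vectorized).
#' @param ell Non-negative integer.
#' @return The rising factorial, as a double (exact for moderate sizes).
#' @export
rising_factorial <- function(w, ell) {
  stopifnot(is.numeric(ell), length(ell) == 1L, ell >= 0,
            ell == round(ell))
  out <- rep(1, length(w))
  if (ell >= 1) {
    for (i in 0:(ell - 1)) out <- out * (w + i)
  }
  out
}

#' Stirling numbers of the second kind
#'
#' `S(l, q)`: the number of ways to partition a set of `l` labeled elements
#' into `q` non-empty blocks, by the standard recurrence
#' `S(l, q) = q * S(l-1, q) + S(l-1, q-1)`.
#'
#' @param ell Number of elements, >= 0.
#' @param q Number of blocks, 0 <= q <= ell (values outside give 0).
#' @return `S(ell, q)` as a double.
#' @export
stirling2 <- function(ell, q) {
  stopifnot(ell >= 0, ell == round(ell), q == round(q))
  if (q < 0 || q > ell) return(0)
  if (ell == 0) return(as.numeric(q == 0))
  # row-by-row recurrence
  row <- c(1, rep(0, ell))  # S(0, .)
  for (l in 1:ell) {
    new <- numeric(ell + 1)
    for (qq in 1:l) {
      new[qq + 1] <- qq * row[qq + 1] + row[qq]
    }
    row <- new
  }
  row[q + 1]
}

#' Expected rising factorial of a clade size
#'
#' While the genealogy of `n` haplotypes has exactly `k` ancestral lineages
#' (epoch `k`), those lineages partition the sample into `k` clades. The
#' size `W` of the clade subtended by a random lineage of epoch `k`
#' satisfies `E[W^(l)] = l! * n^(l) / k^(l)` (rising factorials), a purely
#' combinatorial fact independent of branch lengths.
#'
#' @param n Sample size.
#' @param k Epoch index, `2 <= k <= n`.
#' @param ell Positive integer.
#' @return `E[(W_{k,i})^(ell)]`.
#' @examples
#' expected_clade_rising(6, 2, 1)  # mean 2-clade size = n/k = 3
#' @export
expected_clade_rising <- function(n, k, ell) {
  ell <- check_ell(ell)
  if (k < 2 || k > n) {
    stop("epoch index k must satisfy 2 <= k <= n", call. = FALSE)
  }
  factorial(ell) * rising_factorial(n, ell) / rising_factorial(k, ell)
}

#' Expected power of a clade size
#'
#' Ordinary moments `E[W^l]` of the epoch-`k` clade size, obtained from the
#' rising-factorial moments through the Stirling-number conversion
#' `w^l = sum_q (-1)^(l-q) S(l, q) w^(q)`. For l = 2 this reduces to
#' `n (2n - k + 1) / (k (k + 1))`.
#'
#' @inheritParams expected_clade_rising
#' @return `E[(W_{k,i})^ell]`.
#' @export
expected_clade_moment <- function(n, k, ell) {
  ell <- check_ell(ell)
  if (k < 2 || k > n) {
    stop("epoch index k must satisfy 2 <= k <= n", call. = FALSE)
  }
  out <- 0
  for (q in 1:ell) {
    out <- out + (-1)^(ell - q) * stirling2(ell, q) *
      factorial(q) * rising_factorial(n, q) / rising_factorial(k, q)
  }
  out
}
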