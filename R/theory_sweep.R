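#' Expected 1-HAF of carriers during an ongoing sweep
#'
#' When a fraction `nu` of the `n` sampled haplotypes carry the favored
#' allele of an ongoing hard sweep, under strong selection (`N s >> 1`) and
#' no recombination the expected 1-HAF score of a random carrier is
#' approximately
#'
#'   `theta * n * (nu + 1/2 - 1 / ((1 - nu) n + 1))`.
#'
#' @param nu Carrier fraction in the sample, in `[0, 1]`.
#' @param params A [demography()] supplying `theta` and `n`.
#' @param s Optional selection coefficient; if supplied and `N s < 10` a
#'   warning notes that the strong-selection approximation is strained.
#' @return Expected carrier 1-HAF score (vectorized over `nu`).
#' @examples
#' expected_haf_carrier(0.5, demography(theta = 48, n = 200))
#' @export
expected_haf_carrier <- function(nu, params, s = NULL) {
  stopifnot(inherits(params, "demography"),
            is.numeric(nu), all(nu >= 0), all(nu <= 1))
  warn_weak_selection(params, s)
  th <- params$theta
  n <- params$n
  th * n * (nu + 1 / 2 - 1 / ((1 - nu) * n + 1))
}

#' Expected 1-HAF of non-carriers during an ongoing sweep
#'
#' Companion to [expected_haf_carrier()]: under the same assumptions the
#' expected 1-HAF of a random non-carrier is approximately
#' `theta * n * (1/2 + 1/(2n) - 1 / ((1 - nu) n + 1))`. The carrier minus
#' non-carrier difference is `theta * n * (nu - 1/(2n))`, increasing in
#' `nu` and crossing zero at `nu = 1/(2n)`.
#'
#' @inheritParams expected_haf_carrier
#' @return Expected non-carrier 1-HAF score (vectorized over `nu`).
#' @export
expected_haf_noncarrier <- function(nu, params, s = NULL) {
  stopifnot(inherits(params, "demography"),
            is.numeric(nu), all(nu >= 0), all(nu <= 1))
  warn_weak_selection(params, s)
  n <- params$n
  if (any(nu > (n - 1) / n)) {
    warning("nu > (n-1)/n: no non-carriers exist in a sample of size ", n,
            call. = FALSE)
  }
  params$theta * n * (1 / 2 + 1 / (2 * n) - 1 / ((1 - nu) * n + 1))
}

#' Peak expected carrier 1-HAF over the course of a sweep
#'
#' Maximizing the expected carrier 1-HAF over the carrier fraction `nu` in
#' `[0, 1]` gives the pre-fixation peak `theta * n * (1 - 1/(2n))^2`,
#' approximately `theta * n` — notably independent of the selection
#' coefficient under strong selection.
#'
#' @param params A [demography()] supplying `theta` and `n`.
#' @return The peak value `theta * n * (1 - 1/(2n))^2`.
#' @examples
#' haf_peak(demography(theta = 48, n = 200))  # ~9552, close to theta*n = 9600
#' @export
haf_peak <- function(params) {
  stopifnot(inherits(params, "demography"), params$n >= 2)
  params$theta * params$n * (1 - 1 / (2 * params$n))^2
}

warn_weak_selection <- function(params, s) {
  if (!is.null(s) && params$N * s < 10) {
    warning("N*s = ", params$N * s,
            " < 10: strong-selection approximation may be inaccurate",
            call. = FALSE)
  }
}
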