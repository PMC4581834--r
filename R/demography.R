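#' Demographic parameters for theory and simulation
#'
#' Bundles the population-genetic parameters used throughout: the
#' population-scaled mutation rate `theta = 2*N*mu*L` for the whole region
#' (N counted in haploid genomes), the sample size `n`, the scaled
#' exponential growth rate `alpha = 2*N0*r` (0 means constant size), the
#' scaled recombination rate `rho = 2*N*r_bp*L`, and the (current) haploid
#' population size `N`. Time is measured in generations; with these
#' conventions the expected pairwise coalescence time is `N` generations.
#'
#' @param theta Population-scaled mutation rate for the region, > 0.
#' @param n Sample size (haplotypes), >= 2.
#' @param alpha Population-scaled growth rate, >= 0; 0 = constant size.
#' @param rho Population-scaled recombination rate, >= 0.
#' @param N Haploid population size (the current size `N0` under growth).
#' @param window_length Region length in base pairs (positions of simulated
#'   mutations are placed uniformly on this window).
#' @return A list of class `demography`.
#' @examples
#' demography(theta = 48, n = 200)
#' demography(theta = 48, n = 200, alpha = 80)
#' @export
demography <- function(theta, n, alpha = 0, rho = 0, N = 20000,
                       window_length = 50000) {
  stopifnot(is.numeric(theta), length(theta) == 1L, theta > 0,
            is.numeric(n), length(n) == 1L, n >= 2, n == round(n),
            is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(rho), length(rho) == 1L, rho >= 0,
            is.numeric(N), length(N) == 1L, N >= 2)
  structure(list(theta = theta, n = as.integer(n), alpha = alpha,
                 rho = rho, N = N, window_length = window_length),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("<demography> theta =", x$theta, " n =", x$n,
      if (x$alpha > 0) paste(" alpha =", x$alpha) else " (constant size)",
      " rho =", x$rho, " N =", x$N, "\n")
  invisible(x)
}

# growth rate per generation implied by alpha and N0 (alpha = 2 N0 r)
growth_rate <- function(params) params$alpha / (2 * params$N)

#' Selection parameters for forward sweep simulation
#'
#' @param s Selection coefficient per generation for the favored allele,
#'   0 < s <= 1. Haploid carriers receive relative fitness `1 + s/2`,
#'   i.e. half the diploid homozygote advantage (heterozygosity 0.5).
#' @param nu0 Initial favored-allele frequency at the onset of selection:
#'   `1/N` for a hard sweep (a single new copy), larger for a soft sweep
#'   from standing variation.
#' @param favored_position Base-pair coordinate of the favored site within
#'   the window; defaults to the window midpoint.
#' @return A list of class `sweep_params`.
#' @export
sweep_params <- function(s, nu0 = NULL, favored_position = NULL) {
  stopifnot(is.numeric(s), length(s) == 1L, s > 0, s <= 1)
  structure(list(s = s, nu0 = nu0, favored_position = favored_position),
            class = "sweep_params")
}
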