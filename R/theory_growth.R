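#' Scaled exponential integral e^x E1(x)
#'
#' Evaluates `exp(x) * E1(x)` with `E1(x) = integral_1^Inf exp(-x t) / t dt`
#' without overflow at large `x`: a power series (through the classic
#' `-gamma - log x + sum (-x)^k / (k * k!)` expansion) below the switchover
#' at `x = 1`, and a modified-Lentz continued fraction that yields
#' `exp(x) E1(x)` directly above it. Accurate to near machine precision over
#' the full positive axis.
#'
#' @param x Positive numeric vector.
#' @return `exp(x) * E1(x)`.
#' @export
expE1 <- function(x) {
  stopifnot(is.numeric(x), all(x > 0))
  vapply(x, expE1_scalar, numeric(1))
}

expE1_scalar <- function(x) {
  if (x < 1) {
    s <- -0.577215664901532861 - log(x)
    term <- 1
    k <- 0
    repeat {
      k <- k + 1
      term <- term * (-x) / k
      add <- -term / k
      s <- s + add
      if (abs(add) < 1e-17 * abs(s) || k > 60) break
    }
    exp(x) * s
  } else {
    # e^x E1(x) = 1 / (x + 1 - 1^2/(x + 3 - 2^2/(x + 5 - ...)))
    b <- x + 1
    C <- 1 / 1e-300
    D <- 1 / b
    h <- D
    for (i in 1:300) {
      a <- -i * i
      b <- b + 2
      D <- 1 / (b + a * D)
      C <- b + a / C
      del <- C * D
      h <- h * del
      if (abs(del - 1) < 1e-15) break
    }
    h
  }
}

#' Expected epoch durations under exponential growth
#'
#' For a population of current haploid size `N0` that has been growing
#' exponentially at rate `r` (size `N0 * exp(-r t)` at `t` generations in
#' the past, scaled growth rate `alpha = 2 N0 r`), computes the expected
#' duration of each genealogical epoch by the conditional-expectation
#' recursion: working from `k = n` down to `k = 2`, the expected duration
#' of epoch `k` given the (already computed) later epochs is
#'
#'   `t_k = (1/r) * exp(x_k) * E1(x_k)`,  `x_k = k (k - 1) exp(r tau_k) / alpha`,
#'
#' where `tau_k = t_{k+1} + ... + t_n` is the accumulated time back to the
#' start of epoch `k`. Each later epoch is plugged in at its expectation, so
#' the recursion is an approximation (accurate to about a percent); as
#' `alpha -> 0` it recovers the constant-size `t_k = 2 N0 / (k (k - 1))`.
#'
#' @param params A [demography()] with `alpha > 0`.
#' @return A tibble with columns `k` (epoch, n down to 2), `t` (expected
#'   duration, generations) and `tau` (accumulated time from the present to
#'   the start of epoch `k`).
#' @export
epoch_times_exponential <- function(params) {
  stopifnot(inherits(params, "demography"))
  if (params$alpha <= 0) {
    stop("alpha must be > 0; constant-size epoch times are 2N/(k(k-1))",
         call. = FALSE)
  }
  n <- params$n
  alpha <- params$alpha
  r <- growth_rate(params)
  ks <- n:2
  t <- numeric(length(ks))
  tau <- numeric(length(ks))
  acc <- 0
  for (i in seq_along(ks)) {
    k <- ks[i]
    tau[i] <- acc
    x <- k * (k - 1) * exp(r * acc) / alpha
    t[i] <- expE1(x) / r
    acc <- acc + t[i]
  }
  tibble::tibble(k = ks, t = t, tau = tau)
}

#' Expected l-HAF score under neutral exponential growth
#'
#' Combines the expected epoch durations from [epoch_times_exponential()]
#' with the distribution of clade sizes (which growth leaves untouched —
#' only branch lengths change) to approximate the expected l-HAF score:
#'
#'   `E[l-HAF] ~ (theta / alpha) * sum_k (r t_k) * sum_q (-1)^(l-q) S(l, q) *
#'      ((q+1)! (n+1)^(q) / (k+1)^(q)  -  q * q! * (n+1)^(q-1) / (k+1)^(q-1))`
#'
#' with `S(l, q)` the Stirling numbers of the second kind and `x^(q)` rising
#' factorials. Note `r t_k` depends only on `alpha` and `n`, so the result
#' is independent of `N0`.
#'
#' @param params A [demography()] with `alpha > 0`.
#' @param ell Positive integer exponent l.
#' @return The approximate expected l-HAF score.
#' @examples
#' expected_haf_exponential(demography(theta = 48, n = 200, alpha = 80))
#' @export
expected_haf_exponential <- function(params, ell = 1L) {
  ell <- check_ell(ell)
  stopifnot(inherits(params, "demography"))
  et <- epoch_times_exponential(params)
  n <- params$n
  r <- growth_rate(params)
  inner <- vapply(et$k, function(k) {
    tot <- 0
    for (q in 0:ell) {
      term <- factorial(q + 1) * rising_factorial(n + 1, q) /
        rising_factorial(k + 1, q)
      if (q >= 1) {
        term <- term - q * factorial(q) * rising_factorial(n + 1, q - 1) /
          rising_factorial(k + 1, q - 1)
      }
      tot <- tot + (-1)^(ell - q) * stirling2(ell, q) * term
    }
    tot
  }, numeric(1))
  params$theta / params$alpha * sum(r * et$t * inner)
}
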