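#' Simulate neutral coalescent samples
#'
#' Draws samples of `n` haplotypes under the standard neutral coalescent.
#' With `alpha = 0` epoch durations are exponential with rate
#' `k (k - 1) / (2 N)` per generation (haploid population of size `N`);
#' with `alpha > 0` the same process is run through the deterministic time
#' rescaling of an exponentially growing population, so the waiting time
#' with `k` lineages starting at past time `tau` is
#' `(1/r) log(1 + E * alpha * exp(-r tau) / (k (k - 1)))` for `E ~ Exp(1)`.
#' Mutations fall as a Poisson process at rate `theta / (2 N)` per lineage
#' per generation (infinite sites, positions uniform on the window), and
#' monomorphic columns cannot arise.
#'
#' With `rho > 0`, generation is delegated to the bundled coalescent-with-
#' recombination backend (msprime via the system `python`); genealogies are
#' not recorded in that case. See [sim_neutral_recomb()].
#'
#' @param params A [demography()].
#' @param reps Number of independent samples.
#' @param seed Optional integer seed; `NULL` continues from the current RNG
#'   state, so sequential calls inside `set.seed()` blocks are reproducible.
#' @param keep_genealogy Attach the coalescent genealogy (topology, branch
#'   lengths, mutation placements) to each sample as attribute
#'   `"genealogy"`. Only available for `rho = 0`.
#' @return A list of `reps` [hap_matrix()] objects.
#' @examples
#' s <- sim_neutral(demography(theta = 5, n = 10), reps = 2, seed = 1)
#' haf_score(s[[1]])
#' @export
sim_neutral <- function(params, reps = 1, seed = NULL,
                        keep_genealogy = FALSE) {
  stopifnot(inherits(params, "demography"), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (params$rho > 0) {
    if (keep_genealogy) {
      stop("genealogy recording is not available with recombination",
           call. = FALSE)
    }
    return(sim_neutral_recomb(params, reps))
  }
  lapply(seq_len(reps), function(i) {
    g <- sim_genealogy(params)
    sample_from_genealogy(g, params, keep_genealogy)
  })
}

# One coalescent genealogy: topology, node times (generations), mutations.
# Nodes 1..n are leaves (time 0); node n+i is the i-th coalescence.
sim_genealogy <- function(params) {
  n <- params$n
  N <- params$N
  alpha <- params$alpha
  r <- growth_rate(params)
  tot <- 2L * n - 1L
  parent <- integer(tot)
  ntime <- numeric(tot)
  epoch_t <- numeric(n)  # epoch_t[k] = duration with k lineages
  active <- seq_len(n)
  tcur <- 0
  for (k in n:2) {
    if (alpha == 0) {
      dt <- stats::rexp(1, rate = k * (k - 1) / (2 * N))
    } else {
      e <- stats::rexp(1)
      dt <- log1p(e * alpha * exp(-r * tcur) / (k * (k - 1))) / r
    }
    epoch_t[k] <- dt
    tcur <- tcur + dt
    pair <- sample.int(k, 2L)
    newn <- 2L * n - k + 1L
    parent[active[pair]] <- newn
    ntime[newn] <- tcur
    active <- c(active[-pair], newn)
  }
  blen <- ntime[parent[seq_len(tot - 1L)]] - ntime[seq_len(tot - 1L)]
  mu_region <- params$theta / (2 * N)  # mutation rate per lineage per gen
  S <- stats::rpois(1, mu_region * sum(blen))
  if (S > 0) {
    branch <- sample.int(tot - 1L, S, replace = TRUE, prob = blen)
    mtime <- ntime[branch] + stats::runif(S) * blen[branch]
    pos <- stats::runif(S, 0, params$window_length)
    while (anyDuplicated(pos)) {  # infinite sites: redraw collisions
      dup <- duplicated(pos)
      pos[dup] <- stats::runif(sum(dup), 0, params$window_length)
    }
  } else {
    branch <- integer(0)
    mtime <- numeric(0)
    pos <- numeric(0)
  }
  structure(list(n = n, parent = parent, time = ntime,
                 epoch_t = epoch_t, mut_branch = branch,
                 mut_time = mtime, mut_pos = pos),
            class = "genealogy")
}

# leaf sets subtended by each node, as a list of integer vectors
genealogy_leafsets <- function(g) {
  n <- g$n
  tot <- 2L * n - 1L
  ls <- vector("list", tot)
  for (v in seq_len(n)) ls[[v]] <- v
  kids <- split(seq_len(tot - 1L), g$parent[seq_len(tot - 1L)])
  for (v in (n + 1L):tot) {
    ch <- kids[[as.character(v)]]
    ls[[v]] <- c(ls[[ch[1L]]], ls[[ch[2L]]])
  }
  ls
}

sample_from_genealogy <- function(g, params, keep_genealogy = FALSE) {
  n <- g$n
  S <- length(g$mut_branch)
  ord <- order(g$mut_pos)
  m <- matrix(0L, n, S)
  if (S > 0) {
    ls <- genealogy_leafsets(g)
    for (j in seq_len(S)) {
      m[ls[[g$mut_branch[ord[j]]]], j] <- 1L
    }
  }
  out <- hap_matrix(m, positions = if (S) g$mut_pos[ord] else numeric(0))
  if (keep_genealogy) attr(out, "genealogy") <- g
  out
}

#' Epoch decomposition of a simulated genealogy
#'
#' Epoch `k` of a genealogy is the interval during which exactly `k`
#' ancestral lineages exist; its lineages partition the sample into `k`
#' clades. For every epoch `k` and every lineage `i` active in it, this
#' returns the number of mutations `m` that fell on that lineage within the
#' epoch and the clade size `w` (number of leaves subtended). Every
#' haplotype's l-HAF score is recoverable as
#' `sum_k m_k(v) * w_k(v)^l` over the lineages containing leaf `v`.
#'
#' @param g A `genealogy` as attached by
#'   `sim_neutral(..., keep_genealogy = TRUE)`.
#' @return A tibble with columns `k` (epoch), `node` (lineage id), `m`
#'   (mutations on the lineage during epoch `k`) and `w` (clade size).
#'   Within each epoch, `sum(w) == n`.
#' @export
genealogy_epoch_decomposition <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  n <- g$n
  tot <- 2L * n - 1L
  ls <- genealogy_leafsets(g)
  wsize <- lengths(ls)
  ctimes <- c(0, sort(g$time[(n + 1L):tot]))  # epoch boundaries
  out_k <- integer(0)
  out_node <- integer(0)
  out_m <- integer(0)
  out_w <- integer(0)
  for (k in n:2) {
    lo <- ctimes[n - k + 1L]
    hi <- ctimes[n - k + 2L]
    mid <- (lo + hi) / 2
    act <- which(g$time[seq_len(tot - 1L)] <= lo + 1e-12 &
                   g$time[g$parent[seq_len(tot - 1L)]] >= hi - 1e-12)
    # guard: exactly k lineages must be active
    if (length(act) != k) {
      act <- which(g$time[seq_len(tot - 1L)] < mid &
                     g$time[g$parent[seq_len(tot - 1L)]] > mid)
    }
    ink <- g$mut_time > lo & g$mut_time <= hi
    mcount <- tabulate(g$mut_branch[ink], nbins = tot)
    out_k <- c(out_k, rep.int(k, k))
    out_node <- c(out_node, act)
    out_m <- c(out_m, mcount[act])
    out_w <- c(out_w, wsize[act])
  }
  tibble::tibble(k = out_k, node = out_node, m = out_m, w = out_w)
}

#' Reconstruct l-HAF scores from an epoch decomposition
#'
#' Companion check to [genealogy_epoch_decomposition()]: computes each
#' leaf's l-HAF score by summing `m * w^l` along the path from the leaf to
#' the root, without ever forming the haplotype matrix.
#'
#' @inheritParams genealogy_epoch_decomposition
#' @param ell Positive integer exponent.
#' @return Numeric vector of length `n` of per-haplotype l-HAF scores.
#' @export
haf_from_genealogy <- function(g, ell = 1L) {
  ell <- check_ell(ell)
  stopifnot(inherits(g, "genealogy"))
  n <- g$n
  tot <- 2L * n - 1L
  ls <- genealogy_leafsets(g)
  wsize <- lengths(ls)
  mcount <- tabulate(g$mut_branch, nbins = tot)
  sc <- numeric(n)
  for (v in seq_len(tot - 1L)) {
    if (mcount[v] > 0L) {
      sc[ls[[v]]] <- sc[ls[[v]]] + mcount[v] * as.numeric(wsize[v])^ell
    }
  }
  sc
}
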