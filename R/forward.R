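#' Forward Wright-Fisher simulation of a selective sweep
#'
#' Simulates a haploid Wright-Fisher population of `N` genomes forward in
#' time under multiplicative viability selection on a single favored
#' allele. Carriers have relative fitness `1 + s/2`, i.e. half the diploid
#' homozygote advantage (heterozygosity 0.5). Each generation brings
#' Poisson(`theta / 2`) new infinite-sites mutations placed uniformly on
#' the window, and (when `rho > 0`) single-crossover recombination at
#' per-meiosis window rate `rho / (2 N)`. The starting population is one
#' neutral coalescent sample of `N` haplotypes, so the sweep acts on
#' equilibrium standing variation; `round(nu0 * N)` of them (at least one)
#' receive the favored allele at onset.
#'
#' Trajectories that lose the favored allele are restarted from the same
#' initial population with fresh randomness (restart count reported), so
#' every returned replicate is a sweep that progressed — the conditioning
#' under which sweep theory is derived.
#'
#' @param params A [demography()]; `N` is the population size (default
#'   scale 20000; 2000 is a practical desk scale), `theta`/`rho` the scaled
#'   rates for the window.
#' @param sweep A [sweep_params()].
#' @param sample_nu Increasing vector of favored-allele population
#'   frequencies; a sample of `n` haplotypes is drawn (without replacement)
#'   the first time each frequency is reached. Use `1` to sample at
#'   fixation.
#' @param n Sample size per drawn sample (default `params$n`).
#' @param reps Number of independent sweep replicates.
#' @param seed Optional integer seed (`NULL` = current RNG state).
#' @param max_restarts Maximum restarts after loss before giving up.
#' @param max_generations Safety cap on generations per trajectory.
#' @return A list of `reps` results; each is a list with `samples` (one
#'   [hap_matrix()] per reached threshold, with `carrier_truth` set and
#'   attributes `nu_pop` and `generation`), `trajectory` (favored-allele
#'   frequency per generation) and `restarts`.
#' @export
sim_sweep_forward <- function(params, sweep, sample_nu = 0.5,
                              n = params$n, reps = 1, seed = NULL,
                              max_restarts = 1000,
                              max_generations = 200000) {
  stopifnot(inherits(params, "demography"), inherits(sweep, "sweep_params"),
            all(diff(sample_nu) > 0), all(sample_nu > 0),
            all(sample_nu <= 1), n >= 2)
  if (!is.null(seed)) set.seed(seed)
  N <- as.integer(params$N)
  nu0 <- if (is.null(sweep$nu0)) 1 / N else sweep$nu0
  if (nu0 * N < 1) {
    stop("nu0 * N < 1: fewer than one initial carrier", call. = FALSE)
  }
  fav_pos <- if (is.null(sweep$favored_position)) {
    params$window_length / 2
  } else {
    sweep$favored_position
  }
  lapply(seq_len(reps), function(i) {
    run_sweep(params, sweep, nu0, fav_pos, sample_nu, n,
              max_restarts, max_generations)
  })
}

run_sweep <- function(params, sweep, nu0, fav_pos, sample_nu, n,
                      max_restarts, max_generations) {
  N <- as.integer(params$N)
  s <- sweep$s
  muL <- params$theta / (2 * N)          # new mutations per genome per gen
  r_window <- params$rho / (2 * N)       # crossovers per meiosis
  L <- params$window_length

  # initial standing variation: one neutral coalescent sample of N genomes
  base_params <- demography(theta = params$theta, n = N, alpha = 0,
                            rho = 0, N = N, window_length = L)
  g <- sim_genealogy(base_params)
  ls <- genealogy_leafsets(g)
  S0 <- length(g$mut_branch)
  pop0 <- vector("list", N)
  for (v in seq_len(N)) pop0[[v]] <- integer(0)
  if (S0 > 0) {
    for (j in seq_len(S0)) {
      for (v in ls[[g$mut_branch[j]]]) pop0[[v]] <- c(pop0[[v]], j)
    }
  }
  pos0 <- c(g$mut_pos, fav_pos)
  fav_id <- S0 + 1L

  ncar0 <- max(1L, as.integer(round(nu0 * N)))
  if (r_window == 0) {
    # the favored-allele count is a 1-locus Markov chain independent of the
    # linked neutral variation, so condition first (restart-on-loss on the
    # cheap chain), then evolve the full population once along the
    # successful trajectory
    tr <- draw_conditioned_trajectory(N, s, ncar0, max(sample_nu),
                                      max_restarts, max_generations)
    res <- replay_population(pop0, pos0, fav_id, tr$counts, N, muL, L,
                             sample_nu, n)
    res$restarts <- tr$restarts
    return(res)
  }
  restarts <- 0L
  repeat {
    res <- run_sweep_once(pop0, pos0, fav_id, ncar0, N, s, muL, r_window,
                          L, sample_nu, n, max_generations)
    if (!is.null(res)) break
    restarts <- restarts + 1L
    if (restarts > max_restarts) {
      stop("favored allele lost in ", max_restarts,
           " consecutive trajectories; increase max_restarts or s",
           call. = FALSE)
    }
  }
  res$restarts <- restarts
  res
}

# favored-allele count trajectory under multiplicative selection,
# conditioned (by restart) on reaching nu_max before loss
draw_conditioned_trajectory <- function(N, s, ncar0, nu_max, max_restarts,
                                        max_generations) {
  target <- ceiling(nu_max * N - 1e-9)
  restarts <- 0L
  repeat {
    counts <- integer(0)
    i <- ncar0
    gen <- 0L
    ok <- TRUE
    while (i < target) {
      gen <- gen + 1L
      if (gen > max_generations) {
        stop("sweep did not reach nu = ", nu_max, " within ",
             max_generations, " generations", call. = FALSE)
      }
      p <- (1 + s / 2) * i / ((1 + s / 2) * i + (N - i))
      i <- stats::rbinom(1L, N, p)
      counts <- c(counts, i)
      if (i == 0L) {
        ok <- FALSE
        break
      }
    }
    if (ok) return(list(counts = c(ncar0, counts), restarts = restarts))
    restarts <- restarts + 1L
    if (restarts > max_restarts) {
      stop("favored allele lost in ", max_restarts,
           " consecutive trajectories; increase max_restarts or s",
           call. = FALSE)
    }
  }
}

# evolve the full population along a fixed carrier-count trajectory:
# conditional on the counts, carrier children pick carrier parents
# uniformly and non-carrier children non-carrier parents
replay_population <- function(pop0, pos0, fav_id, counts, N, muL, L,
                              sample_nu, n) {
  pop <- pop0
  pos <- pos0
  carrier_idx <- sample.int(N, counts[1])
  for (v in carrier_idx) pop[[v]] <- c(pop[[v]], fav_id)
  is_car <- logical(N)
  is_car[carrier_idx] <- TRUE

  next_thr <- 1L
  samples <- list()
  traj <- numeric(0)
  gen <- 0L
  for (step in seq_along(counts)) {
    freq <- counts[step]
    while (next_thr <= length(sample_nu) &&
           freq / N >= sample_nu[next_thr] - 1e-12) {
      samples[[next_thr]] <- draw_sample(pop, pos, fav_id, n, N, gen, freq)
      next_thr <- next_thr + 1L
    }
    if (next_thr > length(sample_nu)) break
    if (step == length(counts)) break
    gen <- gen + 1L
    c_next <- counts[step + 1L]
    car_parents <- which(is_car)
    non_parents <- which(!is_car)
    child_car <- sample.int(N, c_next)
    is_car_new <- logical(N)
    is_car_new[child_car] <- TRUE
    parent <- integer(N)
    parent[child_car] <-
      car_parents[sample.int(length(car_parents), c_next, replace = TRUE)]
    parent[!is_car_new] <-
      non_parents[sample.int(length(non_parents), N - c_next,
                             replace = TRUE)]
    pop <- pop[parent]
    is_car <- is_car_new
    nmut <- stats::rpois(1L, N * muL)
    if (nmut > 0L) {
      tgt <- sample.int(N, nmut, replace = TRUE)
      newpos <- stats::runif(nmut, 0, L)
      for (j in seq_len(nmut)) {
        pos <- c(pos, newpos[j])
        pop[[tgt[j]]] <- c(pop[[tgt[j]]], length(pos))
      }
    }
    traj <- c(traj, c_next / N)
  }
  list(samples = samples, trajectory = traj)
}

run_sweep_once <- function(pop0, pos0, fav_id, ncar0, N, s, muL, r_window,
                           L, sample_nu, n, max_generations) {
  pop <- pop0
  pos <- pos0
  carriers0 <- sample.int(N, ncar0)
  for (v in carriers0) pop[[v]] <- c(pop[[v]], fav_id)
  has_fav <- logical(N)
  has_fav[carriers0] <- TRUE

  next_thr <- 1L
  traj <- numeric(0)
  samples <- list()
  gen <- 0L
  freq <- ncar0
  repeat {
    # sample at each newly crossed threshold
    while (next_thr <= length(sample_nu) &&
           freq / N >= sample_nu[next_thr] - 1e-12) {
      samples[[next_thr]] <- draw_sample(pop, pos, fav_id, n, N, gen, freq)
      next_thr <- next_thr + 1L
    }
    if (next_thr > length(sample_nu)) break
    if (freq == 0L) return(NULL)        # lost: caller restarts
    if (freq == N && sample_nu[next_thr] > 1) break
    gen <- gen + 1L
    if (gen > max_generations) {
      stop("sweep did not reach nu = ", sample_nu[next_thr], " within ",
           max_generations, " generations", call. = FALSE)
    }
    fit <- 1 + s / 2 * has_fav
    parent <- sample.int(N, N, replace = TRUE, prob = fit)
    newpop <- pop[parent]
    newfav <- has_fav[parent]
    # single-crossover recombination
    if (r_window > 0) {
      nrec <- stats::rbinom(1L, N, r_window)
      if (nrec > 0L) {
        rec_child <- sample.int(N, nrec)
        rec_p2 <- sample.int(N, nrec, replace = TRUE, prob = fit)
        xpt <- stats::runif(nrec, 0, L)
        for (j in seq_len(nrec)) {
          p1 <- newpop[[rec_child[j]]]
          p2 <- pop[[rec_p2[j]]]
          h <- c(p1[pos[p1] < xpt[j]], p2[pos[p2] >= xpt[j]])
          newpop[[rec_child[j]]] <- h
          newfav[rec_child[j]] <- fav_id %in% h
        }
      }
    }
    # new mutations
    nmut <- stats::rpois(1L, N * muL)
    if (nmut > 0L) {
      tgt <- sample.int(N, nmut, replace = TRUE)
      newpos <- stats::runif(nmut, 0, L)
      for (j in seq_len(nmut)) {
        pos <- c(pos, newpos[j])
        newpop[[tgt[j]]] <- c(newpop[[tgt[j]]], length(pos))
      }
    }
    pop <- newpop
    has_fav <- newfav
    freq <- sum(has_fav)
    traj <- c(traj, freq / N)
  }
  list(samples = samples, trajectory = traj)
}

draw_sample <- function(pop, pos, fav_id, n, N, gen, freq) {
  idx <- sample.int(N, n)
  ids <- sort(unique(unlist(pop[idx], use.names = FALSE)))
  m <- matrix(0L, n, length(ids))
  for (v in seq_len(n)) {
    m[v, match(pop[[idx[v]]], ids)] <- 1L
  }
  truth <- vapply(idx, function(v) fav_id %in% pop[[v]], logical(1))
  ord <- order(pos[ids])
  p <- pos[ids][ord]
  dup <- c(FALSE, diff(p) <= 0)
  p[dup] <- p[dup] + 1e-9 * seq_len(sum(dup))
  out <- filter_polymorphic(
    hap_matrix(m[, ord, drop = FALSE], positions = p,
               carrier_truth = truth))
  attr(out, "nu_pop") <- freq / N
  attr(out, "generation") <- gen
  out
}
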