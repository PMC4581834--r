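# Independent brute-force oracles used across tests.

# The worked 4-haplotype example used throughout the unit tests:
# rows h1..h4, column derived counts (3, 1, 1).
example_hm <- function() {
  hap_matrix(rbind(c(1, 1, 0),
                   c(1, 0, 1),
                   c(1, 0, 0),
                   c(0, 0, 0)))
}

random_hap_matrix <- function(n, S, p = 0.4) {
  m <- matrix(rbinom(n * S, 1, p), n, S)
  filter_polymorphic(hap_matrix(m))
}

# Naive per-haplotype power-sum scorer: loops, no matrix algebra.
naive_ell_haf <- function(x, ell) {
  n <- nrow(x)
  w <- colSums(x)
  vapply(seq_len(n), function(v) {
    sum((w[x[v, ] == 1])^ell)
  }, numeric(1))
}

# Enumerate all coalescent merge histories of n labeled lineages and return
# E[(1/k) sum_i f(w_{k,i})] for each epoch k: the expectation of f applied
# to the clade size of a uniformly chosen epoch-k lineage. Each merge picks
# an unordered pair uniformly, which is exactly the neutral coalescent
# topology distribution.
enumerate_clade_expectation <- function(n, f) {
  acc <- stats::setNames(numeric(n - 1), as.character(2:n))
  recurse <- function(sizes, prob) {
    k <- length(sizes)
    if (k >= 2) {
      acc[as.character(k)] <<- acc[as.character(k)] +
        prob * mean(vapply(sizes, f, numeric(1)))
      pairs <- utils::combn(k, 2)
      p_each <- prob / ncol(pairs)
      for (c_i in seq_len(ncol(pairs))) {
        i <- pairs[1, c_i]; j <- pairs[2, c_i]
        recurse(c(sizes[-c(i, j)], sizes[i] + sizes[j]), p_each)
      }
    }
  }
  recurse(rep(1, n), 1)
  acc
}

# Count set partitions of {1..l} into exactly q non-empty blocks by direct
# enumeration (restricted growth strings).
count_set_partitions <- function(l, q) {
  if (l == 0) return(as.integer(q == 0))
  count <- 0L
  assign_next <- function(labels, maxlab) {
    i <- length(labels) + 1L
    if (i > l) {
      if (maxlab == q) count <<- count + 1L
      return(invisible())
    }
    for (lab in seq_len(min(maxlab + 1L, q))) {
      assign_next(c(labels, lab), max(maxlab, lab))
    }
  }
  assign_next(integer(0), 0L)
  count
}

# Simulate clade sizes of epoch k directly (topology only, no times).
simulate_clade_sizes <- function(n, k) {
  sizes <- rep(1L, n)
  for (m in n:(k + 1)) {
    pair <- sample.int(m, 2)
    sizes <- c(sizes[-pair], sizes[pair[1]] + sizes[pair[2]])
  }
  sizes
}

# Exact two-sided rank-sum p-value by enumerating all assignments of the
# pooled scores to the two groups.
exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(length(pooled), na)
  stats_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}
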