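# Independent brute-force reference for the network equations, written as
# literal neuron-by-neuron loops. Deliberately shares no code with the
# package's vectorized paths.

# single synchronous output pass, f* initialized to E
oracle_outputs <- function(W, E) {
  N <- length(E)
  f <- numeric(N)
  for (p in seq_len(N)) f[p] <- E[p] + sum(E * W[, p])
  f
}

# full recall procedure: clamp partial input, analyze, resolve the first
# tied set (schema order) by a uniform random clamp, re-analyze, repeat
oracle_recall <- function(net, memory, input_sets, tol = 1e-12) {
  sc <- net$schema
  glob <- sc$offset + as.integer(memory)
  E <- numeric(net$N)
  E[glob[input_sets]] <- net$e_mag
  repeat {
    f <- oracle_outputs(net$W, E)
    winners <- rep(NA_integer_, sc$n)
    tie_set <- 0L
    tie_feats <- NULL
    for (i in seq_len(sc$n)) {
      v <- f[(sc$offset[i] + 1L):(sc$offset[i] + sc$M[i])]
      mx <- max(v)
      if (mx <= 0) next
      tied <- which(v >= mx * (1 - tol))
      if (length(tied) > 1L) {
        if (tie_set == 0L) { tie_set <- i; tie_feats <- tied }
      } else winners[i] <- tied
    }
    if (tie_set == 0L)
      return(list(features = winners,
                  hit = !anyNA(winners) && all(winners == memory)))
    pick <- tie_feats[sample.int(length(tie_feats), 1L)]
    E[sc$offset[tie_set] + pick] <- net$e_mag
  }
}

# schema with n sets of m features each, generic labels
toy_schema <- function(n, m) {
  m <- rep_len(m, n)
  san_schema(stats::setNames(
    lapply(seq_len(n), function(i) sprintf("s%d_f%d", i, seq_len(m[i]))),
    sprintf("set%d", seq_len(n))))
}

# dataset of i pairwise feature-disjoint memories over n sets
# (memory r uses feature r in every set)
disjoint_dataset <- function(i, n = 8) {
  san_dataset(toy_schema(n, i), matrix(rep(seq_len(i), n), i, n))
}

# the two-memory construction for tie statistics: identical on sets 1..4
# (single-feature sets), disjoint on sets 5..8
shared_pair_dataset <- function() {
  sc <- toy_schema(8, c(1, 1, 1, 1, 2, 2, 2, 2))
  san_dataset(sc, rbind(rep(1L, 8), c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)))
}

# random small instance for oracle-equivalence sweeps
random_instance <- function() {
  n <- sample(2:4, 1)
  m <- sample(1:4, n, replace = TRUE)
  sc <- toy_schema(n, m)
  i <- sample(1:12, 1)
  mem <- vapply(seq_len(n), function(j) sample.int(m[j], i, replace = TRUE),
                integer(i))
  mem <- matrix(mem, i, n)
  list(dataset = san_dataset(sc, mem), n = n, m = m, i = i)
}
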