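# Relative tolerance under which two neuron outputs are considered tied.
# Weights are common multiples of v_ON (possibly decayed by identical
# factors), so true ties are bit-equal in practice; the tolerance only
# guards accumulated floating error.
.san_tie_tol <- 1e-12

#' Initialize a segmented attractor network
#'
#' Builds the square recurrent weight grid over all `N = sum(M_i)` feature
#' neurons. Weights are indexed `(pre-synaptic, post-synaptic)` and start
#' at zero. Neurons within the same set are never connected (the grid's
#' "empty diagonal" blocks), and there are no self-connections; with
#' `v_ON << |E| / N`, recurrent feedback can never outweigh external
#' input, so input is always trusted as correct.
#'
#' @param schema A [san_schema].
#' @param v_on Programming value a synapse takes when a memory is stored
#'   (default 0.001).
#' @param e_mag Magnitude of external input `|E|` (default 1).
#' @return An object of class `san_network`: list with `W` (N x N weight
#'   matrix), `v_on`, `e_mag`, `schema`, `set_id` (neuron -> set index),
#'   and `N`.
#' @export
init_network <- function(schema, v_on = 0.001, e_mag = 1) {
  stopifnot(inherits(schema, "san_schema"))
  if (v_on <= 0) stop("v_on must be positive")
  if (e_mag <= 0) stop("e_mag must be positive")
  N <- schema$N
  structure(
    list(
      W = matrix(0, N, N),
      v_on = v_on,
      e_mag = e_mag,
      schema = schema,
      set_id = rep.int(seq_len(schema$n), schema$M),
      N = N
    ),
    class = "san_network"
  )
}

#' @export
print.san_network <- function(x, ...) {
  cat(sprintf("san_network: %d neurons in %d sets, %d programmed synapses (v_ON=%g)\n",
              x$N, x$schema$n, sum(x$W > 0), x$v_on))
  invisible(x)
}

# Single synchronous output pass: f = E + t(W) %*% f_prev, computed by
# summing only the active pre-synaptic rows in ascending neuron order.
# Every code path in the package (scalar recall, batched evaluation, the
# exported compute_outputs) funnels through this function so their
# floating-point results are bit-identical.
.san_outputs <- function(W, E, f_prev = E) {
  act <- which(f_prev != 0)
  if (!length(act)) return(E)
  E + .colSums(W[act, , drop = FALSE] * f_prev[act], length(act), ncol(W))
}

#' Compute neuron outputs for a given external input
#'
#' One synchronous pass of the network equation
#' `f = E + t(W) %*% f_prev` with `f_prev` initialized to `E`: each
#' neuron's output is its external input plus the weighted recurrent
#' feedback from currently active neurons. The network's analyze / clamp /
#' re-analyze recall procedure recomputes this single pass from scratch
#' after every tie-breaking clamp; multi-pass settling is exposed through
#' `passes` for experimentation but is not the default semantics.
#'
#' @param net A [san_network].
#' @param E Numeric vector of length `N`; entries must be 0 or `e_mag`.
#' @param passes Number of synchronous passes (default 1).
#' @return An object of class `san_activation`: list with `E` and `f`.
#' @export
compute_outputs <- function(net, E, passes = 1L) {
  stopifnot(inherits(net, "san_network"))
  if (length(E) != net$N)
    stop(sprintf("E must have length %d, got %d", net$N, length(E)))
  if (!all(E == 0 | E == net$e_mag))
    stop("E entries must be 0 or e_mag")
  f <- E
  for (p in seq_len(passes)) f <- .san_outputs(net$W, E, f)
  structure(list(E = E, f = f), class = "san_activation")
}

#' Associate (store) a memory
#'
#' Hebbian programming: every ordered pair of the memory's features lying
#' in distinct sets has its connecting weight set to `v_ON`
#' unconditionally — so re-associating a memory whose weights have decayed
#' restores them to full strength (reinforcement). All other weights are
#' untouched; intra-set and self weights stay zero.
#'
#' @param net A [san_network].
#' @param memory Integer vector of length `n` (one feature index per set),
#'   e.g. from [get_memory()].
#' @return The updated network.
#' @export
associate <- function(net, memory) {
  stopifnot(inherits(net, "san_network"))
  idx <- memory_neurons(net$schema, .check_memory(net$schema, memory))
  net$W[idx, idx] <- net$v_on
  net$W[cbind(idx, idx)] <- 0
  net
}

.check_memory <- function(schema, memory) {
  memory <- as.integer(memory)
  if (length(memory) != schema$n)
    stop("memory must have one feature per set")
  if (anyNA(memory) || any(memory < 1L) || any(memory > schema$M))
    stop("memory has a feature index out of range")
  memory
}

#' Winner-take-all readout of an activation state
#'
#' Per set, the winning feature is the one with the strictly positive,
#' unique maximum output. A set whose outputs are all zero yields the
#' sentinel `NA` ("none"). A set with two or more outputs within relative
#' tolerance `1e-12` of its positive maximum is flagged as tied; ties are
#' resolved by the recall procedure, not here.
#'
#' @param act A `san_activation` from [compute_outputs()], or a bare
#'   numeric output vector.
#' @param net The [san_network] the activation belongs to.
#' @return An object of class `san_readout`: list with `features`
#'   (length-`n` integer vector of winning feature indices, `NA` =
#'   sentinel), `neurons` (their global indices), and `tie_sets` (integer
#'   vector of sets with unresolved ties; empty when the readout is final).
#' @export
readout <- function(act, net) {
  f <- if (inherits(act, "san_activation")) act$f else act
  stopifnot(inherits(net, "san_network"), length(f) == net$N)
  sc <- net$schema
  features <- rep(NA_integer_, sc$n)
  tie_sets <- integer(0)
  for (i in seq_len(sc$n)) {
    v <- f[(sc$offset[i] + 1L):(sc$offset[i] + sc$M[i])]
    mx <- max(v)
    if (mx <= 0) next                      # all-zero set -> sentinel
    tied <- which(v >= mx * (1 - .san_tie_tol))
    if (length(tied) > 1L) tie_sets <- c(tie_sets, i)
    else features[i] <- tied
  }
  structure(
    list(features = features,
         neurons  = ifelse(is.na(features), NA_integer_, sc$offset + features),
         tie_sets = tie_sets),
    class = "san_readout"
  )
}

#' Pattern-completion recall of a memory from partial input
#'
#' Clamps external input on the memory's features in `input_sets`, computes
#' outputs, and reads out the per-set winners. While some set has a tie
#' among its nonzero maxima, the first tied set (in schema order) has one
#' of its tied features selected uniformly at random and clamped with
#' external input, and the network is re-analyzed; clamps persist for the
#' rest of the trial. Sets whose outputs are all zero are ignored
#' (sentinel `NA`). The trial is a hit only if the final readout
#' reproduces *all* `n` of the memory's features exactly; any sentinel is
#' a miss.
#'
#' Tie selection draws from R's global RNG; seed with `set.seed()` for
#' reproducible runs. The network itself is never modified.
#'
#' @param net A [san_network].
#' @param memory Integer feature-index vector of length `n`.
#' @param input_sets Integer vector of set indices receiving input
#'   (at least 1).
#' @return List with `readout` (a `san_readout` with no remaining ties),
#'   `hit` (logical), and `tiebreaks` (number of tie-resolution clamps).
#' @export
recall <- function(net, memory, input_sets) {
  stopifnot(inherits(net, "san_network"))
  memory <- .check_memory(net$schema, memory)
  input_sets <- as.integer(input_sets)
  if (length(input_sets) < 1L || any(input_sets < 1L | input_sets > net$schema$n))
    stop("input_sets must name at least one valid set")
  glob <- memory_neurons(net$schema, memory)
  E <- numeric(net$N)
  E[glob[input_sets]] <- net$e_mag
  sc <- net$schema
  ties <- 0L
  repeat {
    f <- .san_outputs(net$W, E)
    ro <- readout(f, net)
    if (!length(ro$tie_sets)) break
    s <- ro$tie_sets[1L]                 # resolve first tied set only
    v <- f[(sc$offset[s] + 1L):(sc$offset[s] + sc$M[s])]
    tied <- which(v >= max(v) * (1 - .san_tie_tol))
    pick <- tied[sample.int(length(tied), 1L)]
    E[sc$offset[s] + pick] <- net$e_mag  # clamp persists for the trial
    ties <- ties + 1L
  }
  hit <- !anyNA(ro$features) && all(ro$features == memory)
  list(readout = ro, hit = hit, tiebreaks = ties)
}

# Lean recall used by the batched evaluation engine. Semantics and random
# draws are identical to recall(): first tied set in schema order, uniform
# pick among tied features, clamp persists, re-analyze. Returns the final
# per-set winning feature indices with 0 as the "none" sentinel.
.recall_fast <- function(W, N, n_sets, lo, hi, e_mag, glob, input_sets) {
  E <- numeric(N)
  E[glob[input_sets]] <- e_mag
  feats <- integer(n_sets)
  repeat {
    act <- which(E != 0)
    f <- E + .colSums(W[act, , drop = FALSE] * E[act], length(act), N)
    tie_set <- 0L
    for (i in seq_len(n_sets)) {
      v <- f[lo[i]:hi[i]]
      mx <- max(v)
      if (mx <= 0) { feats[i] <- 0L; next }
      tied <- which(v >= mx * (1 - .san_tie_tol))
      if (length(tied) > 1L) { tie_set <- i; tied_keep <- tied; break }
      feats[i] <- tied
    }
    if (tie_set == 0L) return(feats)
    pick <- tied_keep[sample.int(length(tied_keep), 1L)]
    E[lo[tie_set] - 1L + pick] <- e_mag
  }
}

#' Save / load a network checkpoint
#'
#' Serializes the weight grid together with the schema and parameters so a
#' long run can be checkpointed and resumed. Uses R's native serialization
#' (`.rds`).
#'
#' @param net A [san_network].
#' @param path File path.
#' @return `write_network` returns `path` invisibly; `read_network`
#'   returns the restored `san_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "san_network"))
  saveRDS(net, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "san_network"))
  net
}
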