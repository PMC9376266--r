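#' Simulation configuration
#'
#' Describes one lifelong-learning run: the network parameters, the number
#' of input sets per recall trial, the learning behaviors, the random
#' seeds, and the evaluation cadence. Two independent seeds keep the
#' memory presentation order fixed while behaviors or tie-breaking vary,
#' so runs with different behaviors see the same memory sequence.
#'
#' @param v_on Synapse programming value (default 0.001).
#' @param e_mag External input magnitude (default 1).
#' @param k_input Sets receiving input per recall trial; default `n / 2`
#'   (rounded down), resolved against the dataset at run time.
#' @param behaviors A [behavior_config()] (default: all disabled).
#' @param seed_sequence Seed for the memory presentation order.
#' @param seed_ties Seed for recall tie-breaking.
#' @param eval_every Evaluate recall every `eval_every`-th step (default 1,
#'   i.e. after every association; larger values are an engineering
#'   escape hatch for desk-scale runs).
#' @param passes Synchronous output passes per analysis (default 1).
#' @return An object of class `san_sim_config`.
#' @export
simulation_config <- function(v_on = 0.001, e_mag = 1, k_input = NULL,
                              behaviors = behavior_config(),
                              seed_sequence = 1L, seed_ties = 2L,
                              eval_every = 1L, passes = 1L) {
  stopifnot(inherits(behaviors, "san_behaviors"))
  if (eval_every < 1L) stop("eval_every must be >= 1")
  if (v_on <= 0 || e_mag <= 0) stop("v_on and e_mag must be positive")
  structure(
    list(v_on = v_on, e_mag = e_mag, k_input = k_input,
         behaviors = behaviors,
         seed_sequence = as.integer(seed_sequence),
         seed_ties = as.integer(seed_ties),
         eval_every = as.integer(eval_every), passes = as.integer(passes)),
    class = "san_sim_config"
  )
}

#' Random presentation order of a dataset's memories
#'
#' A uniformly random permutation of all `I_tot` memories, deterministic
#' given the seed; each memory is shown to the network exactly once.
#'
#' @param d A [san_dataset].
#' @param seed Integer seed.
#' @return Integer permutation of `1:I_tot` (sequence position -> dataset
#'   row index).
#' @export
generate_sequence <- function(d, seed) {
  stopifnot(inherits(d, "san_dataset"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  sample.int(d$I_tot)
}

#' Evaluate recall of every shown memory under every input combination
#'
#' Runs `t * n_combos` recall trials — each memory shown so far, queried
#' through each combination of `k` input sets — and records hits,
#' occurrences and the step's unique-recall set in the log. The network is
#' strictly read-only during evaluation: recall clamps live on a scratch
#' input vector, never on the weights.
#'
#' Two execution paths produce bit-identical results: a trial-by-trial
#' reference (`batched = FALSE`) that calls [recall()] for every trial,
#' and a batched path that computes all of one memory's combinations as a
#' grid product and only falls back to [recall()] for the rare trials with
#' output ties (tie trials consume the same random draws in both paths, in
#' the same order).
#'
#' @param net A [san_network].
#' @param dataset The [san_dataset] being simulated.
#' @param sequence Presentation order from [generate_sequence()].
#' @param t Current time step (memories `sequence[1:t]` have been shown).
#' @param combos A [san_combos].
#' @param log A [metrics_log()]; modified in place.
#' @param batched Use the batched engine (default TRUE).
#' @return The log, invisibly.
#' @export
evaluate_step <- function(net, dataset, sequence, t, combos, log,
                          batched = TRUE) {
  stopifnot(inherits(net, "san_network"), t >= 1L)
  sc <- net$schema
  C <- combos$n_combos
  shown <- sequence[seq_len(t)]
  if (!batched) {
    for (s in seq_len(t)) {
      m <- dataset$memories[shown[s], ]
      for (c in seq_len(C)) {
        r <- recall(net, m, combos$sets[c, ])
        record_trial(log, t, c, r$readout, r$hit)
      }
    }
    .finalize_step(log, t)
    return(invisible(log))
  }

  W <- net$W
  N <- net$N
  n_sets <- sc$n
  e_mag <- net$e_mag
  tol <- .san_tie_tol
  lo <- sc$offset + 1L
  hi <- sc$offset + sc$M
  mem <- dataset$memories
  offset <- sc$offset
  k <- combos$k
  combo_rows <- lapply(seq_len(C), function(c) combos$sets[c, ])
  clamp_row <- rep(seq_len(C), each = k)
  sets_vec <- as.vector(t(combos$sets))
  m_is_tot <- sc$M                     # per-set widths
  hits_acc <- integer(C)
  occ_acc <- integer(dataset$I_tot)    # counts by sequence position
  uniq_acc <- integer(0)

  for (s in seq_len(t)) {
    m <- mem[shown[s], ]
    glob <- offset + m
    # pre-multiplied weight rows of this memory's 8 neurons; summing the
    # clamped subset (ascending order) reproduces the scalar-path
    # arithmetic bit for bit
    R8m <- W[glob, , drop = FALSE] * e_mag
    Fm <- matrix(0, C, N)
    for (c in seq_len(C))
      Fm[c, ] <- .colSums(R8m[combo_rows[[c]], , drop = FALSE], k, N)
    idx <- cbind(clamp_row, glob[sets_vec])
    Fm[idx] <- Fm[idx] + e_mag
    # per-set winner analysis across all C rows at once
    winners <- matrix(NA_integer_, C, n_sets)
    any_tie <- logical(C)
    for (i in seq_len(n_sets)) {
      sub <- Fm[, lo[i]:hi[i], drop = FALSE]
      j <- max.col(sub, ties.method = "first")
      rmax <- sub[cbind(seq_len(C), j)]
      nt <- .rowSums(sub >= rmax * (1 - tol), C, m_is_tot[i])
      pos <- rmax > 0
      ok <- pos & nt == 1L
      winners[ok, i] <- j[ok]
      any_tie <- any_tie | (pos & nt > 1L)
    }
    # resolve tie trials with the scalar procedure, in combination order,
    # so random draws match the trial-by-trial reference exactly
    tie_ids <- which(any_tie)
    for (c in tie_ids)
      winners[c, ] <- {
        f <- .recall_fast(W, N, n_sets, lo, hi, e_mag, glob, combo_rows[[c]])
        ifelse(f == 0L, NA_integer_, f)
      }
    complete <- !is.na(.rowSums(winners, C, n_sets))
    hitv <- complete & .rowSums(winners == rep(m, each = C), C, n_sets,
                                na.rm = TRUE) == n_sets
    hits_acc <- hits_acc + hitv
    if (any(complete)) {
      keys <- apply(winners[complete, , drop = FALSE], 1L, paste, collapse = "\r")
      row <- match(keys, log$keys)
      posm <- log$row_to_seq[row[!is.na(row)]]
      if (length(posm)) {
        cnt <- tabulate(posm, dataset$I_tot)
        occ_acc <- occ_acc + cnt
        uniq_acc <- c(uniq_acc, unique(posm))
      }
    }
  }
  log$trials[t, ] <- log$trials[t, ] + t
  log$hits[t, ] <- log$hits[t, ] + hits_acc
  nz <- which(occ_acc > 0L)
  log$occurrences[nz, t] <- log$occurrences[nz, t] + occ_acc[nz]
  log$unique_sets[[t]] <- c(log$unique_sets[[t]], unique(uniq_acc))
  .finalize_step(log, t)
  invisible(log)
}

#' Run a lifelong-learning simulation
#'
#' The five-phase loop: after a one-time setup (network initialization and
#' sequence generation), each time step `t = 1..I_tot` performs, in order:
#' forgetting decay (if enabled), association of the step's memory,
#' the predictive sweep (if enabled), the erase check (if enabled), and —
#' every `eval_every` steps — a full recall evaluation of every shown
#' memory under every input combination, with metrics recorded. The run
#' ends when the whole sequence has been shown and evaluated.
#'
#' @param dataset A [san_dataset], a [synth_spec] (generated on the fly),
#'   or a CSV path (loaded with [load_dataset()]).
#' @param config A [simulation_config()].
#' @param batched Use the batched evaluation engine (default TRUE).
#' @param progress Print a progress line every 50 steps (default FALSE).
#' @return An object of class `san_sim_result`: list with `metrics` (the
#'   `san_metrics` log), `network` (final state), `sequence`, `dataset`,
#'   `combos`, and `manifest` (config echo, seeds and dimensions
#'   sufficient to reproduce the run bit-for-bit).
#' @export
run_simulation <- function(dataset, config = simulation_config(),
                           batched = TRUE, progress = FALSE) {
  stopifnot(inherits(config, "san_sim_config"))
  if (inherits(dataset, "san_synth_spec")) dataset <- generate_synthetic(dataset)
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  stopifnot(inherits(dataset, "san_dataset"))
  sc <- dataset$schema
  k <- if (is.null(config$k_input)) max(1L, sc$n %/% 2L) else as.integer(config$k_input)
  if (k < 1L || k >= sc$n) stop("k_input must satisfy 1 <= k_input < n")

  net <- init_network(sc, v_on = config$v_on, e_mag = config$e_mag)
  sequence <- generate_sequence(dataset, config$seed_sequence)
  combos <- enumerate_combos(sc$n, k, dataset_u_factors(dataset))
  log <- metrics_log(dataset, combos, sequence)
  bh <- config$behaviors
  p_th <- bh$p_th_von * config$v_on
  r_th <- bh$r_th_von * config$v_on

  set.seed(config$seed_ties)   # single stream for all tie-breaking
  for (t in seq_len(dataset$I_tot)) {
    m <- dataset$memories[sequence[t], ]
    if (bh$forgetting) net <- apply_forgetting(net, bh$d_rate)
    net <- associate(net, m)
    if (bh$predictive) {
      pr <- apply_predictive(net, m, p_th)
      net <- pr$net
      if (pr$n_predictions > 0L)
        log$prediction_log[[length(log$prediction_log) + 1L]] <-
          list(t = t, neurons = pr$predicted, n = pr$n_predictions)
    }
    if (bh$erase) {
      er <- apply_erase(net, r_th)
      net <- er$net
      if (length(er$erased))
        log$erasure_log[[length(log$erasure_log) + 1L]] <-
          list(t = t, neurons = er$erased, pre_sums = er$pre_sums)
    }
    if (t %% config$eval_every == 0L)
      evaluate_step(net, dataset, sequence, t, combos, log, batched = batched)
    if (progress && t %% 50L == 0L)
      message(sprintf("step %d/%d  umr=%.3f", t, dataset$I_tot, log$umr[t]))
  }

  structure(
    list(metrics = log, network = net, sequence = sequence,
         dataset = dataset, combos = combos,
         manifest = list(
           package_version = as.character(utils::packageVersion("sanet")),
           n = sc$n, N = sc$N, I_tot = dataset$I_tot, k_input = k,
           v_on = config$v_on, e_mag = config$e_mag,
           behaviors = unclass(bh),
           seed_sequence = config$seed_sequence,
           seed_ties = config$seed_ties,
           eval_every = config$eval_every,
           sequence = sequence)),
    class = "san_sim_result"
  )
}

#' @export
print.san_sim_result <- function(x, ...) {
  steps <- which(!is.na(x$metrics$umr))
  final_umr <- if (length(steps)) x$metrics$umr[max(steps)] else NA
  cat(sprintf(paste0(
    "san_sim_result: %d memories, %d sets, k=%d\n",
    "  final UMR: %.4f   predictions: %d   erasure events: %d\n"),
    x$dataset$I_tot, x$dataset$schema$n, x$manifest$k_input,
    final_umr,
    sum(vapply(x$metrics$prediction_log, `[[`, integer(1), "n")),
    length(x$metrics$erasure_log)))
  invisible(x)
}

#' Summarize a finished run
#'
#' @param object A `san_sim_result`.
#' @param ... Unused.
#' @return List with `final_umr`, `peak_hit_rate`, `n_predictions`,
#'   `n_erasure_events`, and `mean_hit_rate_by_step`.
#' @export
summary.san_sim_result <- function(object, ...) {
  log <- object$metrics
  steps <- which(!is.na(log$umr))
  hr <- log$hits[steps, , drop = FALSE] / pmax(log$trials[steps, , drop = FALSE], 1L)
  list(
    final_umr = log$umr[max(steps)],
    peak_hit_rate = max(hr),
    n_predictions = sum(vapply(log$prediction_log, `[[`, integer(1), "n")),
    n_erasure_events = length(log$erasure_log),
    mean_hit_rate_by_step = stats::setNames(rowMeans(hr), steps)
  )
}
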