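#' Enumerate recall input combinations, ordered by average uniqueness
#'
#' All `choose(n, k)` subsets of `k` sets, each with its `U_avg` (mean of
#' the member sets' U-factors), sorted ascending by `U_avg` with ties
#' broken lexicographically by set indices. This ordering is the y-axis of
#' the hit-rate surface: higher rows query the network through more unique
#' parts of the weight grid.
#'
#' @param n Number of sets.
#' @param k Input sets per recall trial (`0 < k <= n`).
#' @param u Numeric vector of per-set U-factors (length `n`), e.g. from
#'   [dataset_u_factors()].
#' @return An object of class `san_combos`: list with `sets` (matrix,
#'   one row per combination, columns the `k` sorted set indices),
#'   `u_avg` (numeric), and `n_combos`.
#' @export
enumerate_combos <- function(n, k, u) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 1L || k > n) stop("k must satisfy 0 < k <= n")
  if (length(u) != n) stop("u must have one entry per set")
  sets <- t(utils::combn(n, k))
  u_avg <- rowMeans(matrix(u[sets], nrow(sets), k))
  ord <- do.call(order, c(list(u_avg), lapply(seq_len(k), function(j) sets[, j])))
  structure(
    list(sets = sets[ord, , drop = FALSE], u_avg = u_avg[ord],
         n_combos = nrow(sets), k = k),
    class = "san_combos"
  )
}

#' @export
print.san_combos <- function(x, ...) {
  cat(sprintf("san_combos: %d combinations of %d sets, U_avg in [%.3f, %.3f]\n",
              x$n_combos, x$k, min(x$u_avg), max(x$u_avg)))
  invisible(x)
}

#' Create a metrics log for a simulation run
#'
#' Mutable accumulator (environment-backed) for the three evaluation
#' surfaces: the hit-rate surface over (time step, input combination), the
#' unique-memory-ratio series, and the per-memory recall-occurrence
#' matrix. Memories are indexed by their position in the presentation
#' sequence, so the occurrence matrix's diagonal marks each memory's
#' introduction step, as in the field's heatmaps.
#'
#' @param dataset A [san_dataset].
#' @param combos A [san_combos].
#' @param sequence Integer permutation of `1:I_tot`: the presentation
#'   order (sequence position -> dataset row).
#' @param n_steps Number of simulated time steps (default `I_tot`).
#' @return An object of class `san_metrics`.
#' @export
metrics_log <- function(dataset, combos, sequence, n_steps = dataset$I_tot) {
  stopifnot(inherits(dataset, "san_dataset"), inherits(combos, "san_combos"))
  e <- new.env(parent = emptyenv())
  e$hits <- matrix(0L, n_steps, combos$n_combos)
  e$trials <- matrix(0L, n_steps, combos$n_combos)
  e$occurrences <- matrix(0L, dataset$I_tot, n_steps)
  e$unique_sets <- vector("list", n_steps)   # per step: seq positions recalled
  e$umr <- rep(NA_real_, n_steps)
  e$prediction_log <- list()
  e$erasure_log <- list()
  e$combos <- combos
  e$n_steps <- n_steps
  # exact-match lookup: memory key -> sequence position
  keys <- memory_keys(dataset$memories)
  pos <- integer(dataset$I_tot)
  pos[sequence] <- seq_along(sequence)
  e$keys <- keys                       # dataset-row order, for match()
  e$row_to_seq <- pos
  e$key_to_seq <- stats::setNames(pos, keys)
  class(e) <- "san_metrics"
  e
}

#' Record one recall trial in the log
#'
#' Increments the combination's trial count at step `t` (and hit count on
#' a hit). Independently, if the final readout equals *any* dataset memory
#' — the queried one or not, shown yet or not — that memory's occurrence
#' count at `t` is incremented and it joins step `t`'s unique-recall set;
#' this is the hit-rate / unique-memory-ratio distinction. Readouts with a
#' sentinel never match.
#'
#' @param log A [metrics_log()].
#' @param t Time step.
#' @param combo_id Row index into the combos.
#' @param ro A `san_readout` (final, no ties).
#' @param hit Logical, from [recall()].
#' @return The log, invisibly (modified in place).
#' @export
record_trial <- function(log, t, combo_id, ro, hit) {
  stopifnot(inherits(log, "san_metrics"))
  log$trials[t, combo_id] <- log$trials[t, combo_id] + 1L
  if (hit) log$hits[t, combo_id] <- log$hits[t, combo_id] + 1L
  feats <- if (inherits(ro, "san_readout")) ro$features else ro
  if (!anyNA(feats)) {
    pos <- unname(log$key_to_seq[paste(feats, collapse = "\r")])
    if (!is.na(pos)) {
      log$occurrences[pos, t] <- log$occurrences[pos, t] + 1L
      log$unique_sets[[t]] <- c(log$unique_sets[[t]], pos)
    }
  }
  invisible(log)
}

# internal fast path used by batched evaluation: record many trials of one
# (step, combo) at once
.record_trials_bulk <- function(log, t, combo_id, n_trials, n_hits, matched_pos) {
  log$trials[t, combo_id] <- log$trials[t, combo_id] + n_trials
  log$hits[t, combo_id] <- log$hits[t, combo_id] + n_hits
  if (length(matched_pos)) {
    cnt <- tabulate(matched_pos, nrow(log$occurrences))
    nz <- which(cnt > 0L)
    log$occurrences[nz, t] <- log$occurrences[nz, t] + cnt[nz]
    log$unique_sets[[t]] <- c(log$unique_sets[[t]], nz)
  }
  invisible(log)
}

#' Unique memory ratio at one time step
#'
#' The number of distinct dataset memories recalled at least once during a
#' step's full evaluation, divided by the number of memories shown so far
#' (`t`). May exceed 1 when unshown memories are recalled by chance — a
#' light form of prediction.
#'
#' @param step_unique_set Vector of (sequence positions of) memories
#'   recalled during the step; duplicates allowed.
#' @param t Memories shown so far (>= 1).
#' @return The ratio, a nonnegative real.
#' @export
unique_memory_ratio <- function(step_unique_set, t) {
  stopifnot(t >= 1)
  length(unique(step_unique_set)) / t
}

# finalize step t: compute UMR from the accumulated unique set
.finalize_step <- function(log, t) {
  log$umr[t] <- unique_memory_ratio(log$unique_sets[[t]], t)
  log$unique_sets[[t]] <- unique(log$unique_sets[[t]])
  invisible(log)
}

#' Export metrics as tidy data frames
#'
#' @param log A `san_metrics` log (or a `san_sim_result`).
#' @return List of data frames: `hit_rate` (long form: `t`, `combo_id`,
#'   `u_avg`, `hits`, `trials`, `hit_rate`), `umr` (`t`, `unique`,
#'   `shown`, `umr`), `occurrences` (nonzero cells: `seq_pos`, `t`,
#'   `count`), plus `predictions` and `erasures` logs.
#' @export
metrics_tables <- function(log) {
  if (inherits(log, "san_sim_result")) log <- log$metrics
  stopifnot(inherits(log, "san_metrics"))
  steps <- which(!is.na(log$umr))
  C <- log$combos$n_combos
  hit_rate <- data.frame(
    t = rep(steps, each = C),
    combo_id = rep(seq_len(C), length(steps)),
    u_avg = rep(log$combos$u_avg, length(steps)),
    hits = as.vector(t(log$hits[steps, , drop = FALSE])),
    trials = as.vector(t(log$trials[steps, , drop = FALSE]))
  )
  hit_rate$hit_rate <- ifelse(hit_rate$trials > 0, hit_rate$hits / hit_rate$trials, NA)
  umr <- data.frame(
    t = steps,
    unique = vapply(log$unique_sets[steps], function(s) length(unique(s)), integer(1)),
    shown = steps,
    umr = log$umr[steps]
  )
  nz <- which(log$occurrences > 0L, arr.ind = TRUE)
  occurrences <- data.frame(seq_pos = nz[, 1L], t = nz[, 2L],
                            count = log$occurrences[nz])
  occurrences <- occurrences[order(occurrences$t, occurrences$seq_pos), ]
  rownames(occurrences) <- NULL
  list(hit_rate = hit_rate, umr = umr, occurrences = occurrences,
       predictions = log$prediction_log, erasures = log$erasure_log)
}

#' Write run metrics to disk
#'
#' Emits `hit_rate.csv`, `umr.csv`, `occurrences.csv` (long format) and
#' `predictions.json` / `erasures.json` into `dir`.
#'
#' @param log A `san_metrics` log or `san_sim_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(log, dir) {
  tabs <- metrics_tables(log)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tabs$hit_rate, file.path(dir, "hit_rate.csv"), row.names = FALSE)
  utils::write.csv(tabs$umr, file.path(dir, "umr.csv"), row.names = FALSE)
  utils::write.csv(tabs$occurrences, file.path(dir, "occurrences.csv"), row.names = FALSE)
  jsonlite::write_json(tabs$predictions, file.path(dir, "predictions.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(tabs$erasures, file.path(dir, "erasures.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
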