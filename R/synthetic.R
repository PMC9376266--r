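#' Specification for a synthetic categorical dataset
#'
#' Describes a dataset to be generated with exact control over the
#' statistical structure the network's behavior depends on: the per-set
#' distinct-feature counts (hence the U-factor profile) and optional
#' *planted* common features occurring with a prescribed similarity
#' frequency `f_sim` (the fraction of memories carrying the feature, the
#' quantity that sizes the erase threshold via
#' [erase_threshold_from_similarity()]).
#'
#' @param n_sets Number of sets (>= 2).
#' @param i_tot Number of memories to generate.
#' @param target_m Integer vector of length `n_sets`; the exact number of
#'   distinct features each set must realize (`1 <= target_m[i] <= i_tot`).
#' @param planted Optional data frame with columns `set` (set index) and
#'   `f_sim` (similarity frequency in `(0, 1]`); each plants one common
#'   feature in that set carried by exactly `round(f_sim * i_tot)` memories.
#'   At most one planted feature per set.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `san_synth_spec`.
#' @export
synth_spec <- function(n_sets, i_tot, target_m, planted = NULL, seed = 1L) {
  n_sets <- as.integer(n_sets); i_tot <- as.integer(i_tot)
  target_m <- as.integer(target_m)
  if (n_sets < 2L) stop("n_sets must be >= 2")
  if (i_tot < 1L) stop("i_tot must be >= 1")
  if (length(target_m) != n_sets)
    stop("target_m must have one entry per set")
  if (any(target_m < 1L)) stop("target_m entries must be >= 1")
  if (any(target_m > i_tot))
    stop("target_m entries cannot exceed i_tot")
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("set", "f_sim") %in% names(planted)))
    if (any(planted$set < 1 | planted$set > n_sets))
      stop("planted set index out of range")
    if (anyDuplicated(planted$set))
      stop("at most one planted feature per set")
    if (any(planted$f_sim <= 0 | planted$f_sim > 1))
      stop("f_sim must be in (0, 1]")
    if (any(round(planted$f_sim * i_tot) < 1))
      stop("round(f_sim * i_tot) must be at least 1 occurrence")
  }
  structure(
    list(n_sets = n_sets, i_tot = i_tot, target_m = target_m,
         planted = planted, seed = as.integer(seed)),
    class = "san_synth_spec"
  )
}

#' @export
print.san_synth_spec <- function(x, ...) {
  cat(sprintf("san_synth_spec: %d sets, %d memories, N=%d, seed=%d\n",
              x$n_sets, x$i_tot, sum(x$target_m), x$seed))
  invisible(x)
}

#' Synthetic spec mirroring the European Heads of State profile
#'
#' Returns a spec with 8 sets and the deposited dataset's per-set
#' unique-feature counts (328, 190, 29, 22, 24, 117, 9, 59 for 700
#' memories, 778 neurons total). For scaled-down experiments `i_tot` may be
#' reduced; the per-set counts are then scaled proportionally (rounded,
#' floor 1) so the U-factor profile is preserved.
#'
#' @param seed Integer seed.
#' @param i_tot Number of memories (default 700, the full-size profile).
#' @return A [synth_spec].
#' @export
ehos_like_spec <- function(seed = 1L, i_tot = 700L) {
  m_full <- c(328L, 190L, 29L, 22L, 24L, 117L, 9L, 59L)
  names(m_full) <- c("first_name", "last_name_title", "century", "state",
                     "position", "dynasty_party", "cause_of_death", "reign")
  i_tot <- as.integer(i_tot)
  m <- if (i_tot == 700L) m_full else pmax(1L, as.integer(round(m_full * i_tot / 700)))
  sp <- synth_spec(8L, i_tot, unname(m), planted = NULL, seed = seed)
  sp$set_names <- names(m_full)
  sp
}

#' Generate a synthetic dataset from a spec
#'
#' Per set, the column is built so the realized distinct-feature count
#' equals `target_m[i]` exactly: every target feature appears at least
#' once and the remaining rows are drawn uniformly from the set's
#' vocabulary; the column is then shuffled independently of other sets.
#' A planted feature is built into its column with exactly
#' `round(f_sim * i_tot)` occurrences. After generation the dataset is
#' canonicalized to first-appearance feature indexing, so writing it with
#' [write_dataset()] and reloading reproduces it exactly.
#'
#' Generation is a pure function of the spec (including its seed): the
#' caller's RNG state is saved and restored.
#'
#' @param spec A [synth_spec].
#' @return A [san_dataset]. If the spec plants features, the returned
#'   object carries an attribute `planted`: a data frame with columns
#'   `set`, `label`, `count`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "san_synth_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n <- spec$n_sets
  I <- spec$i_tot
  set_names <- if (!is.null(spec$set_names)) spec$set_names else sprintf("set%d", seq_len(n))
  planted_info <- NULL
  feats <- vector("list", n)
  mem <- matrix(0L, I, n)

  for (i in seq_len(n)) {
    M <- spec$target_m[i]
    labels <- sprintf("%s_f%03d", set_names[i], seq_len(M))
    pl <- if (!is.null(spec$planted)) spec$planted[spec$planted$set == i, ] else NULL
    if (!is.null(pl) && nrow(pl)) {
      # the planted common feature is feature 1 of the set; build its exact
      # occurrence count into the column so both f_sim and M_i are exact
      k <- as.integer(round(pl$f_sim * I))
      if (I - k < M - 1L)
        stop(sprintf("set %d: planted feature leaves too few rows for %d other features",
                     i, M - 1L))
      rest <- if (M > 1L) {
        extra <- I - k - (M - 1L)
        c(seq.int(2L, M), if (extra > 0L) sample.int(M - 1L, extra, replace = TRUE) + 1L)
      } else integer(0)
      col <- c(rep.int(1L, k), rest)
      planted_info <- rbind(planted_info,
                            data.frame(set = i, label = labels[1L], count = k))
    } else {
      extra <- I - M
      col <- c(seq_len(M), if (extra > 0L) sample.int(M, extra, replace = TRUE))
    }
    col <- col[sample.int(I)]         # shuffle this set's column independently
    # canonicalize: reindex features by first appearance, matching the loader
    ord <- unique(col)
    mem[, i] <- match(col, ord)
    feats[[i]] <- labels[ord]
  }

  names(feats) <- set_names
  d <- san_dataset(san_schema(feats), mem)
  if (!is.null(planted_info)) attr(d, "planted") <- planted_info
  d
}
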