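#' Categorical dataset schema
#'
#' A schema describes the categorical structure of an associative-memory
#' dataset: an ordered collection of *sets* (categories of information such
#' as "first name" or "state"), each holding an ordered vocabulary of
#' distinct *features*. Every feature is represented by one neuron in the
#' network, so the total neuron count is `N = sum(M_i)` where `M_i` is the
#' feature count of set `i`.
#'
#' @param sets Named list of character vectors. Names are set labels;
#'   each vector is the ordered feature vocabulary of that set (position =
#'   feature index).
#' @return An object of class `san_schema` with elements `set_names`,
#'   `features` (list of character vectors), `n` (number of sets), `M`
#'   (per-set feature counts), `N` (total neuron count) and `offset`
#'   (0-based global-neuron offset of each set, so neuron of feature `j`
#'   in set `i` has global index `offset[i] + j`).
#' @examples
#' sc <- san_schema(list(color = c("red", "blue"), shape = c("square")))
#' sc$N  # 3 neurons
#' @export
san_schema <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("a schema needs at least 2 sets")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every set must be named")
  if (anyDuplicated(nm))
    stop("set names must be unique")
  features <- lapply(sets, function(f) {
    f <- as.character(f)
    if (length(f) < 1L) stop("every set needs at least 1 feature")
    if (anyDuplicated(f)) stop("feature labels must be unique within a set")
    f
  })
  M <- vapply(features, length, integer(1))
  structure(
    list(
      set_names = nm,
      features  = features,
      n         = length(features),
      M         = unname(M),
      N         = sum(M),
      offset    = c(0L, cumsum(unname(M)))[seq_along(M)]
    ),
    class = "san_schema"
  )
}

#' @export
print.san_schema <- function(x, ...) {
  cat(sprintf("san_schema: %d sets, %d neurons\n", x$n, x$N))
  for (i in seq_len(x$n))
    cat(sprintf("  %-20s M=%d\n", x$set_names[i], x$M[i]))
  invisible(x)
}

#' Categorical memory dataset
#'
#' A dataset is a schema plus an ordered list of memories, one feature per
#' set each. Memories are stored as an integer matrix with one row per
#' memory and one column per set; entry `(r, i)` is the feature index of
#' memory `r` in set `i`.
#'
#' @param schema A [san_schema].
#' @param memories Integer matrix (`I_tot` rows, `n` columns) of feature
#'   indices, all within each set's vocabulary.
#' @return An object of class `san_dataset` with elements `schema`,
#'   `memories`, and `I_tot` (number of memories).
#' @export
san_dataset <- function(schema, memories) {
  stopifnot(inherits(schema, "san_schema"))
  memories <- as.matrix(memories)
  storage.mode(memories) <- "integer"
  if (ncol(memories) != schema$n)
    stop("memories must have one column per set")
  if (nrow(memories) < 1L)
    stop("a dataset needs at least 1 memory")
  for (i in seq_len(schema$n)) {
    v <- memories[, i]
    if (anyNA(v) || any(v < 1L) || any(v > schema$M[i]))
      stop(sprintf("invalid feature index in set '%s'", schema$set_names[i]))
  }
  colnames(memories) <- schema$set_names
  structure(
    list(schema = schema, memories = memories, I_tot = nrow(memories)),
    class = "san_dataset"
  )
}

#' @export
print.san_dataset <- function(x, ...) {
  cat(sprintf("san_dataset: %d memories, %d sets, %d neurons\n",
              x$I_tot, x$schema$n, x$schema$N))
  invisible(x)
}

#' Extract one memory as a feature-index vector
#'
#' @param d A [san_dataset].
#' @param i Memory (row) index.
#' @return Integer vector of length `n` (one feature index per set).
#' @export
get_memory <- function(d, i) {
  stopifnot(inherits(d, "san_dataset"), i >= 1L, i <= d$I_tot)
  d$memories[i, ]
}

#' Load a dataset from CSV
#'
#' Reads a categorical dataset with one header row, one column per set and
#' one row per memory. Cell values are trimmed of surrounding whitespace
#' and compared case-sensitively; feature indices are assigned in order of
#' first appearance down each column, making the loader deterministic
#' without any sorting assumptions.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param column_order Optional character vector of column (set) names
#'   giving the set order to use; defaults to file order. Useful when a
#'   deposited file's column order differs from the expected one.
#' @return A [san_dataset].
#' @export
load_dataset <- function(path, column_order = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(raw) < 2L)
    stop("dataset CSV needs at least 2 columns")
  if (anyDuplicated(names(raw)))
    stop("duplicate header names in dataset CSV: ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  if (!is.null(column_order)) {
    missing_cols <- setdiff(column_order, names(raw))
    if (length(missing_cols))
      stop("column_order names absent from file: ",
           paste(missing_cols, collapse = ", "))
    raw <- raw[, column_order, drop = FALSE]
  }
  if (nrow(raw) < 1L)
    stop("dataset CSV has no data rows")
  n <- ncol(raw)
  feats <- vector("list", n)
  mem <- matrix(0L, nrow(raw), n)
  for (i in seq_len(n)) {
    v <- trimws(raw[[i]])
    bad <- which(is.na(v) | !nzchar(v))
    if (length(bad))
      stop(sprintf("empty cell at row %d, column '%s'", bad[1], names(raw)[i]))
    lev <- unique(v)                      # first-appearance order
    feats[[i]] <- lev
    mem[, i] <- match(v, lev)
  }
  names(feats) <- names(raw)
  san_dataset(san_schema(feats), mem)
}

#' Write a dataset to CSV
#'
#' Inverse of [load_dataset()]: emits feature labels (not indices) with one
#' header row. Because every `san_dataset` constructed by this package uses
#' first-appearance feature indexing, reloading the written file recovers
#' the identical schema and memory matrix.
#'
#' @param d A [san_dataset].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(d, path) {
  stopifnot(inherits(d, "san_dataset"))
  out <- as.data.frame(lapply(seq_len(d$schema$n), function(i)
    d$schema$features[[i]][d$memories[, i]]))
  names(out) <- d$schema$set_names
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-set uniqueness factors (U-factors)
#'
#' The U-factor of a set is `U_i = M_i / I_tot`: its distinct-feature count
#' divided by the number of memories. It measures how unique the
#' information in that set is — 1 means every memory has its own feature,
#' values near 0 mean heavy sharing.
#'
#' @param d A [san_dataset].
#' @return Named numeric vector of `U_i`, each in `(0, 1]`.
#' @export
dataset_u_factors <- function(d) {
  stopifnot(inherits(d, "san_dataset"), d$I_tot > 0L)
  stats::setNames(d$schema$M / d$I_tot, d$schema$set_names)
}

#' Mean pairwise Hamming distance between memories
#'
#' For every unordered pair of memories, counts the sets where their
#' features differ, and averages over all pairs. Ranges from 0 (all
#' memories identical) to `n` (no two memories share a feature anywhere).
#' Computed exactly by counting equal pairs per set from feature
#' frequencies, so it scales to large datasets.
#'
#' @param d A [san_dataset] with at least 2 memories.
#' @return Mean Hamming distance, in `[0, n]`.
#' @export
mean_hamming <- function(d) {
  stopifnot(inherits(d, "san_dataset"))
  if (d$I_tot < 2L) stop("mean_hamming needs at least 2 memories")
  pairs <- choose(d$I_tot, 2)
  eq <- vapply(seq_len(d$schema$n), function(i) {
    sum(choose(tabulate(d$memories[, i], d$schema$M[i]), 2))
  }, numeric(1))
  d$schema$n - sum(eq) / pairs
}

# Global neuron indices (1-based) of a memory's features.
memory_neurons <- function(schema, memory) {
  schema$offset + as.integer(memory)
}

# One string key per memory row, for exact-match lookup during evaluation.
memory_keys <- function(memories) {
  apply(memories, 1L, paste, collapse = "\r")
}
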