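#' Annotate trimmed reads against a reference pool
#'
#' A read is assigned to a pool sequence only by full-length exact equality
#' after `T -> U` mapping (zero mismatch tolerance); since pool sequences are
#' unique a read can match at most one entry. Everything else — including
#' reads one base longer or shorter than a reference — counts as
#' unannotated. Reads flagged `untrimmed` by [trim_reads()] are excluded
#' before counting.
#'
#' @param trimmed Output of [trim_reads()], or a character vector of insert
#'   sequences.
#' @param pool A [reference_pool()] tibble.
#' @return A tibble of class `lb_counts` with columns `id`, `count` (one row
#'   per pool sequence, zeros kept), and attributes `unannotated` and
#'   `total_reads` satisfying `sum(count) + unannotated == total_reads`.
#' @examples
#' pool <- reference_pool(c(m1 = "ACGU"))
#' annotate_reads(c("ACGU", "GGGG", "ACGU"), pool)
#' @export
annotate_reads <- function(trimmed, pool) {
  if (nrow(pool) == 0) abort("reference pool is empty")
  if (is.character(trimmed)) {
    inserts <- as_rna(trimmed)
  } else {
    stopifnot(is.data.frame(trimmed), "insert" %in% names(trimmed))
    keep <- if ("untrimmed" %in% names(trimmed)) !trimmed$untrimmed else TRUE
    inserts <- as_rna(trimmed$insert[keep])
  }
  inserts <- inserts[!is.na(inserts)]
  hit <- match(inserts, pool$sequence)
  counts <- tabulate(hit, nbins = nrow(pool))
  out <- tibble(id = pool$id, count = as.integer(counts))
  attr(out, "unannotated") <- sum(is.na(hit))
  attr(out, "total_reads") <- length(inserts)
  class(out) <- c("lb_counts", class(out))
  out
}

#' @export
glance.lb_counts <- function(x, ...) {
  tibble(
    total_reads = attr(x, "total_reads"),
    annotated = sum(x$count),
    unannotated = attr(x, "unannotated"),
    n_sequences = nrow(x)
  )
}

#' Normalize annotated counts against pool expectations
#'
#' The normalization factor is the number of annotated reads per unique pool
#' sequence, `sum(count) / N`; dividing each count by it yields normalized
#' reads with mean exactly 1 over the pool. The expected value for sequence
#' *i* is `N * c_i / sum(c)` (1 everywhere for an equimolar pool) and the
#' reported `ratio` is `normalized_reads / expected`: 1 means the sequence is
#' represented exactly as its known abundance predicts.
#'
#' @param counts An `lb_counts` table from [annotate_reads()], or a named
#'   numeric vector of per-id counts.
#' @param pool The [reference_pool()] the counts were annotated against.
#' @return A tibble of class `lb_normtab` with columns `id`, `count`,
#'   `normalized_reads`, `expected`, `ratio` and attribute
#'   `normalization_factor`.
#' @examples
#' pool <- reference_pool(c(m1 = "ACGU", m2 = "GGCC"))
#' normalize_counts(c(m1 = 300, m2 = 100), pool)
#' @export
normalize_counts <- function(counts, pool) {
  if (!is.data.frame(counts)) {
    counts <- tibble(id = names(counts), count = as.numeric(counts))
  }
  stopifnot(all(c("id", "count") %in% names(counts)))
  missing <- setdiff(pool$id, counts$id)
  if (length(missing) > 0) {
    counts <- bind_rows(counts, tibble(id = missing, count = 0))
  }
  extra <- setdiff(counts$id, pool$id)
  if (length(extra) > 0) {
    abort(sprintf("counts contain ids not in the pool: %s",
                  paste(head(extra, 5), collapse = ", ")))
  }
  counts <- counts[match(pool$id, counts$id), ]
  total <- sum(counts$count)
  if (total <= 0) abort("no annotated reads: normalization factor undefined")
  factor <- total / nrow(pool)
  expected <- expected_values(pool)
  out <- tibble(
    id = pool$id,
    count = counts$count,
    normalized_reads = counts$count / factor,
    expected = expected,
    ratio = (counts$count / factor) / expected
  )
  attr(out, "normalization_factor") <- factor
  class(out) <- c("lb_normtab", class(out))
  out
}

#' @export
glance.lb_normtab <- function(x, ...) {
  tibble(
    n_sequences = nrow(x),
    annotated_reads = if ("count" %in% names(x)) sum(x$count) else NA_real_,
    normalization_factor = attr(x, "normalization_factor"),
    mean_normalized = mean(x$normalized_reads)
  )
}

#' Average replicate normalized tables
#'
#' Replicate libraries of the same pool are combined by taking the
#' arithmetic mean of the per-sequence normalized read values; the ratio to
#' expectation is recomputed from the averaged values. Tables must cover the
#' same ids with identical expected values.
#'
#' @param ... Two or more `lb_normtab` tables (or a single list of them).
#' @return An `lb_normtab` tibble with columns `id`, `normalized_reads`,
#'   `expected`, `ratio`; attribute `n_replicates` records how many tables
#'   were averaged.
#' @export
average_replicates <- function(...) {
  tables <- list(...)
  if (length(tables) == 1 && is.list(tables[[1]]) && !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  if (length(tables) < 2) abort("need at least two replicate tables")
  ref <- tables[[1]]
  for (i in seq_along(tables)[-1]) {
    tab <- tables[[i]]
    if (!setequal(ref$id, tab$id)) {
      abort(sprintf("replicate %d has a different id set", i))
    }
    tab <- tab[match(ref$id, tab$id), ]
    if (max(abs(tab$expected - ref$expected)) > 1e-9) {
      abort(sprintf("replicate %d has different expected values", i))
    }
    tables[[i]] <- tab
  }
  norm <- rowMeans(do.call(cbind, map(tables, "normalized_reads")))
  out <- tibble(
    id = ref$id,
    normalized_reads = norm,
    expected = ref$expected,
    ratio = norm / ref$expected
  )
  attr(out, "normalization_factor") <- NA_real_
  attr(out, "n_replicates") <- length(tables)
  class(out) <- c("lb_normtab", class(out))
  out
}

#' Write a normalized table to TSV
#'
#' @param x An `lb_normtab` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_normalized_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}
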