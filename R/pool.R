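#' Build a reference pool from sequences and concentrations
#'
#' A reference pool is the defined mixture of small RNA sequences that a
#' library was built from (for example an equimolar commercial reference of
#' 962 unique miRNAs, or a custom 50-sequence mix with a 500-fold
#' concentration spread). It is represented as a tibble with columns `id`,
#' `sequence` (RNA alphabet) and `concentration` (relative, dimensionless).
#'
#' Ids must be unique and so must sequences: with zero-mismatch annotation a
#' duplicated sequence would be unassignable, so duplicates are rejected with
#' an error naming the colliding ids.
#'
#' @param sequences Named character vector of sequences (names are ids), or a
#'   data frame with columns `id` and `sequence`.
#' @param concentrations Optional numeric vector of relative concentrations,
#'   recycled or matched by id; defaults to 1 (equimolar).
#' @return A tibble with columns `id`, `sequence`, `concentration`.
#' @seealso [read_reference_pool()] to load a pool from FASTA/TSV files.
#' @examples
#' reference_pool(c(m1 = "ACGUACGUACGU", m2 = "GGGCUUAGGCUA"))
#' @export
reference_pool <- function(sequences, concentrations = NULL) {
  if (is.data.frame(sequences)) {
    stopifnot(all(c("id", "sequence") %in% names(sequences)))
    ids <- as.character(sequences$id)
    seqs <- as.character(sequences$sequence)
    if (is.null(concentrations) && "concentration" %in% names(sequences)) {
      concentrations <- sequences$concentration
    }
  } else {
    ids <- names(sequences)
    seqs <- unname(sequences)
  }
  if (length(seqs) == 0) abort("reference pool is empty")
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    abort("every pool sequence needs an id")
  }
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate pool id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- check_alphabet(seqs, allow_n = FALSE, what = "pool sequence")
  dup <- duplicated(seqs) | duplicated(seqs, fromLast = TRUE)
  if (any(dup)) {
    groups <- split(ids[dup], seqs[dup])
    msg <- paste(map_chr(groups, paste, collapse = " & "), collapse = "; ")
    abort(sprintf("duplicate pool sequence(s) shared by ids: %s", msg))
  }
  conc <- concentrations %||% 1
  if (!is.null(names(conc))) {
    extra <- setdiff(names(conc), ids)
    if (length(extra) > 0) {
      abort(sprintf("concentration ids not in pool: %s",
                    paste(extra, collapse = ", ")))
    }
    conc <- unname(conc[ids])
    conc[is.na(conc)] <- 1
  } else {
    conc <- rep_len(conc, length(ids))
  }
  if (any(!is.finite(conc) | conc <= 0)) {
    abort("concentrations must be finite and > 0")
  }
  tibble(id = ids, sequence = seqs, concentration = as.numeric(conc))
}

#' Load a reference pool from FASTA (plus optional concentration TSV)
#'
#' Sequences are converted `T -> U`. The optional TSV must have columns `id`
#' and `concentration`; ids present in the TSV must be a subset of the FASTA
#' ids, and sequences without an entry default to concentration 1.
#'
#' @param path Path to a FASTA file of pool sequences.
#' @param concentrations Optional path to a TSV with columns `id`,
#'   `concentration`.
#' @return A reference pool tibble (see [reference_pool()]).
#' @examples
#' fa <- system.file("extdata", "synthetic_pool.fasta", package = "ligbias")
#' pool <- read_reference_pool(fa)
#' head(pool)
#' @export
read_reference_pool <- function(path, concentrations = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("no sequences in '%s'", path))
  ids <- stringr::str_split_fixed(names(set), "\\s", 2)[, 1]
  conc <- NULL
  if (!is.null(concentrations)) {
    tab <- readr::read_tsv(concentrations, col_types = readr::cols(
      id = readr::col_character(), concentration = readr::col_double()
    ))
    conc <- setNames(tab$concentration, tab$id)
  }
  reference_pool(setNames(as.character(set), ids), conc)
}

# Expected normalized-read value per sequence: N * c_i / sum(c), so that the
# mean expected value is exactly 1 and an equimolar pool expects 1 everywhere.
expected_values <- function(pool) {
  length(pool$concentration) * pool$concentration / sum(pool$concentration)
}
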