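#' Positional nucleotide frequencies of a randomized region
#'
#' For a set of equal-length sequences (e.g. the randomized region extracted
#' from every read of an input or output library), computes the percentage of
#' each nucleotide at each position. Rows (positions) sum to 100%.
#'
#' @param sequences Character vector of equal-length sequences over
#'   `{A,C,G,U}` (T accepted and mapped to U).
#' @return A tibble of class `lb_pfm` with columns `position`, `nucleotide`,
#'   `freq` (percent) — 4 rows per position — and attribute `n_sequences`.
#' @examples
#' positional_frequency(c("AC", "AG"))
#' @export
positional_frequency <- function(sequences) {
  if (length(sequences) == 0) abort("no sequences")
  sequences <- check_alphabet(sequences, what = "sequence")
  lens <- unique(nchar(sequences))
  if (length(lens) != 1) {
    abort(sprintf("sequences have ragged lengths: %s",
                  paste(sort(lens), collapse = ", ")))
  }
  L <- lens
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                ncol = L, byrow = TRUE)
  nucs <- c("A", "C", "G", "U")
  out <- tidyr::expand_grid(position = seq_len(L), nucleotide = nucs)
  out$freq <- as.vector(vapply(seq_len(L), function(p) {
    100 * tabulate(match(mat[, p], nucs), nbins = 4) / length(sequences)
  }, numeric(4)))
  attr(out, "n_sequences") <- length(sequences)
  class(out) <- c("lb_pfm", class(out))
  out
}

#' Input-normalized positional nucleotide enrichment
#'
#' Normalizes each output-library frequency to the corresponding input
#' frequency: `RNnp = 25 * f_out / f_in`, the normalized nucleotide frequency
#' percentage. The reported enrichment is `RNnp - 25`, so 0 means no
#' preference for that nucleotide at that position, positive values a
#' preference and negative values an avoidance. Cells with `f_in = 0` are
#' undefined and returned as `NA` (never dropped).
#'
#' @param output,input `lb_pfm` tables from [positional_frequency()] with
#'   matching dimensions.
#' @return A tibble of class `lb_enrich` with columns `position`,
#'   `nucleotide`, `rnnp`, `enrichment` (`rnnp - 25`, percentage points).
#' @examples
#' pfm <- positional_frequency(c("AC", "AG", "CU", "GU"))
#' positional_enrichment(pfm, pfm) # identical libraries: all zeros
#' @export
positional_enrichment <- function(output, input) {
  stopifnot(is.data.frame(output), is.data.frame(input))
  if (nrow(output) != nrow(input) ||
      !identical(output$position, input$position) ||
      !identical(output$nucleotide, input$nucleotide)) {
    abort("output and input matrices have mismatched dimensions")
  }
  rnnp <- ifelse(input$freq > 0, 25 * output$freq / input$freq, NA_real_)
  undefined <- is.na(rnnp) & output$freq > 0
  if (any(undefined)) {
    warn(sprintf(
      "%d cell(s) have zero input frequency but nonzero output; reported as NA",
      sum(undefined)
    ))
  }
  # f_in = f_out = 0: no data either way, no preference signal -> NA as well
  out <- tibble(
    position = output$position, nucleotide = output$nucleotide,
    rnnp = rnnp, enrichment = rnnp - 25
  )
  class(out) <- c("lb_enrich", class(out))
  out
}

#' Extract the randomized-region substring from reads
#'
#' Convenience for randomized-pool experiments where a fixed-length
#' randomized region sits at a known position of each (already trimmed)
#' read.
#'
#' @param reads Character vector of reads or a tibble with an `insert`
#'   column.
#' @param start 1-based start of the randomized region.
#' @param length Region length (21 in the classic design).
#' @return Character vector of region sequences (reads too short are
#'   dropped).
#' @export
randomized_region <- function(reads, start = 1, length = 21) {
  x <- if (is.data.frame(reads)) reads$insert else reads
  x <- as_rna(x[!is.na(x)])
  x <- x[nchar(x) >= start + length - 1]
  stringr::str_sub(x, start, start + length - 1)
}
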