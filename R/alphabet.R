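#' Nucleotide alphabet helpers
#'
#' Sequences are handled internally in the RNA alphabet `{A, C, G, U}` (with
#' `N` marking randomized positions in adaptors). DNA input is accepted
#' anywhere and converted with `T -> U`; [as_dna()] performs the reverse
#' mapping, e.g. when writing simulated sequencer reads.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @examples
#' as_rna("AGATCGG")
#' reverse_complement("GAUC")
#' @name alphabet
NULL

#' @rdname alphabet
#' @export
as_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' @rdname alphabet
#' @export
as_dna <- function(x) {
  chartr("Uu", "Tt", toupper(x))
}

#' @rdname alphabet
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGUN", "UGCAN", as_rna(x))
  map_chr(strsplit(comp, "", fixed = TRUE), ~ paste(rev(.x), collapse = ""))
}

# Validate sequences over {A,C,G,U} (optionally + N after T->U mapping);
# returns the RNA-alphabet sequences or aborts naming the offender.
check_alphabet <- function(x, allow_n = FALSE, what = "sequence") {
  x <- as_rna(x)
  pat <- if (allow_n) "^[ACGUN]+$" else "^[ACGU]+$"
  bad <- which(!stringr::str_detect(x, pat))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s %d contains characters outside the %s alphabet: '%s'",
      what, bad[1], if (allow_n) "ACGUTN" else "ACGUT", x[bad[1]]
    ))
  }
  x
}
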