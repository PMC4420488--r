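#' Describe a sequencing adaptor
#'
#' An adaptor is the known oligonucleotide ligated to one end of a small RNA.
#' A maximal run of `N` characters marks a randomized region (a pool of
#' adaptors differing only at those positions); at most one N-run is allowed.
#' The 3' adaptor of a standard library is DNA, the 5' adaptor RNA; DNA
#' sequences are kept as given but all matching and folding happens after
#' `T -> U` conversion.
#'
#' @param sequence Adaptor sequence over `{A,C,G,U,T,N}`.
#' @param side `"three_prime"` or `"five_prime"`: which end of the insert the
#'   adaptor is ligated to.
#' @param name Optional adaptor name.
#' @param alphabet `"DNA"` or `"RNA"`; guessed from the sequence if missing
#'   (`T` implies DNA, `U` implies RNA, otherwise the conventional alphabet
#'   for the side).
#' @return An object of class `adaptor_spec`: a list with elements `name`,
#'   `side`, `alphabet`, `sequence` (as given), `rna` (T->U), `n_start`,
#'   `n_length` (0 if no randomized region).
#' @examples
#' adaptor_spec("AGATCGGAAGAGCACACGTCT", "three_prime", name = "A1-3p")
#' adaptor_spec("NNNNNNAGATCGGAAGAGC", "three_prime", name = "Rand-3p")
#' @export
adaptor_spec <- function(sequence, side = c("three_prime", "five_prime"),
                         name = NULL, alphabet = NULL) {
  side <- match.arg(side)
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  sequence <- toupper(sequence)
  if (!stringr::str_detect(sequence, "^[ACGUTN]+$")) {
    abort(sprintf("adaptor contains characters outside ACGUTN: '%s'", sequence))
  }
  if (stringr::str_detect(sequence, "T") && stringr::str_detect(sequence, "U")) {
    abort("adaptor mixes T and U")
  }
  if (is.null(alphabet)) {
    alphabet <- if (stringr::str_detect(sequence, "T")) "DNA"
      else if (stringr::str_detect(sequence, "U")) "RNA"
      else if (side == "three_prime") "DNA" else "RNA"
  }
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  runs <- stringr::str_locate_all(sequence, "N+")[[1]]
  if (nrow(runs) > 1) abort("adaptor has more than one randomized (N) region")
  n_start <- if (nrow(runs) == 1) runs[1, "start"] else NA_integer_
  n_length <- if (nrow(runs) == 1) runs[1, "end"] - runs[1, "start"] + 1L else 0L
  if (n_length == nchar(sequence)) abort("adaptor is all N: no defined flank")
  structure(
    list(
      name = name %||% paste0(if (side == "three_prime") "3p" else "5p", "-adaptor"),
      side = side, alphabet = alphabet, sequence = sequence,
      rna = as_rna(sequence),
      n_start = as.integer(n_start), n_length = as.integer(n_length)
    ),
    class = "adaptor_spec"
  )
}

#' @export
print.adaptor_spec <- function(x, ...) {
  cat(sprintf("<adaptor_spec> %s (%s, %s)\n  %s\n", x$name,
              sub("_", "-", x$side), x$alphabet, x$sequence))
  if (x$n_length > 0) {
    cat(sprintf("  randomized region: %d nt at position %d\n",
                x$n_length, x$n_start))
  }
  invisible(x)
}

#' Default defined-sequence adaptor pair
#'
#' A 3' DNA adaptor and 5' RNA adaptor matching the standard single-sequence
#' small-RNA kit adaptors; used as stand-ins for a study-specific `A1` pair
#' when no adaptor FASTA is supplied. Real adaptor sequences should be loaded
#' with [read_adaptors()].
#'
#' @return A list with elements `three_prime` and `five_prime`.
#' @examples
#' default_adaptors()
#' @export
default_adaptors <- function() {
  list(
    three_prime = adaptor_spec("AGATCGGAAGAGCACACGTCT", "three_prime",
                               name = "A1-like-3p", alphabet = "DNA"),
    five_prime = adaptor_spec("GUUCAGAGUUCUACAGUCCGACGAUC", "five_prime",
                              name = "A1-like-5p", alphabet = "RNA")
  )
}

#' Read adaptors from FASTA
#'
#' Record ids may carry a `3p`/`5p` (or `three_prime`/`five_prime`) token to
#' set the side; otherwise `side` must be supplied.
#'
#' @param path FASTA file of adaptor sequences (N allowed).
#' @param side Optional side applied to every record.
#' @return A list of [adaptor_spec()] objects, named by record id.
#' @export
read_adaptors <- function(path, side = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(sprintf("no sequences in '%s'", path))
  ids <- stringr::str_split_fixed(names(set), "\\s", 2)[, 1]
  specs <- map2(as.character(set), ids, function(seq, id) {
    s <- side
    if (is.null(s)) {
      s <- if (stringr::str_detect(id, "(^|[._-])(3p|three_prime)([._-]|$)")) {
        "three_prime"
      } else if (stringr::str_detect(id, "(^|[._-])(5p|five_prime)([._-]|$)")) {
        "five_prime"
      } else {
        abort(sprintf("cannot infer side for adaptor '%s'; pass side=", id))
      }
    }
    adaptor_spec(seq, s, name = id)
  })
  setNames(specs, ids)
}

#' Fill an adaptor's randomized region with concrete bases
#'
#' Materializes one member of a randomized adaptor pool. `fill` may be a
#' string of the randomized region's length, or `NULL` to draw uniformly
#' from the adaptor's alphabet using the current RNG state.
#'
#' @param adaptor An [adaptor_spec()].
#' @param fill Optional fill string.
#' @return An `adaptor_spec` with no N-run.
#' @export
instantiate_adaptor <- function(adaptor, fill = NULL) {
  stopifnot(inherits(adaptor, "adaptor_spec"))
  if (adaptor$n_length == 0) return(adaptor)
  letters4 <- if (adaptor$alphabet == "DNA") c("A", "C", "G", "T") else c("A", "C", "G", "U")
  if (is.null(fill)) {
    fill <- paste(sample(letters4, adaptor$n_length, replace = TRUE), collapse = "")
  }
  stopifnot(nchar(fill) == adaptor$n_length)
  seq <- adaptor$sequence
  stringr::str_sub(seq, adaptor$n_start, adaptor$n_start + adaptor$n_length - 1) <- fill
  adaptor_spec(seq, adaptor$side, name = paste0(adaptor$name, "/", fill),
               alphabet = adaptor$alphabet)
}
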