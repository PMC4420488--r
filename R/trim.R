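#' Read sequencing reads from FASTQ or FASTA
#'
#' Qualities are ignored; sequences are returned as given (use
#' [trim_reads()], which matches in the RNA alphabet regardless).
#'
#' @param path FASTQ or FASTA file (format guessed from the extension, or
#'   forced via `format`).
#' @param format `"auto"`, `"fastq"` or `"fasta"`.
#' @return A tibble with columns `read_id`, `read`.
#' @export
read_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (stringr::str_detect(path, "\\.(fq|fastq)(\\.gz)?$")) "fastq" else "fasta"
  }
  set <- Biostrings::readBStringSet(path, format = format)
  tibble(
    read_id = stringr::str_split_fixed(names(set), "\\s", 2)[, 1],
    read = unname(as.character(set))
  )
}

# Decide which defined segment of an adaptor the trimmer should anchor on.
# Returns list(flank, offset, check, gap): `flank` is the RNA-alphabet
# subsequence to search for and `offset` the number of adaptor bases lying
# between the flank and the insert (N-run bases and any defined segment
# shorter than min_flank), removed by length once the flank is located.
# When the flank is insert-proximal and followed (towards the insert-distal
# side) by an N-run plus a further defined segment, that segment is
# returned as `check` with `gap` N bases in between: a candidate flank
# occurrence only counts if the defined segment is found at its expected
# distance, which disambiguates fills that happen to recreate the flank.
trim_anchor <- function(adaptor, min_flank, flank_width = NULL) {
  s <- adaptor$rna
  len <- nchar(s)
  check <- ""
  gap <- 0L
  if (adaptor$n_length == 0) {
    flank <- s
    offset <- 0L
  } else {
    n0 <- adaptor$n_start
    n1 <- adaptor$n_start + adaptor$n_length - 1L
    before <- if (n0 > 1) stringr::str_sub(s, 1, n0 - 1) else ""
    after <- if (n1 < len) stringr::str_sub(s, n1 + 1, len) else ""
    if (adaptor$side == "three_prime") {
      # insert-proximal side is the adaptor's 5' end
      if (nchar(before) >= min_flank) {
        flank <- before
        offset <- 0L
        check <- after
        gap <- adaptor$n_length
      } else {
        flank <- after
        offset <- nchar(before) + adaptor$n_length
      }
    } else {
      # insert-proximal side is the adaptor's 3' end
      if (nchar(after) >= min_flank) {
        flank <- after
        offset <- 0L
        check <- before
        gap <- adaptor$n_length
      } else {
        flank <- before
        offset <- nchar(after) + adaptor$n_length
      }
    }
  }
  if (nchar(flank) < min_flank) {
    abort(sprintf(
      "adaptor '%s': defined flank '%s' is shorter than min_flank = %d",
      adaptor$name, flank, min_flank
    ))
  }
  if (!is.null(flank_width) && nchar(flank) > flank_width) {
    # keep the insert-proximal part of the flank; the rest of the adaptor is
    # downstream of the cut and removed with it
    flank <- if (adaptor$side == "three_prime") {
      stringr::str_sub(flank, 1, flank_width)
    } else {
      stringr::str_sub(flank, -flank_width, -1)
    }
    check <- ""
  }
  list(flank = flank, offset = as.integer(offset),
       check = check, gap = as.integer(gap))
}

# Candidate-scanning match used when a validation segment is configured:
# among all flank occurrences, pick the outermost (rightmost for the 3'
# side, leftmost for the 5' side) whose distal defined segment lies at the
# expected distance. Returns the flank match start (NA when none passes).
scan_validated <- function(rna, anchor, side) {
  flen <- nchar(anchor$flank)
  clen <- nchar(anchor$check)
  cands <- stringi::stri_locate_all_fixed(rna, anchor$flank)
  vapply(seq_along(rna), function(i) {
    starts <- cands[[i]][, "start"]
    if (anyNA(starts)) return(NA_integer_)
    if (side == "three_prime") {
      starts <- rev(starts)
    }
    for (s in starts) {
      if (side == "three_prime") {
        v0 <- s + flen + anchor$gap
        v1 <- v0 + clen - 1
        if (v1 <= nchar(rna[i]) &&
            substr(rna[i], v0, v1) == anchor$check) return(as.integer(s))
      } else {
        v1 <- s - anchor$gap - 1
        v0 <- v1 - clen + 1
        if (v0 >= 1 && substr(rna[i], v0, v1) == anchor$check) {
          return(as.integer(s))
        }
      }
    }
    NA_integer_
  }, integer(1))
}

#' Trim adaptor sequences off reads
#'
#' The 3' adaptor is located by an exact search for its insert-proximal
#' defined flank, scanning from the read's 3' side (rightmost occurrence),
#' so inserts that happen to contain the flank internally are cut at the
#' occurrence nearest the adaptor. When the adaptor's randomized (N) region
#' is insert-proximal, the first defined segment beyond it is the anchor and
#' the known number of intervening bases is removed together with the match.
#' The 5' adaptor is handled symmetrically (leftmost occurrence of its
#' insert-proximal flank). Reads in which a required flank is not found are
#' flagged `untrimmed` and excluded from annotation. All matching is done
#' after `T -> U` conversion.
#'
#' @param reads A tibble with columns `read_id` and `read` (see
#'   [read_reads()]), or a character vector of read sequences.
#' @param three_prime 3' [adaptor_spec()].
#' @param five_prime Optional 5' [adaptor_spec()].
#' @param min_flank Minimum usable defined-flank length; shorter flanks are
#'   rejected as too ambiguous to anchor a cut.
#' @param flank_width Optionally cap the searched flank at this many
#'   insert-proximal bases (default: the full defined segment must match).
#' @return A tibble with columns `read_id`, `read`, `insert` (RNA alphabet;
#'   `NA` when untrimmed) and `untrimmed`.
#' @examples
#' a3 <- adaptor_spec("GUUUGG", "three_prime")
#' trim_reads(c("AAACCCGUUUGG", "AAACCC"), a3)
#' @export
trim_reads <- function(reads, three_prime, five_prime = NULL,
                       min_flank = 4, flank_width = NULL) {
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("read", seq_along(reads)), read = reads)
  }
  stopifnot(is.data.frame(reads), all(c("read_id", "read") %in% names(reads)))
  stopifnot(inherits(three_prime, "adaptor_spec"),
            three_prime$side == "three_prime")
  rna <- as_rna(reads$read)
  n <- length(rna)
  insert <- rna
  untrimmed <- rep(FALSE, n)

  a3 <- trim_anchor(three_prime, min_flank, flank_width)
  start3 <- if (nzchar(a3$check)) {
    scan_validated(rna, a3, "three_prime")
  } else {
    stringi::stri_locate_last_fixed(rna, a3$flank)[, "start"]
  }
  cut3 <- start3 - 1L - a3$offset
  ok3 <- !is.na(cut3) & cut3 >= 0L
  untrimmed <- untrimmed | !ok3
  insert[ok3] <- stringr::str_sub(insert[ok3], 1, cut3[ok3])

  if (!is.null(five_prime)) {
    stopifnot(inherits(five_prime, "adaptor_spec"),
              five_prime$side == "five_prime")
    a5 <- trim_anchor(five_prime, min_flank, flank_width)
    start5 <- if (nzchar(a5$check)) {
      scan_validated(insert, a5, "five_prime")
    } else {
      stringi::stri_locate_first_fixed(insert, a5$flank)[, "start"]
    }
    from5 <- start5 + nchar(a5$flank) + a5$offset
    ok5 <- !untrimmed & !is.na(from5) & from5 <= nchar(insert) + 1L
    untrimmed <- untrimmed | !ok5
    insert[ok5] <- stringr::str_sub(insert[ok5], from5[ok5], -1)
  }
  insert[untrimmed] <- NA_character_
  tibble(read_id = reads$read_id, read = reads$read,
         insert = insert, untrimmed = untrimmed)
}
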