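#' Build a complementary-region ("C3"-style) 5' adaptor
#'
#' Replaces the 3'-terminal `k` bases of a 5' adaptor with the reverse
#' complement (RNA alphabet) of the first `k` bases of the 3' adaptor. The
#' resulting adaptor can base-pair with the 3' adaptor already attached to
#' every insert, promoting junction-in-a-loop cofold structures during the
#' 5' ligation regardless of the insert sequence.
#'
#' @param five_prime 5' [adaptor_spec()] (or sequence).
#' @param three_prime 3' [adaptor_spec()] (or sequence).
#' @param k Complementary-region length (default 7).
#' @return A 5' `adaptor_spec` (RNA alphabet) named after the input with a
#'   `-C3` suffix.
#' @examples
#' ad <- default_adaptors()
#' make_c3_adaptor(ad$five_prime, ad$three_prime)
#' @export
make_c3_adaptor <- function(five_prime, three_prime, k = 7) {
  a5 <- if (inherits(five_prime, "adaptor_spec")) five_prime
    else adaptor_spec(five_prime, "five_prime")
  a3 <- if (inherits(three_prime, "adaptor_spec")) three_prime
    else adaptor_spec(three_prime, "three_prime")
  if (k < 1) abort("k must be >= 1")
  if (nchar(a3$rna) < k) abort("k exceeds the 3' adaptor length")
  if (nchar(a5$rna) < k) abort("k exceeds the 5' adaptor length")
  suffix <- reverse_complement(stringr::str_sub(a3$rna, 1, k))
  seq <- paste0(stringr::str_sub(a5$rna, 1, nchar(a5$rna) - k), suffix)
  adaptor_spec(seq, "five_prime", name = paste0(a5$name, "-C3"),
               alphabet = "RNA")
}

#' Insert a randomized region into an adaptor
#'
#' Produces a randomized-pool adaptor: `n` `N` positions either at the
#' insert-proximal end of the adaptor (`"end_proximal"`, the classic
#' junction-adjacent randomized design) or starting at an internal position
#' (`"internal"`, the mid-adaptor design that keeps defined sequence at the
#' junction so insert termini remain identifiable). The defined flank on
#' the insert-distal side must keep at least 4 bases so the trimmer can
#' anchor on it.
#'
#' @param adaptor An [adaptor_spec()] without an existing N-run.
#' @param n Randomized-region length (default 6; 0 returns the adaptor
#'   unchanged).
#' @param placement `"internal"` or `"end_proximal"`.
#' @param position For `"internal"`: 1-based position at which the N-run
#'   starts (bases from `position` onward are shifted right).
#' @return An `adaptor_spec` with the N-run recorded.
#' @examples
#' a3 <- adaptor_spec("AGATCGGAAGAGC", "three_prime")
#' make_randomized_adaptor(a3, 6, "internal", position = 7)
#' make_randomized_adaptor(a3, 6, "end_proximal")
#' @export
make_randomized_adaptor <- function(adaptor, n = 6,
                                    placement = c("internal", "end_proximal"),
                                    position = NULL) {
  stopifnot(inherits(adaptor, "adaptor_spec"))
  placement <- match.arg(placement)
  if (adaptor$n_length > 0) abort("adaptor already has a randomized region")
  if (n == 0) return(adaptor)
  len <- nchar(adaptor$sequence)
  nn <- strrep("N", n)
  if (placement == "end_proximal") {
    # insert-proximal end: 5' end of a 3' adaptor, 3' end of a 5' adaptor
    seq <- if (adaptor$side == "three_prime") paste0(nn, adaptor$sequence)
      else paste0(adaptor$sequence, nn)
    distal <- len
  } else {
    if (is.null(position) || position < 1 || position > len + 1) {
      abort("internal placement needs a position within the adaptor")
    }
    seq <- paste0(stringr::str_sub(adaptor$sequence, 1, position - 1), nn,
                  stringr::str_sub(adaptor$sequence, position, len))
    distal <- if (adaptor$side == "three_prime") len - position + 1
      else position - 1
  }
  if (distal < 4) {
    abort("placement leaves fewer than 4 defined bases on the insert-distal side")
  }
  adaptor_spec(seq, adaptor$side,
               name = paste0(adaptor$name, if (placement == "internal")
                 "-MidRand" else "-Rand"),
               alphabet = adaptor$alphabet)
}

#' Design a 5' adaptor targeting a cofold junction state for one substrate
#'
#' Searches for an adaptor whose cofold with the target molecule (an insert
#' with its 3' adaptor already appended) places the ligation junction in
#' the requested configuration — by default an unpaired base in a loop on
#' both sides, the junction-in-a-broken-loop structure preferred by the
#' 5'-end ligase. Candidates are built by appending to the base adaptor's
#' 3' end the reverse complement (Watson-Crick only) of a 7-nt window of
#' the target starting at offsets 2..6, leaving at least one unpaired
#' target base 5' of the paired window so the loop can form. The first
#' candidate whose *accepted* cofold matches the requested state pair is
#' returned; if none does, the best accepted candidate (lowest joint
#' energy) is returned flagged unmet.
#'
#' @param target Target sequence (insert + 3' adaptor), RNA alphabet, at
#'   least 12 nt.
#' @param base Base 5' [adaptor_spec()] (or sequence) to extend.
#' @param desired Length-2 character vector: requested `(state_a, state_b)`
#'   junction states.
#' @param offsets Window start offsets to scan (default `2:6`).
#' @param window Complementary window length (default 7).
#' @param backend A [pair_fold_backend()].
#' @param map Junction category mapping table.
#' @return A list with elements `adaptor` (an `adaptor_spec`), `cofold`
#'   (its one-row [cofold_pairs()] result), `met` (logical) and
#'   `candidates` (all scanned candidates with their classifications).
#' @export
design_targeted_adaptor <- function(target, base,
                                    desired = c("loop_unpaired", "loop_unpaired"),
                                    offsets = 2:6, window = 7,
                                    backend = pair_fold_backend(),
                                    map = junction_category_map()) {
  a5 <- if (inherits(base, "adaptor_spec")) base
    else adaptor_spec(base, "five_prime")
  target <- check_alphabet(target, what = "target")
  if (nchar(target) < 12) abort("target must be at least 12 nt")
  stopifnot(length(desired) == 2, all(desired %in% junction_states))
  offsets <- offsets[offsets + window - 1 <= nchar(target)]
  if (length(offsets) == 0) abort("no window fits the target")
  cand_seq <- map_chr(offsets, function(w) {
    paste0(a5$rna,
           reverse_complement(stringr::str_sub(target, w, w + window - 1)))
  })
  cands <- cofold_pairs(tibble(offset = offsets, seq_a = cand_seq,
                               seq_b = target),
                        backend = backend, map = map)
  hit <- which(cands$accepted & cands$state_a == desired[1] &
                 cands$state_b == desired[2])
  met <- length(hit) > 0
  pick <- if (met) {
    hit[1]
  } else if (any(cands$accepted)) {
    acc <- which(cands$accepted)
    acc[which.min(cands$mfe_ab[acc])]
  } else {
    which.min(cands$mfe_ab)
  }
  adaptor <- adaptor_spec(cands$seq_a[pick], "five_prime",
                          name = paste0(a5$name, "-designed-w",
                                        cands$offset[pick]),
                          alphabet = "RNA")
  list(adaptor = adaptor, cofold = cands[pick, ], met = met,
       candidates = cands)
}
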