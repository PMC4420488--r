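#' Default favorability tables
#'
#' Each of the four folding attributes (3' fold of the bare insert, 5' fold
#' of the insert with 3' adaptor appended, 3' cofold with the 3' adaptor,
#' 5' cofold of the 5' adaptor with the insert-3'-adaptor hybrid) maps a
#' class label to a favorability call. The defaults encode the qualitative
#' ligase preferences driving the package's planted simulation model:
#' a paired terminal base (group `"0"`) is unfavorable; enrichment grows
#' with the number of free terminal bases (groups of 3+ favorable); fully
#' unstructured molecules (`"no pairing"`) are poor substrates for the
#' 5'-end ligase but good ones for the truncated ligase used at the 3' end;
#' junctions falling in a loop broken by the junction are favorable while
#' junctions next to a base paired within its own molecule (a stem or
#' bulge context) are unfavorable. Analyses of real libraries should
#' replace these with calls derived from measured enrichments via
#' [favorability_call()].
#'
#' @param end Which ligation end the single-molecule fold table is for.
#' @return `default_fold_favorability()`: a tibble with columns `group`,
#'   `call`; `default_cofold_favorability()`: a tibble with columns
#'   `state_a`, `state_b`, `call`; `default_favorability()`: a named list
#'   of all four tables (`fold3`, `fold5`, `cofold3`, `cofold5`).
#' @export
default_fold_favorability <- function(end = c("three_prime", "five_prime")) {
  end <- match.arg(end)
  groups <- c(as.character(0:5), "6+", "no pairing")
  call <- c("unfavorable", "neutral", "neutral", rep("favorable", 4),
            if (end == "five_prime") "unfavorable" else "favorable")
  tibble(group = groups, call = call)
}

#' @rdname default_fold_favorability
#' @export
default_cofold_favorability <- function() {
  map <- junction_category_map()
  loopish <- c("loop_unpaired", "exterior_unpaired")
  call <- dplyr::case_when(
    map$state_a == "paired_intra" | map$state_b == "paired_intra" ~ "unfavorable",
    map$state_a %in% loopish & map$state_b %in% loopish &
      (map$state_a == "loop_unpaired" | map$state_b == "loop_unpaired") ~ "favorable",
    TRUE ~ "neutral"
  )
  tibble(state_a = map$state_a, state_b = map$state_b, call = call)
}

#' @rdname default_fold_favorability
#' @export
default_favorability <- function() {
  list(
    fold3 = default_fold_favorability("three_prime"),
    fold5 = default_fold_favorability("five_prime"),
    cofold3 = default_cofold_favorability(),
    cofold5 = default_cofold_favorability()
  )
}

# Look up the call for a terminal-group label, collapsing large counts into
# the table's open-ended top group (e.g. "6+"). Unseen labels are neutral
# with a warning.
lookup_fold_call <- function(labels, table) {
  plus <- stringr::str_subset(table$group, "\\+$")
  if (length(plus) == 1) {
    cap <- as.numeric(sub("\\+$", "", plus))
    num <- suppressWarnings(as.numeric(labels))
    labels <- ifelse(!is.na(num) & num >= cap, plus, labels)
  }
  call <- table$call[match(labels, table$group)]
  if (anyNA(call)) {
    warn(sprintf("no favorability entry for group(s) %s; treated as neutral",
                 paste(unique(labels[is.na(call)]), collapse = ", ")))
    call[is.na(call)] <- "neutral"
  }
  call
}

lookup_cofold_call <- function(state_a, state_b, accepted, table) {
  call <- table$call[match(paste(state_a, state_b),
                           paste(table$state_a, table$state_b))]
  if (anyNA(call[accepted])) {
    warn("no favorability entry for some junction state pairs; treated as neutral")
    call[is.na(call)] <- "neutral"
  }
  # a rejected joint fold means no A:B structure is considered at all
  call[!accepted] <- "neutral"
  call
}

#' Per-sequence folding attribute vectors
#'
#' Computes, for every pool sequence, the four folding attributes that
#' drive ligation efficiency and their favorability calls:
#'
#' * `fold3`: terminal unpaired-base group at the 3' end of the bare insert;
#' * `fold5`: terminal unpaired-base group at the 5' end of the insert with
#'   the 3' adaptor sequence appended (the molecule actually entering the
#'   5' ligation);
#' * `cofold3`: junction states of the insert cofolded with the 3' adaptor
#'   (junction = insert 3' end / adaptor start);
#' * `cofold5`: junction states of the 5' adaptor cofolded with the
#'   insert-3'-adaptor hybrid.
#'
#' `n_unfavorable` (0-4) counts unfavorable slots; sequences with many
#' unfavorable attributes are the ones most under-represented in libraries
#' built with single-sequence adaptors.
#'
#' @param pool A [reference_pool()] tibble.
#' @param three_prime,five_prime [adaptor_spec()] objects with no
#'   uninstantiated randomized region.
#' @param favorability A list of four call tables as returned by
#'   [default_favorability()].
#' @param single_backend Backend for single-molecule folds.
#' @param pair_backend Backend for pair folds.
#' @param map Junction category mapping table.
#' @return A tibble with one row per pool sequence: group labels, junction
#'   states and categories, the four calls and `n_unfavorable`.
#' @export
attribute_vectors <- function(pool, three_prime, five_prime,
                              favorability = default_favorability(),
                              single_backend = single_fold_backend(),
                              pair_backend = pair_fold_backend(),
                              map = junction_category_map()) {
  stopifnot(inherits(three_prime, "adaptor_spec"),
            inherits(five_prime, "adaptor_spec"))
  if (three_prime$n_length > 0 || five_prime$n_length > 0) {
    abort(paste("adaptors with a randomized region must be instantiated",
                "before attribute analysis (see make_randomized_adaptor",
                "details or draw fills per variant)"))
  }
  a3 <- three_prime$rna
  a5 <- five_prime$rna
  hybrid <- paste0(pool$sequence, a3)

  f3 <- backend_fold(single_backend, pool$sequence)
  f5 <- backend_fold(single_backend, hybrid)
  fold3_group <- count_terminal_unpaired(f3$structure, "three_prime")
  fold5_group <- count_terminal_unpaired(f5$structure, "five_prime")

  cf3 <- cofold_pairs(tibble(seq_a = pool$sequence, seq_b = a3),
                      backend = pair_backend, map = map)
  cf5 <- cofold_pairs(tibble(seq_a = a5, seq_b = hybrid),
                      backend = pair_backend, map = map)

  fold3_call <- lookup_fold_call(fold3_group, favorability$fold3)
  fold5_call <- lookup_fold_call(fold5_group, favorability$fold5)
  cofold3_call <- lookup_cofold_call(cf3$state_a, cf3$state_b, cf3$accepted,
                                     favorability$cofold3)
  cofold5_call <- lookup_cofold_call(cf5$state_a, cf5$state_b, cf5$accepted,
                                     favorability$cofold5)
  calls <- cbind(fold3_call, fold5_call, cofold3_call, cofold5_call)

  tibble(
    id = pool$id,
    fold3_group = fold3_group, fold5_group = fold5_group,
    cofold3_state_a = cf3$state_a, cofold3_state_b = cf3$state_b,
    cofold3_category = cf3$category, cofold3_accepted = cf3$accepted,
    cofold5_state_a = cf5$state_a, cofold5_state_b = cf5$state_b,
    cofold5_category = cf5$category, cofold5_accepted = cf5$accepted,
    fold3_call = fold3_call, fold5_call = fold5_call,
    cofold3_call = cofold3_call, cofold5_call = cofold5_call,
    n_unfavorable = as.integer(rowSums(calls == "unfavorable"))
  )
}
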