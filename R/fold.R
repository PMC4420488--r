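#' Configure folding backends
#'
#' Two backends are used, mirroring the use of different programs for the
#' two prediction tasks: a single-molecule MFE predictor (default: RNAfold
#' with default settings) and a two-molecule cofold predictor (default:
#' RNAcofold at 25 degrees C with the 1999 Turner parameter set). The
#' `"toy"` engine is a self-contained pair-energy dynamic program usable for
#' both tasks when ViennaRNA is not on the PATH; its energies live on their
#' own scale.
#'
#' @param engine `"auto"` (ViennaRNA if available, else toy), `"vienna"` or
#'   `"toy"`.
#' @param temperature Folding temperature in degrees C (ViennaRNA only).
#' @param parameters ViennaRNA energy parameter set: a name such as
#'   `"turner1999"`/`"turner2004"`, a path to a `.par` file, or `NULL` for
#'   the program default.
#' @return A `fold_backend` object.
#' @examples
#' pair_fold_backend()
#' single_fold_backend(engine = "toy")
#' @name backends
NULL

new_backend <- function(engine, temperature, parameters, task) {
  engine <- match.arg(engine, c("auto", "vienna", "toy"))
  if (engine == "auto") engine <- if (vienna_available()) "vienna" else "toy"
  structure(
    list(engine = engine, temperature = temperature,
         parameters = parameters, task = task),
    class = "fold_backend"
  )
}

#' @rdname backends
#' @export
single_fold_backend <- function(engine = "auto", temperature = 37,
                                parameters = NULL) {
  new_backend(engine, temperature, parameters, "single")
}

#' @rdname backends
#' @export
pair_fold_backend <- function(engine = "auto", temperature = 25,
                              parameters = "turner1999") {
  new_backend(engine, temperature, parameters, "pair")
}

#' @export
print.fold_backend <- function(x, ...) {
  cat(sprintf("<fold_backend> %s (%s-molecule), T = %s, parameters = %s\n",
              x$engine, if (x$task == "single") "single" else "two",
              x$temperature, x$parameters %||% "default"))
  invisible(x)
}

backend_fold <- function(backend, sequences) {
  if (backend$engine == "vienna") {
    vienna_fold_batch(sequences, backend$temperature, backend$parameters)
  } else {
    toy_fold_batch(sequences)
  }
}

backend_cofold <- function(backend, a, b) {
  if (backend$engine == "vienna") {
    vienna_cofold_batch(a, b, backend$temperature, backend$parameters)
  } else {
    toy_cofold_batch(a, b)
  }
}

#' Predict single-molecule secondary structures
#'
#' Minimum-free-energy structure and energy for each sequence, one canonical
#' structure per molecule (no suboptimal ensemble).
#'
#' @param data A data frame with a `sequence` column (RNA alphabet; T
#'   accepted), or a character vector.
#' @param backend A [single_fold_backend()].
#' @return The input tibble with `structure` (dot-bracket) and `mfe`
#'   (kcal/mol) columns appended.
#' @examples
#' fold_sequences(c("AAAAAAA", "GGGGAAAACCCC"), single_fold_backend("toy"))
#' @export
fold_sequences <- function(data, backend = single_fold_backend()) {
  if (is.character(data)) data <- tibble(sequence = data)
  stopifnot(is.data.frame(data), "sequence" %in% names(data))
  if (nrow(data) == 0) abort("no sequences to fold")
  if (any(!nzchar(data$sequence))) abort("empty sequence")
  seqs <- check_alphabet(data$sequence, what = "sequence")
  res <- backend_fold(backend, seqs)
  out <- as_tibble(data)
  out$sequence <- seqs
  out$structure <- res$structure
  out$mfe <- res$mfe
  out
}

#' @rdname fold_sequences
#' @param sequence A single sequence.
#' @export
fold_single <- function(sequence, backend = single_fold_backend()) {
  stopifnot(length(sequence) == 1)
  fold_sequences(sequence, backend)
}

#' Cofold molecule pairs and classify the ligation junction
#'
#' Each pair (A, B) is folded jointly; the ligation junction sits between
#' A's last base and B's first base. A joint structure is only *accepted* —
#' and its junction classified — when the free energy of AB formation is
#' below that of either molecule folded alone (monomer energies computed
#' under the same backend settings). DNA input is converted `T -> U` and
#' folded with the RNA model.
#'
#' @param data A data frame with columns `seq_a` and `seq_b`.
#' @param backend A [pair_fold_backend()].
#' @param map Junction category mapping table, see [junction_category_map()].
#' @return The input tibble with columns `structure` (dual dot-bracket with
#'   `&`), `mfe_ab`, `mfe_a`, `mfe_b`, `accepted`, `state_a`, `state_b`,
#'   `category` (`NA` unless accepted) appended.
#' @examples
#' cofold_pair("GGGGG", "CCCCC", backend = pair_fold_backend("toy"))
#' @export
cofold_pairs <- function(data, backend = pair_fold_backend(),
                         map = junction_category_map()) {
  stopifnot(is.data.frame(data), all(c("seq_a", "seq_b") %in% names(data)))
  if (nrow(data) == 0) abort("no pairs to fold")
  a <- check_alphabet(data$seq_a, what = "seq_a")
  b <- check_alphabet(data$seq_b, what = "seq_b")
  co <- backend_cofold(backend, a, b)
  mono_seqs <- unique(c(a, b))
  mono <- backend_fold(backend, mono_seqs)
  mfe_a <- mono$mfe[match(a, mono_seqs)]
  mfe_b <- mono$mfe[match(b, mono_seqs)]
  accepted <- co$mfe < pmin(mfe_a, mfe_b)
  cls <- classify_junction(co$structure, map = map)
  out <- as_tibble(data)
  out$seq_a <- a
  out$seq_b <- b
  out$structure <- co$structure
  out$mfe_ab <- co$mfe
  out$mfe_a <- mfe_a
  out$mfe_b <- mfe_b
  out$accepted <- accepted
  out$state_a <- cls$state_a
  out$state_b <- cls$state_b
  out$category <- ifelse(accepted, cls$category_id, NA_integer_)
  out
}

#' @rdname cofold_pairs
#' @param seq_a,seq_b A single pair of sequences.
#' @export
cofold_pair <- function(seq_a, seq_b, backend = pair_fold_backend(),
                        map = junction_category_map()) {
  cofold_pairs(tibble(seq_a = seq_a, seq_b = seq_b), backend, map)
}

#' Terminal unpaired-base group of a fold
#'
#' Length of the maximal run of unpaired bases (`.`) at the chosen end of a
#' dot-bracket structure, as a group label; a structure with no paired base
#' at all forms its own group, `"no pairing"`.
#'
#' @param structure Character vector of dot-bracket structures.
#' @param end `"five_prime"` (left end) or `"three_prime"` (right end).
#' @return Character vector of group labels (`"0"`, `"1"`, ..., or
#'   `"no pairing"`).
#' @examples
#' count_terminal_unpaired(c(".((...))", "((....))", "........"), "five_prime")
#' @export
count_terminal_unpaired <- function(structure,
                                    end = c("five_prime", "three_prime")) {
  end <- match.arg(end)
  pat <- if (end == "five_prime") "^\\.*" else "\\.*$"
  k <- nchar(stringr::str_extract(structure, pat))
  ifelse(!stringr::str_detect(structure, "\\("), "no pairing", as.character(k))
}

# The four terminal states a junction-flanking base can be in, in the order
# used by the default category numbering.
junction_states <- c("exterior_unpaired", "loop_unpaired",
                     "paired_intra", "paired_inter")

#' Junction category mapping table
#'
#' The 16 junction categories are the 4 x 4 combinations of the terminal
#' state of the two bases flanking the ligation junction: each base is
#' either an unpaired base enclosed by no pair (`exterior_unpaired`), an
#' unpaired base inside a loop (`loop_unpaired`), paired within its own
#' molecule (`paired_intra`), or paired across the junction
#' (`paired_inter`). The default table assigns ids 1..16 in row-major state
#' order; supply a reordered table to [classify_junction()] to recalibrate
#' the numbering against a published scheme.
#'
#' @return A tibble with columns `state_a`, `state_b`, `category_id` — a
#'   bijection onto 1..16.
#' @export
junction_category_map <- function() {
  out <- tidyr::expand_grid(state_a = junction_states,
                            state_b = junction_states)
  out$category_id <- seq_len(16)
  out
}

check_category_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("state_a", "state_b", "category_id") %in% names(map)))
  if (nrow(map) != 16 ||
      anyDuplicated(paste(map$state_a, map$state_b)) ||
      !setequal(map$category_id, 1:16)) {
    abort("category map must be a bijection from the 16 state pairs onto 1..16")
  }
  map
}

#' Classify the ligation junction of a dual dot-bracket structure
#'
#' For each base flanking the `&` junction, determines its terminal state
#' (see [junction_category_map()]): paired across the junction, paired
#' within its own molecule, unpaired inside a loop (enclosed by at least one
#' pair), or unpaired outside any pair.
#'
#' @param structure Character vector of dual dot-bracket structures, each
#'   with exactly one `&`.
#' @param map Category mapping table.
#' @return A tibble with columns `state_a`, `state_b`, `category_id`.
#' @examples
#' classify_junction("(((...&...)))")
#' classify_junction("(((&)))")
#' @export
classify_junction <- function(structure, map = junction_category_map()) {
  map <- check_category_map(map)
  one <- function(s) {
    amp <- stringr::str_locate_all(s, stringr::fixed("&"))[[1]][, 1]
    if (length(amp) != 1) abort(sprintf("need exactly one '&' in '%s'", s))
    chars <- strsplit(sub("&", "", s, fixed = TRUE), "", fixed = TRUE)[[1]]
    la <- amp - 1L
    n <- length(chars)
    if (la < 1 || la >= n) abort(sprintf("junction at the end of '%s'", s))
    if (!all(chars %in% c(".", "(", ")"))) {
      abort(sprintf("malformed dot-bracket '%s'", s))
    }
    partner <- rep(NA_integer_, n)
    depth_at <- integer(n)
    stack <- integer(0)
    for (i in seq_len(n)) {
      depth_at[i] <- length(stack)
      if (chars[i] == "(") {
        stack <- c(stack, i)
      } else if (chars[i] == ")") {
        if (length(stack) == 0) abort(sprintf("unbalanced brackets in '%s'", s))
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        partner[i] <- j
        partner[j] <- i
        depth_at[i] <- length(stack) # enclosure depth outside this pair
      }
    }
    if (length(stack) > 0) abort(sprintf("unbalanced brackets in '%s'", s))
    state_of <- function(pos) {
      if (chars[pos] == ".") {
        if (depth_at[pos] > 0) "loop_unpaired" else "exterior_unpaired"
      } else {
        p <- partner[pos]
        if ((pos <= la) != (p <= la)) "paired_inter" else "paired_intra"
      }
    }
    c(state_of(la), state_of(la + 1L))
  }
  states <- vapply(structure, one, character(2), USE.NAMES = FALSE)
  out <- tibble(state_a = states[1, ], state_b = states[2, ])
  key <- paste(out$state_a, out$state_b)
  out$category_id <- map$category_id[match(key, paste(map$state_a, map$state_b))]
  out
}

#' Distribution of junction categories among accepted cofolds
#'
#' @param cofolds Output of [cofold_pairs()].
#' @return A tibble with columns `category`, `n`, `pct` (percent of accepted
#'   cofolds; sums to 100) and attribute `n_rejected` counting pairs whose
#'   joint fold was not accepted.
#' @export
category_distribution <- function(cofolds) {
  stopifnot(is.data.frame(cofolds),
            all(c("accepted", "category") %in% names(cofolds)))
  acc <- cofolds[cofolds$accepted, ]
  if (nrow(acc) == 0) {
    abort(sprintf("no accepted cofolds (%d pairs rejected)", nrow(cofolds)))
  }
  out <- acc |>
    count(category = .data$category, name = "n") |>
    mutate(pct = 100 * .data$n / sum(.data$n))
  attr(out, "n_rejected") <- sum(!cofolds$accepted)
  out
}

#' Distribution of arbitrary group labels
#'
#' Percent of sequences per group, e.g. terminal unpaired-base groups from
#' [count_terminal_unpaired()].
#'
#' @param groups Character vector of group labels.
#' @return A tibble with columns `group`, `n`, `pct`.
#' @export
group_distribution <- function(groups) {
  if (length(groups) == 0) abort("no groups")
  tibble(group = groups) |>
    count(.data$group, name = "n") |>
    mutate(pct = 100 * .data$n / sum(.data$n))
}

#' Enrichment of a subset distribution over a reference distribution
#'
#' The signed fraction `(subset - all) / all` applied to matching category
#' or group percentages: +0.5 means the class is 50% more frequent in the
#' subset (e.g. well-represented sequences, or a ligated "output" library)
#' than in the reference ("all" sequences, or the "input" library).
#' Categories absent from the reference are `NA`.
#'
#' @param subset_pct,all_pct Numeric vectors of matching percentages.
#' @return Numeric vector of enrichment fractions.
#' @examples
#' enrichment(30, 20)
#' @export
enrichment <- function(subset_pct, all_pct) {
  ifelse(all_pct > 0, (subset_pct - all_pct) / all_pct, NA_real_)
}

#' Join two distributions and compute per-class enrichment
#'
#' @param subset,all Distribution tibbles (from [category_distribution()] or
#'   [group_distribution()]) sharing their first grouping column.
#' @param by Name of the grouping column (default: first column of `all`).
#' @return A tibble with the grouping column, `pct_subset`, `pct_all`,
#'   `enrichment`. Classes missing from `subset` get `pct_subset = 0`.
#' @export
enrichment_table <- function(subset, all, by = names(all)[1]) {
  out <- all |>
    select(dplyr::all_of(by), pct_all = "pct") |>
    left_join(subset |> select(dplyr::all_of(by), pct_subset = "pct"),
              by = by) |>
    mutate(
      pct_subset = dplyr::coalesce(.data$pct_subset, 0),
      enrichment = enrichment(.data$pct_subset, .data$pct_all)
    ) |>
    select(dplyr::all_of(by), "pct_subset", "pct_all", "enrichment")
  out
}

#' Favorability call for an enrichment value
#'
#' An attribute class is *unfavorable* for ligation when its enrichment is
#' -10% or worse, and *favorable* when its enrichment reaches +20% (cofold
#' attributes) or +5% (single-molecule fold attributes); anything between is
#' neutral.
#'
#' @param E Numeric vector of enrichment fractions (e.g. -0.12 for -12%).
#' @param kind `"cofold"` or `"contrafold"` (single-molecule fold), which
#'   sets the favorable threshold.
#' @return Character vector: `"favorable"`, `"neutral"` or `"unfavorable"`.
#' @examples
#' favorability_call(c(-0.12, 0.1, 0.25), "cofold")
#' favorability_call(0.1, "contrafold")
#' @export
favorability_call <- function(E, kind = c("cofold", "contrafold")) {
  kind <- match.arg(kind)
  up <- if (kind == "cofold") 0.20 else 0.05
  dplyr::case_when(
    is.na(E) ~ NA_character_,
    E <= -0.10 ~ "unfavorable",
    E >= up ~ "favorable",
    TRUE ~ "neutral"
  )
}
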