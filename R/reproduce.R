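#' Full reference-pool bias analysis from raw files
#'
#' End-to-end pipeline for a defined-pool experiment: load the pool, trim
#' and annotate each replicate's reads, normalize, average replicates,
#' summarize fold deviation, and run the structure analysis — cofold
#' category distributions for all sequences versus the well-represented
#' subset (normalized reads >= 0.5), per-category enrichment and
#' favorability calls, per-sequence attribute vectors and the 0-4
#' unfavorable-attribute grouping with its per-group deviation metrics.
#'
#' This is the entry point for reproducing a published defined-pool
#' analysis from deposited sequencing runs; all inputs are local files.
#'
#' @param pool_fasta FASTA of the defined pool.
#' @param reads_files Character vector of FASTQ/FASTA read files (replicate
#'   libraries of the same adaptor scheme).
#' @param three_prime,five_prime [adaptor_spec()] objects used for
#'   trimming and for the cofold attribute analysis.
#' @param concentrations Optional concentration TSV (see
#'   [read_reference_pool()]).
#' @param over_threshold Normalized-read threshold defining the
#'   well-represented subset (default 0.5).
#' @param min_flank,flank_width Passed to [trim_reads()].
#' @param single_backend,pair_backend,map Structure-analysis settings.
#' @return A list: `pool`, `replicates` (per-file normalized tables),
#'   `norm` (averaged), `bias` (fold-deviation report), `attrs`,
#'   `cofold3_enrichment`, `cofold5_enrichment` (enrichment tables with
#'   favorability calls), `group_bias` (per 0-4 unfavorable group metrics),
#'   `replicate_r2` and `replicate_discrepancy_pct` when >= 2 replicates.
#' @export
reproduce_reference_analysis <- function(pool_fasta, reads_files,
                                         three_prime, five_prime,
                                         concentrations = NULL,
                                         over_threshold = 0.5,
                                         min_flank = 4, flank_width = NULL,
                                         single_backend = single_fold_backend(),
                                         pair_backend = pair_fold_backend(),
                                         map = junction_category_map()) {
  pool <- read_reference_pool(pool_fasta, concentrations)
  reps <- map(reads_files, function(f) {
    reads <- read_reads(f)
    trimmed <- trim_reads(reads, three_prime, five_prime,
                          min_flank = min_flank, flank_width = flank_width)
    normalize_counts(annotate_reads(trimmed, pool), pool)
  })
  norm <- if (length(reps) >= 2) average_replicates(reps) else reps[[1]]

  attrs0 <- attribute_vectors(pool, three_prime, five_prime,
                              single_backend = single_backend,
                              pair_backend = pair_backend, map = map)
  over_ids <- norm$id[norm$normalized_reads >= over_threshold]
  enr <- function(state_a, state_b, accepted) {
    df <- tibble(id = pool$id, accepted = accepted,
                 category = ifelse(accepted,
                                   classify_key(state_a, state_b, map),
                                   NA_integer_))
    all_d <- category_distribution(
      tibble(accepted = df$accepted, category = df$category))
    over_d <- category_distribution(
      tibble(accepted = df$accepted, category = df$category)[df$id %in% over_ids, ])
    out <- enrichment_table(over_d, all_d, by = "category")
    out$call <- favorability_call(out$enrichment, "cofold")
    out
  }
  cofold3_enr <- enr(attrs0$cofold3_state_a, attrs0$cofold3_state_b,
                     attrs0$cofold3_accepted)
  cofold5_enr <- enr(attrs0$cofold5_state_a, attrs0$cofold5_state_b,
                     attrs0$cofold5_accepted)

  # refold favorability from the measured enrichments, then regroup
  fav <- default_favorability()
  fav$cofold3 <- calls_to_state_table(cofold3_enr, map)
  fav$cofold5 <- calls_to_state_table(cofold5_enr, map)
  attrs <- attribute_vectors(pool, three_prime, five_prime,
                             favorability = fav,
                             single_backend = single_backend,
                             pair_backend = pair_backend, map = map)

  joined <- left_join(as_tibble(norm),
                      select(attrs, "id", "n_unfavorable"), by = "id")
  group_bias <- joined |>
    group_by(.data$n_unfavorable) |>
    dplyr::reframe(fold_deviation_metrics(.data$ratio))

  out <- list(pool = pool, replicates = reps, norm = norm,
              bias = fold_deviation_metrics(norm),
              attrs = attrs, cofold3_enrichment = cofold3_enr,
              cofold5_enrichment = cofold5_enr, group_bias = group_bias)
  if (length(reps) >= 2) {
    x <- reps[[1]]$normalized_reads
    y <- reps[[2]]$normalized_reads[match(reps[[1]]$id, reps[[2]]$id)]
    out$replicate_r2 <- replicate_correlation(x, y)
    out$replicate_discrepancy_pct <- replicate_discrepancy(x, y)
  }
  out
}

classify_key <- function(state_a, state_b, map) {
  map$category_id[match(paste(state_a, state_b),
                        paste(map$state_a, map$state_b))]
}

# Spread per-category favorability calls back onto the 16 state pairs
# (categories never observed stay neutral).
calls_to_state_table <- function(enr, map) {
  out <- map
  out$call <- enr$call[match(out$category_id, enr$category)]
  out$call[is.na(out$call)] <- "neutral"
  select(out, "state_a", "state_b", "call")
}
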