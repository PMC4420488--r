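# One top-level seed; every random draw derives from a named substream so
# that pool construction, per-context efficiency residuals and read
# sampling are independently reproducible.
substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 10007 + h * 7919) %% 2147483629)
}

#' Configuration for the synthetic ligation-bias study
#'
#' Describes a defined pool and library construction under a planted
#' structure-driven ligation-efficiency model: each sequence's efficiency
#' is the product of one multiplier per favorability call over its four
#' folding attributes, times a lognormal per-(sequence, adaptor-context)
#' residual capturing ligation variability the four discrete attributes do
#' not explain (real single-adaptor libraries show a continuous spread of
#' several orders of magnitude, not a handful of discrete levels). Reads
#' are then drawn multinomially with probabilities proportional to
#' concentration times efficiency.
#'
#' @param pool_size Number of unique pool sequences.
#' @param insert_length Length range (inclusive) of pool sequences, nt.
#' @param mix `"equimolar"` or `"spread"` (geometric concentration series
#'   spanning `spread_fold` from the most to least abundant sequence).
#' @param spread_fold Concentration spread for `mix = "spread"`.
#' @param three_prime,five_prime Adaptor pair used for library construction
#'   and attribute analysis.
#' @param multipliers Named numeric: efficiency multiplier per favorability
#'   call.
#' @param sd_log_effect sdlog of the lognormal residual (0 disables it).
#' @param total_reads Reads per simulated library.
#' @param error_rate Per-base uniform substitution rate applied to emitted
#'   reads (default 0 so zero-mismatch annotation stays exact).
#' @param seed Top-level seed; all draws derive from it via named
#'   substreams.
#' @param favorability Favorability tables used both to plant efficiencies
#'   and (by a well-calibrated analysis) to recover them.
#' @param single_backend,pair_backend Folding backends.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(pool_size = 200,
                       insert_length = c(20, 25),
                       mix = c("equimolar", "spread"),
                       spread_fold = 500,
                       three_prime = default_adaptors()$three_prime,
                       five_prime = default_adaptors()$five_prime,
                       multipliers = c(unfavorable = 0.15, neutral = 1,
                                       favorable = 2),
                       sd_log_effect = 1,
                       total_reads = 2e6,
                       error_rate = 0,
                       seed = 1,
                       favorability = default_favorability(),
                       single_backend = single_fold_backend(),
                       pair_backend = pair_fold_backend()) {
  mix <- match.arg(mix)
  if (pool_size < 1) abort("pool_size must be >= 1")
  stopifnot(length(insert_length) == 2, insert_length[1] <= insert_length[2])
  if (any(multipliers <= 0)) abort("multipliers must be > 0")
  if (total_reads < pool_size) abort("total_reads must be >= pool_size")
  structure(
    list(pool_size = pool_size, insert_length = insert_length, mix = mix,
         spread_fold = spread_fold, three_prime = three_prime,
         five_prime = five_prime, multipliers = multipliers,
         sd_log_effect = sd_log_effect, total_reads = total_reads,
         error_rate = error_rate, seed = seed, favorability = favorability,
         single_backend = single_backend, pair_backend = pair_backend),
    class = "sim_config"
  )
}

#' Generate a defined synthetic reference pool
#'
#' Unique random RNA sequences in the configured length range with
#' equimolar or geometrically spread concentrations; byte-for-byte
#' reproducible for a fixed seed.
#'
#' @param config A [sim_config()].
#' @return A [reference_pool()] tibble.
#' @export
generate_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$pool_size
  withr::with_seed(substream(config$seed, "pool"), {
    seqs <- character(0)
    for (round in 1:20) {
      lens <- sample(seq(config$insert_length[1], config$insert_length[2]),
                     2 * n, replace = TRUE)
      new <- map_chr(lens, ~ paste(sample(c("A", "C", "G", "U"), .x,
                                          replace = TRUE), collapse = ""))
      seqs <- unique(c(seqs, new))
      if (length(seqs) >= n) break
    }
    if (length(seqs) < n) abort("could not generate enough unique sequences")
    seqs <- seqs[seq_len(n)]
    conc <- if (config$mix == "equimolar") {
      rep(1, n)
    } else if (n == 1) {
      1
    } else {
      sample(config$spread_fold^((seq_len(n) - 1) / (n - 1)))
    }
    reference_pool(setNames(seqs, sprintf("syn%04d", seq_len(n))), conc)
  })
}

#' Planted ligation efficiency from attribute calls
#'
#' The deterministic part of the planted model: the product over the four
#' attribute slots of the multiplier for that slot's favorability call.
#'
#' @param attrs An [attribute_vectors()] tibble.
#' @param multipliers Named numeric multiplier per call.
#' @return A tibble with columns `id`, `efficiency`.
#' @examples
#' attrs <- tibble::tibble(id = "s1", fold3_call = "neutral",
#'   fold5_call = "neutral", cofold3_call = "unfavorable",
#'   cofold5_call = "favorable")
#' planted_efficiency(attrs, c(unfavorable = 0.15, neutral = 1, favorable = 2))
#' @export
planted_efficiency <- function(attrs,
                               multipliers = c(unfavorable = 0.15,
                                               neutral = 1, favorable = 2)) {
  cols <- c("fold3_call", "fold5_call", "cofold3_call", "cofold5_call")
  stopifnot(all(cols %in% names(attrs)))
  m <- sapply(cols, function(cl) unname(multipliers[attrs[[cl]]]))
  m <- matrix(m, nrow = nrow(attrs))
  if (anyNA(m)) abort("favorability call without a multiplier")
  tibble(id = attrs$id, efficiency = apply(m, 1, prod))
}

# Efficiency of every pool sequence in one adaptor context: planted product
# times the lognormal residual for that context.
context_efficiency <- function(pool, attrs, config, context) {
  e <- planted_efficiency(attrs, config$multipliers)
  effect <- if (config$sd_log_effect > 0) {
    withr::with_seed(substream(config$seed, paste0("effect:", context)),
                     rlnorm(nrow(pool), 0, config$sd_log_effect))
  } else {
    rep(1, nrow(pool))
  }
  tibble(id = pool$id, e_attr = e$efficiency, effect = effect,
         efficiency = e$efficiency * effect)
}

#' Per-sequence efficiencies for a pool of adaptor variants
#'
#' Emulates library construction with randomized-region adaptors: each
#' variant is one concrete instantiation of the adaptor pair's N-runs, its
#' attribute vectors are recomputed (the cofold and hybrid-fold attributes
#' change with the fill) and a fresh residual is drawn. A sequence's
#' effective efficiency under the adaptor pool is the mean over variants,
#' which is what averages structure-driven bias away.
#'
#' @param pool A [reference_pool()] tibble.
#' @param config A [sim_config()] whose adaptors carry N-runs (defined
#'   adaptors give variants differing only by residual).
#' @param n_variants Number of adaptor variants (>= 2; 16 or more for a
#'   realistic randomized pool).
#' @return A list: `pooled` (tibble `id`, `efficiency` — the mean),
#'   `per_variant` (long tibble with `variant` column).
#' @export
adaptor_pool_efficiencies <- function(pool, config, n_variants = 16) {
  if (n_variants < 2) abort("need at least 2 adaptor variants")
  per <- map(seq_len(n_variants), function(v) {
    ctx <- paste0("variant", v)
    a3 <- withr::with_seed(substream(config$seed, paste0(ctx, ":fill3")),
                           instantiate_adaptor(config$three_prime))
    a5 <- withr::with_seed(substream(config$seed, paste0(ctx, ":fill5")),
                           instantiate_adaptor(config$five_prime))
    attrs <- attribute_vectors(pool, a3, a5,
                               favorability = config$favorability,
                               single_backend = config$single_backend,
                               pair_backend = config$pair_backend)
    eff <- context_efficiency(pool, attrs, config, ctx)
    eff$variant <- v
    eff
  })
  per <- bind_rows(per)
  pooled <- per |>
    group_by(.data$id) |>
    summarise(efficiency = mean(.data$efficiency), .groups = "drop")
  list(pooled = pooled[match(pool$id, pooled$id), ], per_variant = per)
}

#' Simulate a sequencing library from planted efficiencies
#'
#' Read counts are drawn from one multinomial with probabilities
#' proportional to `concentration * efficiency`. Optionally emits the reads
#' themselves (DNA alphabet) as 5'-adaptor + insert + 3'-adaptor with any
#' randomized regions filled uniformly per read, for end-to-end runs
#' through [trim_reads()] and [annotate_reads()].
#'
#' @param pool A [reference_pool()] tibble.
#' @param efficiencies Tibble with columns `id`, `efficiency` (e.g. from
#'   [context_efficiency()] via [simulate_bias_study()], or
#'   [adaptor_pool_efficiencies()]`$pooled`).
#' @param config A [sim_config()].
#' @param context Substream label; two calls with the same config and
#'   context give identical draws, different contexts give independent
#'   libraries (e.g. replicates).
#' @param emit_reads If `TRUE`, include a `reads` tibble.
#' @return A list with `counts` (an `lb_counts` table, directly usable by
#'   [normalize_counts()]), `truth` (id, concentration, efficiency, p,
#'   count) and optionally `reads` (`read_id`, `read`).
#' @export
simulate_library <- function(pool, efficiencies, config, context = "library",
                             emit_reads = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  eff <- efficiencies$efficiency[match(pool$id, efficiencies$id)]
  if (anyNA(eff)) abort("efficiencies missing for some pool ids")
  w <- pool$concentration * eff
  if (!any(w > 0)) abort("degenerate probability vector: all weights zero")
  p <- w / sum(w)
  counts <- withr::with_seed(
    substream(config$seed, paste0("reads:", context)),
    as.integer(rmultinom(1, config$total_reads, p))
  )
  truth <- tibble(id = pool$id, concentration = pool$concentration,
                  efficiency = eff, p = p, count = counts)
  ct <- tibble(id = pool$id, count = counts)
  attr(ct, "unannotated") <- 0L
  attr(ct, "total_reads") <- sum(counts)
  class(ct) <- c("lb_counts", class(ct))
  out <- list(counts = ct, truth = truth)
  if (emit_reads) {
    out$reads <- withr::with_seed(
      substream(config$seed, paste0("emit:", context)),
      emit_reads_for(pool, counts, config)
    )
  }
  out
}

emit_reads_for <- function(pool, counts, config) {
  total <- sum(counts)
  inserts <- rep(pool$sequence, counts)
  fill_for <- function(adaptor) {
    if (adaptor$n_length == 0) return(rep(adaptor$rna, total))
    fills <- matrix(sample(c("A", "C", "G", "U"),
                           total * adaptor$n_length, replace = TRUE),
                    nrow = total)
    fills <- apply(fills, 1, paste, collapse = "")
    seq <- adaptor$rna
    pre <- stringr::str_sub(seq, 1, adaptor$n_start - 1)
    post <- stringr::str_sub(seq, adaptor$n_start + adaptor$n_length, -1)
    paste0(pre, fills, post)
  }
  reads <- as_dna(paste0(fill_for(config$five_prime), inserts,
                         fill_for(config$three_prime)))
  if (config$error_rate > 0) {
    reads <- map_chr(reads, function(r) {
      b <- strsplit(r, "", fixed = TRUE)[[1]]
      hit <- runif(length(b)) < config$error_rate
      b[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
      paste(b, collapse = "")
    })
  }
  perm <- sample.int(total)
  tibble(read_id = sprintf("sim%07d", seq_len(total)), read = reads[perm])
}

#' Write reads to FASTQ
#'
#' Constant qualities; companion to [simulate_library()]'s `reads` output.
#'
#' @param reads Tibble with `read_id`, `read`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$read))
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$read,
                             "+", qual)), path)
  invisible(path)
}

#' Run the full synthetic bias study
#'
#' Generates a pool, plants efficiencies for the configured single-sequence
#' adaptor pair, simulates a library (plus an independent replicate), then
#' simulates a library under a randomized-adaptor pool (mid-adaptor
#' randomized 3' adaptor and randomized + complementary 5' adaptor built
#' from the same base pair) and normalizes everything, so single-adaptor
#' bias, replicate agreement and the improvement from adaptor pooling can
#' be quantified.
#'
#' @param config A [sim_config()].
#' @param n_variants Adaptor variants in the randomized pool.
#' @return A list with the pool, attribute table, truth/efficiency tables,
#'   and normalized tables `norm_single`, `norm_replicate`, `norm_pooled`.
#' @export
simulate_bias_study <- function(config, n_variants = 16) {
  pool <- generate_pool(config)
  attrs <- attribute_vectors(pool, config$three_prime, config$five_prime,
                             favorability = config$favorability,
                             single_backend = config$single_backend,
                             pair_backend = config$pair_backend)
  eff_single <- context_efficiency(pool, attrs, config, "single")
  lib_single <- simulate_library(pool, eff_single, config, "single")
  lib_replicate <- simulate_library(pool, eff_single, config, "replicate")

  rand_cfg <- config
  rand_cfg$three_prime <- make_randomized_adaptor(config$three_prime, 6,
                                                  "internal", position = 7)
  rand_cfg$five_prime <- make_randomized_adaptor(
    make_c3_adaptor(config$five_prime, config$three_prime), 6,
    "internal", position = 7
  )
  pooled <- adaptor_pool_efficiencies(pool, rand_cfg, n_variants)
  lib_pooled <- simulate_library(pool, pooled$pooled, rand_cfg, "pooled")

  list(
    config = config, pool = pool, attrs = attrs,
    eff_single = eff_single, eff_pooled = pooled$pooled,
    per_variant = pooled$per_variant,
    truth_single = lib_single$truth,
    norm_single = normalize_counts(lib_single$counts, pool),
    norm_replicate = normalize_counts(lib_replicate$counts, pool),
    norm_pooled = normalize_counts(lib_pooled$counts, pool)
  )
}
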