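# Desk-scale simulation checks run with the toy folding backend and small
# pools/read depths so they stay fast; the full-scale study conditions are
# exercised in test-acceptance.R.
toy_cfg <- function(...) {
  sim_config(
    single_backend = single_fold_backend("toy"),
    pair_backend = pair_fold_backend("toy"),
    ...
  )
}

test_that("generated pools are unique, reproducible and honour the mix design", {
  cfg <- toy_cfg(pool_size = 50, seed = 1, total_reads = 1000)
  pool <- generate_pool(cfg)
  expect_equal(nrow(pool), 50)
  expect_equal(anyDuplicated(pool$sequence), 0L)
  expect_true(all(nchar(pool$sequence) >= 20 & nchar(pool$sequence) <= 25))
  expect_identical(pool, generate_pool(cfg))
  expect_false(identical(pool, generate_pool(toy_cfg(pool_size = 50, seed = 2,
                                                     total_reads = 1000))))

  spread <- generate_pool(toy_cfg(pool_size = 50, mix = "spread",
                                  spread_fold = 500, seed = 1,
                                  total_reads = 1000))
  expect_equal(max(spread$concentration) / min(spread$concentration), 500,
               tolerance = 1e-9)
  expect_error(sim_config(pool_size = 0), "pool_size")
})

test_that("planted efficiency is the product of per-slot multipliers", {
  m <- c(unfavorable = 0.15, neutral = 1, favorable = 2)
  attrs <- tibble::tibble(
    id = c("s1", "s2", "s3"),
    fold3_call = c("neutral", "unfavorable", "favorable"),
    fold5_call = c("neutral", "unfavorable", "favorable"),
    cofold3_call = c("neutral", "unfavorable", "neutral"),
    cofold5_call = c("neutral", "unfavorable", "neutral")
  )
  e <- planted_efficiency(attrs, m)
  expect_equal(e$efficiency, c(1, 0.15^4, 4))
  expect_equal(0.15^4, 5.0625e-4)
})

test_that("library simulation is multinomial, deterministic and conservation-exact", {
  cfg <- toy_cfg(pool_size = 30, seed = 5, total_reads = 2e5,
                 sd_log_effect = 0)
  pool <- generate_pool(cfg)
  eff <- tibble::tibble(id = pool$id, efficiency = 1)
  lib <- simulate_library(pool, eff, cfg, "lib")
  expect_equal(sum(lib$counts$count), 2e5)
  # multinomial concentration: all p-hat within 4 binomial SDs
  p <- 1 / 30
  expect_true(all(abs(lib$counts$count / 2e5 - p) <=
                    4 * sqrt(p * (1 - p) / 2e5)))
  # zero efficiency receives zero reads
  eff0 <- eff
  eff0$efficiency[1] <- 0
  expect_equal(simulate_library(pool, eff0, cfg, "lib")$counts$count[1], 0L)
  # determinism per context, independence across contexts
  expect_identical(simulate_library(pool, eff, cfg, "lib")$counts,
                   lib$counts)
  expect_false(identical(simulate_library(pool, eff, cfg, "rep")$counts,
                         lib$counts))
})

test_that("emitted reads run end-to-end back to the exact multinomial counts", {
  cfg <- toy_cfg(pool_size = 20, seed = 9, total_reads = 4000)
  pool <- generate_pool(cfg)
  attrs <- attribute_vectors(pool, cfg$three_prime, cfg$five_prime,
                             single_backend = cfg$single_backend,
                             pair_backend = cfg$pair_backend)
  eff <- ligbias:::context_efficiency(pool, attrs, cfg, "single")
  lib <- simulate_library(pool, eff, cfg, "single", emit_reads = TRUE)
  expect_equal(nrow(lib$reads), 4000)
  # same seed twice: identical reads
  lib2 <- simulate_library(pool, eff, cfg, "single", emit_reads = TRUE)
  expect_identical(lib$reads, lib2$reads)

  trimmed <- trim_reads(lib$reads, cfg$three_prime, cfg$five_prime)
  ct <- annotate_reads(trimmed, pool)
  expect_equal(attr(ct, "unannotated"), 0L)
  expect_equal(ct$count, lib$truth$count)
})

test_that("randomized-region reads still annotate exactly", {
  cfg <- toy_cfg(pool_size = 10, seed = 13, total_reads = 800)
  cfg$three_prime <- make_randomized_adaptor(cfg$three_prime, 6,
                                             "internal", position = 7)
  cfg$five_prime <- make_randomized_adaptor(cfg$five_prime, 6,
                                            "internal", position = 7)
  pool <- generate_pool(cfg)
  eff <- tibble::tibble(id = pool$id, efficiency = 1)
  lib <- simulate_library(pool, eff, cfg, "lib", emit_reads = TRUE)
  trimmed <- trim_reads(lib$reads, cfg$three_prime, cfg$five_prime)
  ct <- annotate_reads(trimmed, pool)
  expect_equal(attr(ct, "unannotated"), 0L)
  expect_equal(ct$count, lib$truth$count)
})

test_that("substitution errors break exact annotation when enabled", {
  cfg <- toy_cfg(pool_size = 10, seed = 13, total_reads = 500,
                 error_rate = 0.05)
  pool <- generate_pool(cfg)
  eff <- tibble::tibble(id = pool$id, efficiency = 1)
  lib <- simulate_library(pool, eff, cfg, "lib", emit_reads = TRUE)
  trimmed <- trim_reads(lib$reads, cfg$three_prime, cfg$five_prime)
  ct <- annotate_reads(trimmed, pool)
  expect_gt(attr(ct, "unannotated") +
              sum(trimmed$untrimmed), 0)
})
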