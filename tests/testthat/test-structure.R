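
test_that("toy backend folds match the worked examples", {
  be <- single_fold_backend("toy")
  expect_equal(fold_single("AAAAAAA", be)$structure, ".......")
  f <- fold_single("GGGGAAAACCCC", be)
  expect_equal(f$structure, "((((....))))")
  expect_equal(f$mfe, oracle_mfe("GGGGAAAACCCC"))
  expect_error(fold_single("", be), "empty|invalid")
  expect_error(fold_single("ACGX", be), "alphabet")
})

test_that("toy backend MFE equals exhaustive enumeration on small single molecules", {
  for (seq in all_seqs_over(6, c("G", "U"))) {
    expect_equal(toy_fold_batch(seq)$mfe, oracle_mfe(seq))
  }
  withr::with_seed(2, {
    seqs <- replicate(25, paste(sample(c("A", "C", "G", "U"),
                                       sample(5:12, 1), replace = TRUE),
                                collapse = ""))
  })
  for (seq in seqs) {
    expect_equal(toy_fold_batch(seq)$mfe, oracle_mfe(seq))
  }
})

test_that("cofold acceptance requires the dimer to beat both monomers", {
  be <- pair_fold_backend("toy")
  no <- cofold_pair("AAAA", "AAAA", backend = be)
  expect_false(no$accepted)
  expect_true(is.na(no$category))

  duplex <- cofold_pair("GGGGG", "CCCCC", backend = be)
  expect_equal(duplex$structure, "(((((&)))))")
  expect_true(duplex$accepted)
  expect_equal(duplex$mfe_ab, oracle_mfe("GGGGGCCCCC", junction = 5))

  # appending a self-complementary hairpin arm to A lowers the monomer
  # energy as much as the dimer energy: never flips acceptance on when B
  # is a homopolymer
  withr::with_seed(9, {
    as <- replicate(12, paste(sample(c("A", "C", "G", "U"), 8,
                                     replace = TRUE), collapse = ""))
  })
  for (a in as) {
    base <- cofold_pair(a, "AAAAAA", backend = be)
    ext <- cofold_pair(paste0(a, "GGGGAAAACCCC"), "AAAAAA", backend = be)
    expect_false(!base$accepted && ext$accepted)
  }
})

test_that("junction classification recovers every attainable state pair", {
  cls <- classify_junction(junction_exemplars$structure)
  expect_equal(cls$state_a, junction_exemplars$state_a)
  expect_equal(cls$state_b, junction_exemplars$state_b)
  expect_false(anyNA(cls$category_id))
  expect_equal(anyDuplicated(cls$category_id), 0L)

  # the mapping table itself is a bijection over all 16 combinations
  map <- junction_category_map()
  expect_equal(nrow(map), 16)
  expect_setequal(map$category_id, 1:16)
  expect_equal(nrow(dplyr::distinct(map, state_a, state_b)), 16)

  expect_error(classify_junction("((&)"), "unbalanced")
  expect_error(classify_junction("...."), "exactly one")
  expect_error(classify_junction("(&)(&)"), "exactly one")
  expect_error(classify_junction("&.."), "junction at the end")
})

test_that("worked junction examples classify as forced by the state rules", {
  expect_equal(
    unlist(classify_junction("(((...&...)))")[1, c("state_a", "state_b")],
           use.names = FALSE),
    c("loop_unpaired", "loop_unpaired")
  )
  expect_equal(
    unlist(classify_junction("(((&)))")[1, c("state_a", "state_b")],
           use.names = FALSE),
    c("paired_inter", "paired_inter")
  )
  expect_equal(
    unlist(classify_junction("((..))&...")[1, c("state_a", "state_b")],
           use.names = FALSE),
    c("paired_intra", "exterior_unpaired")
  )
})

test_that("terminal unpaired-base groups count dots with a no-pairing class", {
  expect_equal(count_terminal_unpaired(".((...))", "five_prime"), "1")
  expect_equal(count_terminal_unpaired("((....))", "five_prime"), "0")
  expect_equal(count_terminal_unpaired("........", "five_prime"), "no pairing")
  expect_equal(count_terminal_unpaired("((....))..", "three_prime"),
               count_terminal_unpaired("..((....))", "five_prime"))
  expect_equal(count_terminal_unpaired("((...)).", "three_prime"), "1")
})

test_that("category distributions and enrichment behave as percentages", {
  co <- tibble::tibble(accepted = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                       category = c(6L, 6L, 6L, 11L, NA))
  d <- category_distribution(co)
  expect_equal(d$pct[d$category == 6], 75)
  expect_equal(d$pct[d$category == 11], 25)
  expect_equal(sum(d$pct), 100, tolerance = 1e-6)
  expect_equal(attr(d, "n_rejected"), 1L)
  expect_error(category_distribution(dplyr::filter(co, !accepted)),
               "no accepted")

  expect_equal(enrichment(30, 20), 0.5)
  expect_equal(enrichment(20, 20), 0)
  expect_true(is.na(enrichment(0, 0)))

  et <- enrichment_table(
    tibble::tibble(group = c("a", "b"), pct = c(30, 70)),
    tibble::tibble(group = c("a", "b", "c"), pct = c(20, 75, 5)),
    by = "group"
  )
  expect_equal(et$enrichment, c(0.5, 70 / 75 - 1, -1))
})

test_that("favorability thresholds follow the -10%/+20%/+5% rules", {
  expect_equal(favorability_call(-0.12, "cofold"), "unfavorable")
  expect_equal(favorability_call(-0.10, "cofold"), "unfavorable")
  expect_equal(favorability_call(0.25, "cofold"), "favorable")
  expect_equal(favorability_call(0.10, "cofold"), "neutral")
  expect_equal(favorability_call(0.10, "contrafold"), "favorable")
  expect_equal(favorability_call(0.04, "contrafold"), "neutral")
})

test_that("attribute vectors combine the four slots and count unfavorables", {
  pool <- random_pool_tbl(6, seed = 21)
  ad <- default_adaptors()
  attrs <- attribute_vectors(
    pool, ad$three_prime, ad$five_prime,
    single_backend = single_fold_backend("toy"),
    pair_backend = pair_fold_backend("toy")
  )
  expect_equal(nrow(attrs), 6)
  calls <- as.matrix(attrs[, c("fold3_call", "fold5_call",
                               "cofold3_call", "cofold5_call")])
  expect_true(all(calls %in% c("favorable", "neutral", "unfavorable")))
  expect_equal(attrs$n_unfavorable,
               as.integer(rowSums(calls == "unfavorable")))
  expect_true(all(attrs$n_unfavorable %in% 0:4))

  # rejected cofolds contribute no structural evidence: neutral slot
  expect_true(all(calls[, "cofold3_call"][!attrs$cofold3_accepted] == "neutral"))

  # uninstantiated randomized adaptors are refused
  rnd <- make_randomized_adaptor(ad$three_prime, 6, "internal", position = 7)
  expect_error(attribute_vectors(pool, rnd, ad$five_prime), "instantiated")
})

test_that("a sequence-specific favorability table changes calls with a warning for unseen groups", {
  tbl <- tibble::tibble(group = c("0", "1"), call = c("unfavorable", "neutral"))
  expect_warning(out <- ligbias:::lookup_fold_call(c("0", "9"), tbl),
                 "treated as neutral")
  expect_equal(out, c("unfavorable", "neutral"))
  # the open-ended top group captures large counts
  full <- default_fold_favorability("three_prime")
  expect_equal(ligbias:::lookup_fold_call("11", full),
               full$call[full$group == "6+"])
})
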