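test_that("complementary-region adaptors reverse-complement the 3' adaptor prefix", {
  a5 <- adaptor_spec("GUUCAGAGUUCUACAGUCCGACGAUC", "five_prime")
  a3 <- adaptor_spec("AGATCGGAAGAGCACACGTCT", "three_prime")
  c3 <- make_c3_adaptor(a5, a3, k = 7)
  expect_equal(nchar(c3$sequence), nchar(a5$sequence))
  expect_equal(stringr::str_sub(c3$sequence, -7, -1), "CCGAUCU")
  # involution: reverse-complementing the suffix recovers the 3' prefix
  expect_equal(reverse_complement(stringr::str_sub(c3$rna, -7, -1)),
               stringr::str_sub(a3$rna, 1, 7))

  k1 <- make_c3_adaptor(a5, adaptor_spec("GAAAAA", "three_prime"), k = 1)
  expect_equal(stringr::str_sub(k1$sequence, -1, -1), "C")
  expect_error(make_c3_adaptor(a5, adaptor_spec("GAAA", "three_prime"), k = 7),
               "exceeds")
})

test_that("randomized adaptors place the N-run and keep a usable distal flank", {
  a3 <- adaptor_spec("AGATCGGAAGAGC", "three_prime")
  mid <- make_randomized_adaptor(a3, 6, "internal", position = 7)
  expect_equal(mid$sequence, "AGATCGNNNNNNGAAGAGC")
  expect_equal(nchar(mid$sequence), nchar(a3$sequence) + 6)
  expect_equal(mid$n_length, 6L)
  expect_equal(mid$n_start, 7L)

  expect_identical(make_randomized_adaptor(a3, 0, "internal", position = 7), a3)

  prox <- make_randomized_adaptor(a3, 6, "end_proximal")
  expect_equal(prox$sequence, paste0("NNNNNN", a3$sequence))

  # a placement leaving a 3-base distal flank is refused
  expect_error(make_randomized_adaptor(a3, 6, "internal", position = 11),
               "fewer than 4")

  # randomized adaptors round-trip through the trimmer for arbitrary fills
  a5 <- make_randomized_adaptor(
    adaptor_spec("GUUCAGAGUUCUACAGUCCGACGAUC", "five_prime"),
    6, "internal", position = 10
  )
  pool <- random_pool_tbl(5, seed = 31)
  withr::with_seed(17, {
    for (i in seq_len(3)) {
      i3 <- instantiate_adaptor(mid)
      i5 <- instantiate_adaptor(a5)
      reads <- as_dna(paste0(i5$rna, pool$sequence, i3$rna))
      tr <- trim_reads(reads, mid, a5)
      expect_equal(tr$insert, pool$sequence)
    }
  })
})

test_that("targeted adaptor design reaches the requested junction states when accessible", {
  be <- pair_fold_backend("toy")
  base <- adaptor_spec("GUUCAGAGUUCUACAGUCCGACGAUC", "five_prime")
  target <- paste0("AAGCUGCCAGUUGAAGAACUGUA", "AGAUCGGAAGAGCACACGUCU")
  des <- design_targeted_adaptor(target, base, backend = be)
  # the postcondition is self-verifying: re-classification of the returned
  # adaptor's cofold reproduces the requested states
  if (des$met) {
    re <- cofold_pair(des$adaptor$rna, target, backend = be)
    expect_true(re$accepted)
    expect_equal(re$state_a, "loop_unpaired")
    expect_equal(re$state_b, "loop_unpaired")
  } else {
    expect_s3_class(des$cofold, "tbl_df")
  }
  expect_equal(nrow(des$candidates), 5)

  # homopolymer target: nothing can pair, the request is unmet
  homo <- design_targeted_adaptor(strrep("A", 30),
                                  adaptor_spec("AAAAAAAAAA", "five_prime"),
                                  backend = be)
  expect_false(homo$met)
  expect_error(design_targeted_adaptor("ACGUACGU", base, backend = be),
               "12 nt")
})
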