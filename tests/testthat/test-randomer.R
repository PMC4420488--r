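test_that("positional frequencies are percentages summing to 100 per position", {
  pfm <- positional_frequency(c("AC", "AG"))
  expect_equal(pfm$freq[pfm$position == 1 & pfm$nucleotide == "A"], 100)
  expect_equal(pfm$freq[pfm$position == 2 & pfm$nucleotide == "C"], 50)
  expect_equal(pfm$freq[pfm$position == 2 & pfm$nucleotide == "G"], 50)

  one <- positional_frequency("A")
  expect_equal(one$freq, c(100, 0, 0, 0))

  four <- positional_frequency(c("A", "C", "G", "U"))
  expect_equal(four$freq, rep(25, 4))

  withr::with_seed(3, {
    seqs <- replicate(40, paste(sample(c("A", "C", "G", "U"), 21,
                                       replace = TRUE), collapse = ""))
  })
  pfm2 <- positional_frequency(seqs)
  sums <- dplyr::summarise(dplyr::group_by(pfm2, position),
                           s = sum(freq))$s
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_equal(attr(pfm2, "n_sequences"), 40)

  expect_error(positional_frequency(c("AC", "ACG")), "ragged")
  expect_error(positional_frequency(character(0)), "no sequences")
})

test_that("input-normalized enrichment is zero iff output matches input", {
  withr::with_seed(5, {
    seqs <- replicate(30, paste(sample(c("A", "C", "G", "U"), 8,
                                       replace = TRUE), collapse = ""))
  })
  pfm <- positional_frequency(seqs)
  enr <- positional_enrichment(pfm, pfm)
  expect_true(all(is.na(enr$enrichment) | abs(enr$enrichment) < 1e-12))

  # hand-computed cells: RNnp = 25 * f_out / f_in
  out <- positional_frequency(c("A", "A", "A", "C", "C", "G", "G", "G", "U", "U"))
  inp <- positional_frequency(c("A", "A", "C", "C", "G", "G", "U", "U", "U", "U"))
  e <- positional_enrichment(out, inp)
  expect_equal(e$rnnp[e$nucleotide == "A"], 25 * 30 / 20)
  expect_equal(e$enrichment[e$nucleotide == "A"], 12.5)
  expect_equal(e$enrichment[e$nucleotide == "C"], 0)

  # swapping output and input flips the sign of every deviation direction
  e_rev <- positional_enrichment(inp, out)
  dir <- sign(e$enrichment)
  dir_rev <- sign(e_rev$enrichment)
  nz <- dir != 0
  expect_true(all(dir[nz] == -dir_rev[nz]))

  # zero input with nonzero output is an explicit NA cell, kept in the table
  out2 <- positional_frequency(c("A", "A"))
  in2 <- positional_frequency(c("C", "C"))
  expect_warning(e2 <- positional_enrichment(out2, in2), "zero input")
  expect_true(is.na(e2$rnnp[e2$nucleotide == "A"]))
  expect_equal(nrow(e2), 4)
})

test_that("randomized regions are extracted from trimmed reads", {
  reads <- c("ACGUACGUAA", "GGGGCCCCUU", "ACG")
  expect_equal(randomized_region(reads, start = 1, length = 4),
               c("ACGU", "GGGG"))
})
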