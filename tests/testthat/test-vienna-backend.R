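test_that("thermodynamic backend returns canonical MFE structures and energies", {
  f <- fold_single("GGGGAAAACCCC")
  expect_equal(f$structure, "((((....))))")
  expect_equal(f$mfe, -5.4, tolerance = 0.2)
  expect_equal(fold_single("AAAAAAA")$structure, ".......")

  batch <- fold_sequences(c("GGGGAAAACCCC", "AAAAAAA", "GGGGAAAACCCC"))
  expect_equal(batch$structure[1], batch$structure[3])
  expect_equal(batch$mfe[2], 0)
})

test_that("pair folding applies the acceptance rule at 25C/Turner-1999", {
  no <- cofold_pair("AAAA", "AAAA")
  expect_false(no$accepted)
  expect_true(is.na(no$category))
  expect_equal(no$structure, "....&....")

  duplex <- cofold_pair("GGGGG", "CCCCC")
  expect_equal(duplex$structure, "(((((&)))))")
  expect_true(duplex$accepted)
  expect_lt(duplex$mfe_ab, min(duplex$mfe_a, duplex$mfe_b))
  expect_equal(duplex$state_a, "paired_inter")
  expect_equal(duplex$state_b, "paired_inter")

  # backend configuration resolves the bundled 1999 parameter file
  expect_true(file.exists(ligbias:::vienna_param_file("turner1999")))
  expect_error(ligbias:::vienna_param_file("not_a_model"), "cannot resolve")

  # monomer energies come from the same settings as the pair fold
  hp <- cofold_pair("GGGGAAAACCCC", "AAAA")
  expect_equal(hp$mfe_a, fold_single("GGGGAAAACCCC",
                                     single_fold_backend(temperature = 25,
                                                         parameters = "turner1999"))$mfe)
})

test_that("cofold batches preserve order and fold DNA input as RNA", {
  pairs <- tibble::tibble(
    seq_a = c("GGGGG", "AAAA", "AGATCGG"),
    seq_b = c("CCCCC", "AAAA", "CCGATCT")
  )
  out <- cofold_pairs(pairs)
  expect_equal(nrow(out), 3)
  expect_equal(out$seq_a[3], "AGAUCGG")
  expect_true(out$accepted[1])
  expect_false(out$accepted[2])
  expect_true(stringr::str_detect(out$structure[3], "&"))
})
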