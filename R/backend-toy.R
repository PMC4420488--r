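# Self-contained folding backend: minimum-energy non-crossing secondary
# structure under a simple pair-energy model (G:C -3, A:U -2, G:U -1
# kcal/mol, no stacking terms), computed by interval dynamic programming.
# Hairpin loops need at least 3 unpaired bases except across the junction of
# a two-molecule fold, where the "loop" is the physical gap between the
# molecules and any size is allowed. Useful for dependency-free runs and as
# a fully enumerable model for small-case validation; energies are not
# comparable to Turner-model energies.

toy_energy_matrix <- function() {
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                       c("A", "C", "G", "U")))
  m["G", "C"] <- m["C", "G"] <- -3
  m["A", "U"] <- m["U", "A"] <- -2
  m["G", "U"] <- m["U", "G"] <- -1
  m
}

# junction: number of bases belonging to the first molecule, or NA for a
# single-molecule fold. Returns list(structure, mfe).
toy_mfe <- function(sequence, junction = NA_integer_) {
  enc <- match(strsplit(sequence, "", fixed = TRUE)[[1]], c("A", "C", "G", "U"))
  if (length(enc) == 0) abort("empty sequence")
  if (anyNA(enc)) abort(sprintf("invalid RNA sequence '%s'", sequence))
  n <- length(enc)
  em <- toy_energy_matrix()
  jx <- if (is.na(junction)) -1L else as.integer(junction)
  # E[i+1, j+1] = minimum energy of interval i..j; zero-width intervals = 0
  E <- matrix(0, n + 2, n + 2)
  if (n >= 2) {
    for (len in 2:n) {
      for (i in seq_len(n - len + 1)) {
        j <- i + len - 1
        ks <- (i + 1):j
        e <- em[enc[i], enc[ks]]
        ok <- e < 0 & ((ks - i - 1) >= 3 | (i <= jx & ks > jx))
        best <- E[i + 2, j + 1] # i unpaired
        if (any(ok)) {
          ks <- ks[ok]
          cand <- e[ok] + E[i + 2, ks] + E[cbind(ks + 2, j + 1)]
          best <- min(best, cand)
        }
        E[i + 1, j + 1] <- best
      }
    }
  }
  energy <- function(i, j) if (j < i) 0 else E[i + 1, j + 1]
  struct <- rep(".", n)
  # deterministic traceback: prefer leaving i unpaired, then smallest partner
  stack <- list(c(1L, n))
  while (length(stack) > 0) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i < j) {
      if (energy(i, j) == energy(i + 1, j)) {
        i <- i + 1L
        next
      }
      for (k in (i + 1):j) {
        e <- em[enc[i], enc[k]]
        if (e < 0 && ((k - i - 1) >= 3 || (i <= jx && k > jx)) &&
            energy(i, j) == e + energy(i + 1, k - 1) + energy(k + 1, j)) {
          struct[i] <- "("
          struct[k] <- ")"
          if (k + 1 <= j) stack[[length(stack) + 1]] <- c(k + 1L, j)
          j <- k - 1L
          i <- i + 1L
          break
        }
      }
    }
  }
  list(structure = paste(struct, collapse = ""), mfe = energy(1, n))
}

toy_fold_batch <- function(sequences) {
  res <- map(sequences, toy_mfe)
  tibble(structure = map_chr(res, "structure"), mfe = map_dbl(res, "mfe"))
}

toy_cofold_batch <- function(a, b) {
  res <- map2(a, b, function(x, y) toy_mfe(paste0(x, y), junction = nchar(x)))
  structure_dual <- map2_chr(res, nchar(a), function(r, la) {
    paste0(stringr::str_sub(r$structure, 1, la), "&",
           stringr::str_sub(r$structure, la + 1, -1))
  })
  tibble(structure = structure_dual, mfe = map_dbl(res, "mfe"))
}
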