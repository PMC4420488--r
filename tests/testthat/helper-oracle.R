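# Independent oracles and fixture builders used across the test files.

# Exhaustive minimum over all non-crossing structures via top-down interval
# recursion (memoised), written against the same pair-energy model as the
# package's toy backend but independently of its bottom-up DP/traceback.
oracle_mfe <- function(sequence, junction = NA_integer_) {
  code <- match(strsplit(sequence, "", fixed = TRUE)[[1]], c("A", "C", "G", "U"))
  em <- matrix(0, 4, 4)
  em[3, 2] <- em[2, 3] <- -3
  em[1, 4] <- em[4, 1] <- -2
  em[3, 4] <- em[4, 3] <- -1
  n <- length(code)
  jx <- if (is.na(junction)) -1L else junction
  memo <- matrix(NA_real_, n, n)
  rec <- function(i, j) {
    if (i >= j) return(0)
    if (!is.na(memo[i, j])) return(memo[i, j])
    best <- rec(i + 1, j)
    for (k in (i + 1):j) {
      p <- em[code[i], code[k]]
      if (p < 0 && ((k - i - 1) >= 3 || (i <= jx && k > jx))) {
        cand <- p + rec(i + 1, k - 1) + rec(k + 1, j)
        if (cand < best) best <- cand
      }
    }
    memo[i, j] <<- best
    best
  }
  rec(1, n)
}

all_seqs_over <- function(len, alphabet) {
  do.call(paste0, expand.grid(rep(list(alphabet), len),
                              stringsAsFactors = FALSE))
}

# Two-tailed Mann-Whitney p by complete enumeration of group assignments.
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(b) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

random_pool_tbl <- function(n, len = c(20, 25), seed = 1) {
  withr::with_seed(seed, {
    seqs <- unique(replicate(3 * n, paste(
      sample(c("A", "C", "G", "U"), sample(seq(len[1], len[2]), 1),
             replace = TRUE), collapse = "")))
    reference_pool(stats::setNames(seqs[seq_len(n)],
                                   sprintf("p%03d", seq_len(n))))
  })
}

write_temp_fasta <- function(seqs, ids = names(seqs)) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(as.vector(rbind(paste0(">", ids), unname(seqs))), path)
  path
}

# Exemplar dual dot-brackets for every geometrically attainable junction
# state pair. Four of the 16 combinations cannot occur in well-formed
# notation: an unpaired junction base can only sit inside a loop if a pair
# spans the junction above it, and such a pair encloses (or is) the other
# junction base too, so exterior/loop and exterior/inter mixtures across
# the junction are impossible. This matches the observation that some
# categories never acquire representatives.
junction_exemplars <- tibble::tribble(
  ~structure,    ~state_a,            ~state_b,
  ".&.",         "exterior_unpaired", "exterior_unpaired",
  ".&()",        "exterior_unpaired", "paired_intra",
  "(.&.)",       "loop_unpaired",     "loop_unpaired",
  "(.&().)",     "loop_unpaired",     "paired_intra",
  "((.&))..",    "loop_unpaired",     "paired_inter",
  "()&.",        "paired_intra",      "exterior_unpaired",
  "(()&.)",      "paired_intra",      "loop_unpaired",
  "()&()",       "paired_intra",      "paired_intra",
  "(()&)",       "paired_intra",      "paired_inter",
  "(&.)",        "paired_inter",      "loop_unpaired",
  "(&())",       "paired_inter",      "paired_intra",
  "(&)",         "paired_inter",      "paired_inter"
)
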