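# Shared fixtures and independent oracles. Oracles are deliberately naive
# (base-by-base walks, full enumeration, per-locus loops) and never call the
# implementation paths they check.

toy_map <- function() {
  break_map(tibble::tibble(
    contig = "chr1",
    pos = c(100L, 103L, 200L, 500L, 503L),
    strand = c("watson", "crick", "watson", "watson", "crick"),
    count = c(5L, 5L, 9L, 12L, 10L)
  ))
}

# Random CIGAR over M/I/D/S with M runs guaranteed at the ends (as emitted
# by real aligners after soft clips).
random_cigar <- function() {
  n_ops <- sample(1:6, 1)
  ops <- sample(c("M", "I", "D"), n_ops, replace = TRUE, prob = c(.6, .2, .2))
  ops[c(1, n_ops)] <- "M"
  lens <- sample(1:40, n_ops, replace = TRUE)
  if (runif(1) < 0.3) {
    ops <- c("S", ops)
    lens <- c(sample(1:5, 1), lens)
  }
  paste0(lens, ops, collapse = "")
}

# Brute-force 5' caller: walks the alignment base by base over the
# reference, tracking every reference position the read aligns to.
oracle_five_prime <- function(leftmost, cigar, is_reverse) {
  m <- stringr::str_match_all(cigar, "(\\d+)([A-Z])")[[1]]
  ref <- leftmost
  touched <- integer(0)
  for (i in seq_len(nrow(m))) {
    len <- as.integer(m[i, 2])
    op <- m[i, 3]
    if (op %in% c("M", "D")) {
      touched <- c(touched, ref:(ref + len - 1))
      ref <- ref + len
    }
    # I and S consume no reference
  }
  if (is_reverse) max(touched) else min(touched)
}

# Minimum-likelihood two-sided p by full enumeration of Binomial(n, 1/2).
oracle_exact_p <- function(w, c) {
  n <- w + c
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[w + 1] * (1 + 1e-12)])
}

# Deterministic 10-kb toy genome for sequence work.
fixture_genome <- function() {
  ccbreakr::make_genome(10000, gc = 0.5, seed = 424, name = "chrF")
}
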