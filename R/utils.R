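# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` evaluates in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Pick the per-position signal column of a track-like tibble.
signal_col <- function(x) {
  for (cand in c("hpm", "value", "count")) {
    if (cand %in% names(x)) {
      return(cand)
    }
  }
  abort("no signal column found (expected one of 'hpm', 'value', 'count')")
}

# Coerce a genome to a named character vector of contig sequences.
genome_as_character <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- names(genome)
    return(out)
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) {
      abort("character genome must be a named vector of contig sequences")
    }
    return(genome)
  }
  abort("genome must be a Biostrings::DNAStringSet or a named character vector")
}

# Named integer vector of contig lengths from a genome object or a
# lengths vector passed through unchanged.
contig_lengths <- function(genome) {
  if (is.numeric(genome) && !is.null(names(genome))) {
    return(genome)
  }
  g <- genome_as_character(genome)
  setNames(nchar(g), names(g))
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
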