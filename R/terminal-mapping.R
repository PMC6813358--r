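#' Classify a read pair by its SAM flag combination
#'
#' Only concordant, fully aligned pairs carry break information: flags
#' (99, 147) are a Watson pair (Read-1 on the plus strand), flags (83, 163)
#' a Crick pair (Read-1 on the minus strand). Every other combination —
#' unmapped mates, discordant or secondary alignments — is rejected.
#'
#' @param flag_read1,flag_read2 Integer SAM flags of the two mates, in either
#'   order. Vectorised.
#' @return Character vector: `"watson_pair"`, `"crick_pair"` or `"reject"`.
#' @export
#' @examples
#' classify_pair(99, 147)  # watson_pair
#' classify_pair(163, 83)  # crick_pair (order-symmetric)
#' classify_pair(77, 141)  # reject
classify_pair <- function(flag_read1, flag_read2) {
  lo <- pmin(flag_read1, flag_read2)
  hi <- pmax(flag_read1, flag_read2)
  dplyr::case_when(
    lo == 99 & hi == 147 ~ "watson_pair",
    lo == 83 & hi == 163 ~ "crick_pair",
    TRUE ~ "reject"
  )
}

#' Build a break map from paired-end alignment records
#'
#' The central mapping operation: converts a stream of paired alignment
#' records into a strand-specific, nucleotide-resolution map of protein-linked
#' 5' termini. Read-1's 5' end is the protein-linked terminus (the library
#' design ligates a distinguishable adapter to the cleaved end); Read-2 marks
#' the sonicated end and is never emitted as a break coordinate.
#'
#' A pair is counted once, at Read-1's called 5' coordinate on its strand,
#' unless it is rejected because (i) the flag combination is not 99/147 or
#' 83/163 or the mates map to different contigs; (ii) either mate's MAPQ is
#' below `mapq_min`; or (iii) the 5'-terminal mismatch run (see
#' [five_prime_mismatch_run()]) exceeds `max_end_mismatch` on Read-1
#' (`mode = "single"`) or on either read (`mode = "double"`).
#'
#' @param records A tibble of alignment records with columns `qname`, `flag`,
#'   `rname`, `pos`, `mapq`, `cigar` and `md` (as from [read_alignments()]).
#'   Every query name must occur exactly twice.
#' @param mode Library mode: `"single"` (only Read-1's 5' end is
#'   protein-linked) or `"double"` (both ends informative for filtering).
#' @param mapq_min Minimum mapping quality applied to both mates. The source
#'   protocol used 0 for yeast and 10 for human alignments.
#' @param max_end_mismatch Longest tolerated 5'-terminal mismatch run;
#'   default 1, i.e. runs of 2 or more disqualify the pair.
#' @param genome_id,sample_id Passed to [break_map()].
#' @return A list with elements `map` (a [break_map()]) and `stats` (a
#'   one-row tibble partitioning every input pair into `pairs_counted`,
#'   `pairs_flag_rejected`, `pairs_mapq_rejected`, `pairs_ambiguous_end`).
#' @export
map_read_pairs <- function(records, mode = c("single", "double"),
                           mapq_min = 0, max_end_mismatch = 1,
                           genome_id = NA_character_,
                           sample_id = NA_character_) {
  mode <- match.arg(mode)
  records <- as_tibble(records)
  if (!"md" %in% names(records)) {
    records$md <- NA_character_
  }
  tab <- table(records$qname)
  if (any(tab != 2)) {
    bad <- names(tab)[tab != 2]
    abort(paste0(
      "unpaired alignment record(s) for query name(s): ",
      paste(head(bad, 5), collapse = ", "),
      if (length(bad) > 5) " ..." else ""
    ))
  }
  # one row per pair; read-1 identified by flag bit 0x40
  records <- records |>
    mutate(.r1 = bitwAnd(.data$flag, 64L) > 0L) |>
    arrange(.data$qname, dplyr::desc(.data$.r1))
  r1 <- records |> filter(!duplicated(.data$qname))
  r2 <- records |> filter(duplicated(.data$qname))
  r2 <- r2[match(r1$qname, r2$qname), ]

  cls <- classify_pair(r1$flag, r2$flag)
  cls[r1$rname != r2$rname] <- "reject"
  flag_rej <- cls == "reject"
  mapq_rej <- !flag_rej & (r1$mapq < mapq_min | r2$mapq < mapq_min)

  kept <- !flag_rej & !mapq_rej
  ambiguous <- logical(length(cls))
  if (any(kept)) {
    rev1 <- cls[kept] == "crick_pair" # Read-1 minus iff Crick pair
    run1 <- five_prime_mismatch_run(r1$md[kept], r1$cigar[kept], rev1)
    amb <- run1 > max_end_mismatch
    if (mode == "double") {
      run2 <- five_prime_mismatch_run(r2$md[kept], r2$cigar[kept], !rev1)
      amb <- amb | run2 > max_end_mismatch
    }
    ambiguous[kept] <- amb
  }
  counted <- kept & !ambiguous

  stats <- tibble(
    pairs_seen = length(cls),
    pairs_flag_rejected = sum(flag_rej),
    pairs_mapq_rejected = sum(mapq_rej),
    pairs_ambiguous_end = sum(ambiguous),
    pairs_counted = sum(counted)
  )

  if (any(counted)) {
    called <- call_five_prime(
      r1$pos[counted], r1$cigar[counted], cls[counted] == "crick_pair"
    )
    hits <- tibble(
      contig = r1$rname[counted],
      pos = called$pos,
      strand = called$strand
    ) |>
      count(.data$contig, .data$pos, .data$strand, name = "count")
  } else {
    hits <- tibble(
      contig = character(), pos = integer(),
      strand = character(), count = integer()
    )
  }
  map <- break_map(hits,
    total_mapped_pairs = stats$pairs_counted,
    genome_id = genome_id, sample_id = sample_id
  )
  list(map = map, stats = stats)
}

#' Mask or restrict a break map with a set of intervals
#'
#' Used to drop repetitive or artefact-prone regions (rDNA, telomeres, LTRs,
#' ultra-high-signal regions) before analysis. Intervals are 1-based
#' half-open: a position `p` is inside `[start, end)` when
#' `start <= p < end`. `total_mapped_pairs` is deliberately left unchanged so
#' that hits-per-million normalisation still refers to the library size.
#'
#' @param map A [break_map()] (or any track tibble with `contig` and `pos`).
#' @param mask A tibble of intervals with columns `contig`, `start`, `end`.
#' @param mode `"exclude"` drops positions inside any interval; `"include"`
#'   keeps only those.
#' @return A filtered object of the same class as `map`.
#' @export
apply_region_mask <- function(map, mask, mode = c("exclude", "include")) {
  mode <- match.arg(mode)
  mask <- as_tibble(mask)
  if (nrow(mask) > 0 && any(mask$end < mask$start)) {
    abort("malformed mask interval: end < start")
  }
  inside <- rep(FALSE, nrow(map))
  if (nrow(mask) > 0) {
    for (i in seq_len(nrow(mask))) {
      inside <- inside |
        (map$contig == mask$contig[i] &
           map$pos >= mask$start[i] & map$pos < mask$end[i])
    }
  }
  keep <- if (mode == "exclude") !inside else inside
  out <- map[keep, , drop = FALSE]
  if (inherits(map, "break_map")) {
    out <- rewrap_break_map(out, map)
  }
  out
}
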