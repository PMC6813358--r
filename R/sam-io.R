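# Alignment record I/O. SAM text is parsed in-package because the fields the
# mapper consumes (flag, leftmost coordinate, MAPQ, CIGAR, MD:Z) are exactly
# the substance of terminal mapping; BAM input is delegated to Rsamtools.

#' Read paired-end alignment records
#'
#' Reads a SAM (text) or BAM file into the flat record tibble consumed by
#' [map_read_pairs()]. Records are paired by query name; a query name seen an
#' odd number of times (an orphan mate) is a hard error, reported with the
#' offending names. Input sort order is irrelevant.
#'
#' @param path Path to a `.sam` (text) or `.bam` file.
#' @return A tibble with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `md`, arranged with mates adjacent.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("alignment file not found: ", path))
  }
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    recs <- read_bam_records(path)
  } else {
    recs <- read_sam_records(path)
  }
  tab <- table(recs$qname)
  orphan <- names(tab)[tab %% 2L != 0L]
  if (length(orphan) > 0) {
    abort(paste0(
      "orphan mate(s) at end of stream for query name(s): ",
      paste(head(orphan, 5), collapse = ", "),
      if (length(orphan) > 5) " ..." else ""
    ))
  }
  recs |> arrange(.data$qname, bitwAnd(.data$flag, 64L) == 0L)
}

read_sam_records <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(tibble(
      qname = character(), flag = integer(), rname = character(),
      pos = integer(), mapq = integer(), cigar = character(),
      md = character()
    ))
  }
  m <- stringr::str_match(
    lines,
    "^([^\t]+)\t(\\d+)\t([^\t]+)\t(\\d+)\t(\\d+)\t([^\t]+)\t"
  )
  if (anyNA(m[, 1])) {
    bad <- which(is.na(m[, 1]))[1]
    abort(paste0("malformed SAM record at data line ", bad))
  }
  md <- stringr::str_match(lines, "\tMD:Z:([^\t]+)")[, 2]
  tibble(
    qname = m[, 2],
    flag = as.integer(m[, 3]),
    rname = m[, 4],
    pos = as.integer(m[, 5]),
    mapq = as.integer(m[, 6]),
    cigar = m[, 7],
    md = md
  )
}

read_bam_records <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading BAM requires the Rsamtools package")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "MD"
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  tibble(
    qname = b$qname,
    flag = as.integer(b$flag),
    rname = as.character(b$rname),
    pos = as.integer(b$pos),
    mapq = as.integer(b$mapq),
    cigar = b$cigar,
    md = as.character(b$tag$MD)
  )
}

#' Write alignment records as a SAM text file
#'
#' Emits a minimal, coordinate-sorted SAM file with `@SQ` header lines taken
#' from `genome`. Used by the read simulator; records need columns `qname`,
#' `flag`, `rname`, `pos`, `mapq`, `cigar`, `seq` and optionally `md`.
#'
#' @param records Alignment record tibble.
#' @param genome Genome the records refer to (for `@SQ` lengths), or a named
#'   vector of contig lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, genome, path) {
  lens <- contig_lengths(genome)
  records <- as_tibble(records)
  # mate coordinates for PNEXT/TLEN
  mate_pos <- records |>
    group_by(.data$qname) |>
    mutate(pnext = rev(.data$pos)) |>
    ungroup() |>
    pull(.data$pnext)
  records$pnext <- mate_pos
  records <- records |> arrange(match(.data$rname, names(lens)), .data$pos)
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens))
  )
  md_field <- if ("md" %in% names(records)) {
    if_else(is.na(records$md), "", paste0("\tMD:Z:", records$md))
  } else {
    ""
  }
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t0\t%s\t%s%s",
    records$qname, records$flag, records$rname, records$pos,
    records$mapq, records$cigar, records$pnext,
    records$seq, strrep("I", nchar(records$seq)), md_field
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}
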