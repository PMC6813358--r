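# CIGAR and MD:Z parsing: the coordinate-calling arithmetic at the heart of
# terminal mapping. Only M, I, D and S operations are supported; anything else
# (chimeric/supplementary alignment artefacts) is a hard error.

parse_cigar <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([A-Z=])")
  purrr::map2(m, cigar, function(ops, cg) {
    if (nrow(ops) == 0 || paste0(ops[, 1], collapse = "") != cg) {
      abort(paste0("malformed CIGAR string: '", cg, "'"))
    }
    bad <- setdiff(ops[, 3], c("M", "I", "D", "S"))
    if (length(bad) > 0) {
      abort(paste0("unsupported CIGAR operation '", bad[1], "' in '", cg, "'"))
    }
    list(len = as.integer(ops[, 2]), op = ops[, 3])
  })
}

#' Reference span of a CIGAR string
#'
#' Number of reference bases covered by an alignment, scored with weights
#' M = 1, D = 1, I = 0, S = 0. Insertions in the read are ignored so that
#' called coordinates stay accurate to the reference; soft-clipped bases do
#' not align and contribute nothing.
#'
#' @param cigar Character vector of CIGAR strings (operations M, I, D, S).
#' @return Integer vector of reference spans.
#' @export
#' @examples
#' reference_span("75M")            # 75
#' reference_span("35M2D10M3I30M")  # 77
reference_span <- function(cigar) {
  uniq <- !duplicated(cigar)
  ops <- parse_cigar(cigar[uniq])
  span_u <- vapply(ops, function(o) sum(o$len[o$op %in% c("M", "D")]),
                   integer(1))
  span_u[match(cigar, cigar[uniq])]
}

# Length of the soft clip at the reference-left (five_prime = "left") or
# reference-right end of the CIGAR.
soft_clip_len <- function(cigar, end = c("left", "right")) {
  end <- match.arg(end)
  ops <- parse_cigar(cigar)
  vapply(ops, function(o) {
    k <- if (end == "left") 1L else length(o$op)
    if (o$op[k] == "S") o$len[k] else 0L
  }, integer(1))
}

#' Call the 5'-terminal reference coordinate of an aligned read
#'
#' SAM records give the 1-based leftmost aligned coordinate. For a
#' plus-strand (Watson) read the leftmost base is already the 5' terminus.
#' For a minus-strand (Crick) read the leftmost base is the 3' end, so the
#' 5' coordinate is `leftmost + reference_span(cigar) - 1`.
#'
#' @param leftmost Integer vector of 1-based leftmost coordinates.
#' @param cigar Character vector of CIGAR strings.
#' @param is_reverse Logical vector; `TRUE` for minus-strand reads.
#' @return A tibble with columns `pos` (called 5' coordinate) and `strand`
#'   (`"watson"` for plus-strand reads, `"crick"` for minus).
#' @export
#' @examples
#' call_five_prime(10200, "35M2D10M3I30M", TRUE)  # pos 10276
#' call_five_prime(10200, "75M", TRUE)            # pos 10274
call_five_prime <- function(leftmost, cigar, is_reverse) {
  n <- max(length(leftmost), length(cigar), length(is_reverse))
  leftmost <- rep_len(as.integer(leftmost), n)
  cigar <- rep_len(cigar, n)
  is_reverse <- rep_len(is_reverse, n)
  span <- reference_span(cigar)
  tibble(
    pos = if_else(is_reverse, leftmost + span - 1L, leftmost),
    strand = if_else(is_reverse, "crick", "watson")
  )
}

# Tokenise one MD:Z value into a walk of per-reference-position states:
# "m" (match), "x" (mismatch), "d" (deleted from read). Zero-length match
# runs are dropped. Returns a character vector, reference-left to -right.
md_walk <- function(md) {
  toks <- stringr::str_match_all(
    md, "(\\d+)|(\\^[ACGTN]+)|([ACGTN])"
  )[[1]]
  if (nrow(toks) == 0 || paste0(toks[, 1], collapse = "") != md) {
    bad <- sub(paste0("^", gsub(
      "([][{}()+*^$|\\\\?.])", "\\\\\\1",
      paste0(toks[, 1], collapse = "")
    )), "", md)
    abort(paste0("malformed MD:Z tag '", md, "' at '", bad, "'"))
  }
  states <- lapply(seq_len(nrow(toks)), function(i) {
    tok <- toks[i, 1]
    if (grepl("^\\d+$", tok)) {
      rep("m", as.integer(tok))
    } else if (startsWith(tok, "^")) {
      rep("d", nchar(tok) - 1L)
    } else {
      "x"
    }
  })
  unlist(states, use.names = FALSE)
}

#' Length of the mismatch run at a read's 5' terminus
#'
#' Walks the MD:Z tag reference-left to reference-right and counts consecutive
#' mismatched or deleted positions at the read's 5' end. MD runs along the
#' reference, which for a minus-strand read is the read's 3'-to-5' direction,
#' so the 5' run of a minus read is measured from the right end of the walk.
#' Soft-clipped bases at the 5' end are positionally uninformative and count
#' toward the run.
#'
#' A run of two or more flags the protein-linked end as ambiguous (see
#' [map_read_pairs()]).
#'
#' @param md Character vector of MD:Z tag values (`NA` treated as all-match).
#' @param cigar Matching CIGAR strings, used for terminal soft clips.
#' @param is_reverse Logical; `TRUE` for minus-strand reads.
#' @return Integer vector of 5'-terminal mismatch-run lengths.
#' @export
#' @examples
#' five_prime_mismatch_run("0T0C25A5^T10", "75M", FALSE)  # 2
#' five_prime_mismatch_run("75", "75M", FALSE)            # 0
five_prime_mismatch_run <- function(md, cigar, is_reverse) {
  n <- max(length(md), length(cigar), length(is_reverse))
  md <- rep_len(md, n)
  cigar <- rep_len(cigar, n)
  is_reverse <- rep_len(is_reverse, n)
  clip <- integer(n)
  clip[!is_reverse] <- soft_clip_len(cigar[!is_reverse], "left")
  clip[is_reverse] <- soft_clip_len(cigar[is_reverse], "right")
  run_of <- function(md_i, rev_i) {
    if (is.na(md_i)) {
      return(0L)
    }
    walk <- md_walk(md_i)
    if (rev_i) walk <- rev(walk)
    mism <- walk != "m"
    if (all(mism)) length(walk) else which(!mism)[1] - 1L
  }
  # most reads share a handful of MD values (e.g. full-length match), so
  # evaluate the walk once per unique (md, orientation) combination
  key <- paste(md, is_reverse)
  uniq <- !duplicated(key)
  run_u <- mapply(run_of, md[uniq], is_reverse[uniq], USE.NAMES = FALSE)
  runs <- run_u[match(key, key[uniq])]
  clip + as.integer(runs)
}
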