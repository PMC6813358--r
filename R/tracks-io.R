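# Track file formats. Internal coordinates are 1-based inclusive; bedGraph
# files are 0-based half-open — the conversion happens here and only here.

#' Write one strand of a track as bedGraph
#'
#' Emits a 4-column, 0-based half-open bedGraph with one line per nonzero
#' coordinate, in deterministic (contig, position) order. A 1-based position
#' `p` becomes the interval `[p-1, p)`.
#'
#' @param track A `break_map` or `hpm_track` (or any tibble with `contig`,
#'   `pos`, a signal column, and optionally `strand`).
#' @param path Output path.
#' @param strand Which strand to write (`"watson"` or `"crick"`); ignored if
#'   the track has no `strand` column.
#' @param track_line Write a `track type=bedGraph` header line (default TRUE).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = NULL, track_line = TRUE) {
  vc <- signal_col(track)
  x <- as_tibble(track)
  if (!is.null(strand) && "strand" %in% names(x)) {
    x <- x |> filter(.data$strand == !!strand)
  }
  x <- x |> arrange(.data$contig, .data$pos)
  lines <- sprintf("%s\t%d\t%d\t%s", x$contig, x$pos - 1L, x$pos,
                   format(x[[vc]], trim = TRUE, scientific = FALSE))
  if (track_line) {
    nm <- if (is.null(strand)) "track" else strand
    lines <- c(sprintf("track type=bedGraph name=%s", nm), lines)
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a 1-based track tibble
#'
#' Inverse of [write_bedgraph()]: intervals wider than one base are expanded
#' to per-base rows so the result is always nucleotide resolution.
#'
#' @param path bedGraph path.
#' @param strand Optional strand label to attach to every row.
#' @return Tibble with columns `contig`, `pos` (1-based), `value` and, when
#'   `strand` is given, `strand`.
#' @export
read_bedgraph <- function(path, strand = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble(contig = character(), pos = integer(), value = numeric())
  } else {
    m <- stringr::str_split_fixed(lines, "\t", 4)
    out <- tibble(
      contig = m[, 1],
      start0 = as.integer(m[, 2]),
      end0 = as.integer(m[, 3]),
      value = as.numeric(m[, 4])
    ) |>
      mutate(width = .data$end0 - .data$start0) |>
      tidyr::uncount(.data$width, .id = "offset") |>
      mutate(pos = .data$start0 + .data$offset) |>
      select("contig", "pos", "value")
  }
  if (!is.null(strand)) {
    out$strand <- strand
  }
  out
}

#' Write a break map as a compact two-strand TSV
#'
#' One row per occupied coordinate: `contig`, `pos` (1-based), `watson`,
#' `crick`. The companion reader is [read_breaks_tsv()].
#'
#' @param map A [break_map()] or hpm track.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breaks_tsv <- function(map, path) {
  vc <- signal_col(map)
  wide <- as_tibble(map) |>
    select("contig", "pos", "strand", value = dplyr::all_of(vc)) |>
    tidyr::pivot_wider(
      names_from = "strand", values_from = "value", values_fill = 0
    )
  for (s in c("watson", "crick")) {
    if (!s %in% names(wide)) wide[[s]] <- 0
  }
  wide <- wide |>
    select("contig", "pos", "watson", "crick") |>
    arrange(.data$contig, .data$pos)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a two-strand TSV back into a break map
#'
#' @param path Path written by [write_breaks_tsv()].
#' @param total_mapped_pairs Library size to attach; defaults to the sum of
#'   counts.
#' @return A [break_map()].
#' @export
read_breaks_tsv <- function(path, total_mapped_pairs = NULL) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  long <- wide |>
    tidyr::pivot_longer(c("watson", "crick"),
      names_to = "strand", values_to = "count"
    ) |>
    filter(.data$count > 0)
  break_map(long, total_mapped_pairs = total_mapped_pairs)
}

#' Read a BED file of intervals
#'
#' Converts the 0-based half-open BED convention to the package's 1-based
#' half-open mask convention (`[start, end)` against 1-based positions), so
#' the same bases are covered: BED `[s0, e0)` becomes `[s0 + 1, e0 + 1)`.
#' BED6 strand and name/score columns are kept when present.
#'
#' @param path BED path.
#' @return Tibble with `contig`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  m <- stringr::str_split(lines, "\t")
  ncol_min <- min(lengths(m))
  out <- tibble(
    contig = vapply(m, `[`, "", 1),
    start = as.integer(vapply(m, `[`, "", 2)) + 1L,
    end = as.integer(vapply(m, `[`, "", 3)) + 1L
  )
  if (ncol_min >= 4) out$name <- vapply(m, `[`, "", 4)
  if (ncol_min >= 5) out$score <- as.numeric(vapply(m, `[`, "", 5))
  if (ncol_min >= 6) out$strand <- vapply(m, `[`, "", 6)
  out
}
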