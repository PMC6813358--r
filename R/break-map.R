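#' Construct a strand-specific break map
#'
#' A break map is the core container of the package: a sparse, nucleotide
#' resolution record of where protein-linked 5' DNA termini were observed.
#' Each row holds one (contig, position, strand) cell with a positive count of
#' read pairs whose informative 5' end mapped there. Watson is the reference
#' top strand, Crick the bottom strand.
#'
#' @param x A data frame with columns `contig` (character), `pos` (1-based
#'   integer coordinate of the 5'-terminal nucleotide), `strand` (`"watson"`
#'   or `"crick"`) and `count` (positive integer).
#' @param total_mapped_pairs Total accepted read pairs the map was built from;
#'   used for hits-per-million normalisation. Defaults to the sum of counts.
#' @param genome_id,sample_id Optional free-text identifiers.
#' @return A tibble of class `break_map` with attributes
#'   `total_mapped_pairs`, `genome_id` and `sample_id`.
#' @export
#' @examples
#' break_map(tibble::tibble(
#'   contig = "chr1", pos = c(100L, 103L),
#'   strand = c("watson", "crick"), count = c(5L, 4L)
#' ))
break_map <- function(x, total_mapped_pairs = NULL, genome_id = NA_character_,
                      sample_id = NA_character_) {
  x <- as_tibble(x)
  required <- c("contig", "pos", "strand", "count")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("break_map input lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(x$strand %in% c("watson", "crick"))) {
    abort("strand must be 'watson' or 'crick'")
  }
  if (any(x$count <= 0)) {
    abort("all break-map counts must be positive")
  }
  if (any(x$pos < 1)) {
    abort("coordinates are 1-based: pos must be >= 1")
  }
  x <- x |>
    group_by(.data$contig, .data$strand, .data$pos) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$contig, .data$pos, .data$strand)
  total <- total_mapped_pairs %||% sum(x$count)
  if (total < sum(x$count)) {
    abort("total_mapped_pairs cannot be smaller than the sum of counts")
  }
  structure(x,
    class = c("break_map", class(x)),
    total_mapped_pairs = as.numeric(total),
    genome_id = genome_id,
    sample_id = sample_id
  )
}

#' @export
print.break_map <- function(x, ...) {
  cat(sprintf(
    "<break_map> %d positions, %s hits, %s mapped pairs\n",
    nrow(x), format(sum(x$count), big.mark = ","),
    format(attr(x, "total_mapped_pairs"), big.mark = ",")
  ))
  NextMethod()
}

# Rebuild break_map attributes after a dplyr verb stripped them.
rewrap_break_map <- function(x, template, total_mapped_pairs = NULL) {
  break_map(x,
    total_mapped_pairs = total_mapped_pairs %||%
      attr(template, "total_mapped_pairs"),
    genome_id = attr(template, "genome_id"),
    sample_id = attr(template, "sample_id")
  )
}

#' Total mapped read pairs recorded on a map or track
#'
#' @param x A `break_map` or `hpm_track`.
#' @return A single number.
#' @export
total_mapped_pairs <- function(x) {
  attr(x, "total_mapped_pairs")
}
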