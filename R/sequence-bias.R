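# Dyad-centred, signal-weighted nucleotide composition around cleavage
# sites. Weighting each site by its normalised Watson/Crick signal samples
# the flanking DNA in proportion to the strand disparity of interest while
# removing between-site coverage differences.

#' Equalise per-site totals without changing the Watson:Crick ratio
#'
#' Rescales each site's `(w, c)` counts to a common total (default 100), so
#' downstream composition profiles are not dominated by strong sites:
#' W9:C1 becomes W90:C10 and W30:C10 becomes W75:C25.
#'
#' @param sites Tibble with `w` and `c` columns (e.g. from
#'   [pair_offset_sites()] or `tidy()` of a [fractionate()] result).
#' @param common_total Target per-site total (default 100).
#' @return `sites` with added `w_weight` and `c_weight` columns.
#' @export
#' @examples
#' normalize_site_weights(tibble::tibble(w = 30, c = 10))
normalize_site_weights <- function(sites, common_total = 100) {
  sites <- as_tibble(sites)
  if (any(sites$w + sites$c <= 0)) {
    abort("cannot normalise a site with zero total signal")
  }
  sites |>
    mutate(
      w_weight = common_total * .data$w / (.data$w + .data$c),
      c_weight = common_total * .data$c / (.data$w + .data$c)
    )
}

#' Dyad-axis coordinate of an offset site
#'
#' The dyad axis is the two-fold symmetry centre of the cleavage site: the
#' midpoint of the central two base pairs of the 5' overhang, a half-integer
#' reference coordinate. For a Watson 5' terminus at `w` and an `n`-nt
#' overhang the dyad is `w + (n - 1) / 2`. Sites with signal on only one
#' strand get an inferred dyad at the same relative position (the
#' coordinates of an offset site already fix it).
#'
#' @param sites An `offset_sites` tibble (needs `watson_pos`).
#' @param overhang Overhang length in nt (default 4, Top2-like).
#' @return `sites` with an added half-integer `dyad` column.
#' @export
#' @examples
#' dyad_axis(tibble::tibble(watson_pos = 100), overhang = 4) # dyad 101.5
dyad_axis <- function(sites, overhang = 4) {
  if (overhang < 1) {
    abort("overhang must be >= 1")
  }
  sites <- as_tibble(sites)
  sites |> mutate(dyad = .data$watson_pos + (overhang - 1) / 2)
}

#' Signal-weighted nucleotide composition around dyad axes
#'
#' For every site, the top-strand sequence 5'->3' around the dyad is
#' accumulated with the site's Watson weight, and the bottom-strand sequence
#' 5'->3' (the reverse complement, i.e. the same window read in mirrored
#' offsets) with the Crick weight. Position labels are signed offsets from
#' the dyad with no zero: -1/+1 are the central two bases of the overhang,
#' and for a 4-nt overhang the base 5' of the Watson scissile phosphate sits
#' at -3. Values are reported in top-strand-equivalent orientation; because
#' both strand readings are pooled, a palindromic preference appears
#' rotationally symmetric about the dyad.
#'
#' Ambiguous bases (N) are masked from both numerator and denominator at the
#' affected position. Sites whose window leaves the contig are dropped with
#' a message.
#'
#' @param sites Tibble with `contig`, `dyad`, `w_weight`, `c_weight`
#'   (see [normalize_site_weights()] and [dyad_axis()]).
#' @param genome `Biostrings::DNAStringSet` or named character vector.
#' @param flank Half-window in bp (default 20; positions -flank..+flank).
#' @return A `composition_profile` tibble: `position`, `base`, `fraction`,
#'   `weight` (effective weight at that position).
#' @export
weighted_composition <- function(sites, genome, flank = 20) {
  sites <- as_tibble(sites)
  need <- c("contig", "dyad", "w_weight", "c_weight")
  miss <- setdiff(need, names(sites))
  if (length(miss) > 0) {
    abort(paste0("sites lack column(s): ", paste(miss, collapse = ", ")))
  }
  g <- genome_as_character(genome)
  lens <- nchar(g)
  width <- 2L * flank
  start <- sites$dyad - flank + 0.5 # first base of the window
  ok <- start >= 1 & start + width - 1 <= lens[sites$contig]
  if (any(!ok)) {
    inform(sprintf("dropped %d site(s) within %d bp of a contig end",
                   sum(!ok), flank))
  }
  sites <- sites[ok, , drop = FALSE]
  start <- start[ok]
  if (nrow(sites) == 0) {
    abort("no site window fits inside the genome")
  }
  seqs <- substring(g[sites$contig], start, start + width - 1)
  top <- do.call(rbind, strsplit(seqs, ""))
  bot <- do.call(rbind, strsplit(revcomp_chr(seqs), ""))
  counts <- matrix(0, nrow = 4, ncol = width,
                   dimnames = list(DNA_BASES, NULL))
  for (b in DNA_BASES) {
    counts[b, ] <- colSums((top == b) * sites$w_weight) +
      colSums((bot == b) * sites$c_weight)
  }
  denom <- colSums(counts)
  positions <- c(-flank:-1, 1:flank)
  tibble(
    position = rep(positions, each = 4),
    base = rep(DNA_BASES, times = width),
    fraction = as.vector(sweep(counts, 2, denom, "/")),
    weight = rep(denom, each = 4)
  ) |>
    (\(x) structure(x, class = c("composition_profile", class(x))))()
}

#' Goodness-of-fit test of composition against a background
#'
#' One-sample chi-squared test per position: observed per-base "counts" are
#' the effective weights times the base fractions, expected counts come from
#' the background composition; 3 degrees of freedom.
#'
#' @param profile A `composition_profile`.
#' @param background Named fractions for A, C, G, T (default uniform).
#' @return Tibble `position`, `statistic`, `df`, `p_value`.
#' @export
chi_squared_bias <- function(profile,
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25)) {
  background <- background[DNA_BASES]
  prof <- as_tibble(profile)
  out <- prof |>
    group_by(.data$position) |>
    summarise(
      statistic = {
        o <- .data$fraction[match(DNA_BASES, .data$base)] * .data$weight[1]
        e <- background * .data$weight[1]
        if (any(e == 0 & o > 0)) {
          abort("background fraction of 0 with nonzero observed count")
        }
        sum((o - e)^2 / e)
      },
      .groups = "drop"
    ) |>
    mutate(df = 3L, p_value = pchisq(.data$statistic, df = 3,
                                     lower.tail = FALSE))
  out
}

#' Log2 deviation matrices and cognate-noncognate difference
#'
#' Deviation of each base's fraction from its local average — the mean
#' fraction of that base over the whole profile window — on the log2 scale,
#' with the per-position sum of absolute deviations; when a second profile
#' is given, also the per-cell absolute log2 difference between the two
#' profiles and its per-position sum. Zero fractions are floored at
#' `pseudo_fraction` (logged) before taking logs.
#'
#' @param profile_cognate A `composition_profile`.
#' @param profile_noncognate Optional second profile sharing positions.
#' @param pseudo_fraction Floor for zero fractions (default 1e-4).
#' @return A `bias_matrices` list: `deviation` (and `deviation_noncognate`),
#'   `sum_abs_deviation`, and when two profiles are given `difference` and
#'   `sum_abs_difference`.
#' @export
deviation_matrices <- function(profile_cognate, profile_noncognate = NULL,
                               pseudo_fraction = 1e-4) {
  dev_of <- function(profile) {
    prof <- as_tibble(profile)
    floored <- prof$fraction == 0
    if (any(floored)) {
      inform(sprintf("floored %d zero fraction(s) at %g",
                     sum(floored), pseudo_fraction))
    }
    prof |>
      mutate(fraction = pmax(.data$fraction, pseudo_fraction)) |>
      group_by(.data$base) |>
      mutate(deviation = log2(.data$fraction / mean(.data$fraction))) |>
      ungroup() |>
      select("position", "base", "deviation")
  }
  dc <- dev_of(profile_cognate)
  out <- list(
    deviation = dc,
    sum_abs_deviation = dc |>
      group_by(.data$position) |>
      summarise(sum_abs = sum(abs(.data$deviation)), .groups = "drop")
  )
  if (!is.null(profile_noncognate)) {
    dn <- dev_of(profile_noncognate)
    if (!identical(dc$position, dn$position)) {
      abort("profiles do not share positions")
    }
    diff <- dc |>
      mutate(difference = abs(.data$deviation - dn$deviation)) |>
      select("position", "base", "difference")
    out$deviation_noncognate <- dn
    out$difference <- diff
    out$sum_abs_difference <- diff |>
      group_by(.data$position) |>
      summarise(sum_abs = sum(abs(.data$difference)), .groups = "drop")
  }
  structure(out, class = "bias_matrices")
}
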