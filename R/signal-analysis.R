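# Binning, aggregation, correlation and region-level quantification of
# nucleotide-resolution break tracks.

#' Bin a nucleotide-resolution track
#'
#' A 1-based position `p` falls into bin `floor((p - 1) / bin_width)`; bin
#' values are sums, so total signal is conserved. When a genome (or named
#' contig-length vector) is supplied, every bin of every contig is present,
#' zeros included — required by the noise estimator, broad-scale pipeline and
#' autocorrelation.
#'
#' @param track Tibble with `contig`, `pos` and a signal column.
#' @param bin_width Bin size in bp (>= 1).
#' @param genome Optional genome or named contig-length vector for complete
#'   (zero-filled) bins.
#' @param by_strand Keep strands separate (default FALSE: strands are summed).
#' @return Tibble `contig`, `bin`, `bin_start0`, `value` (plus `strand` when
#'   `by_strand`).
#' @export
bin_track <- function(track, bin_width, genome = NULL, by_strand = FALSE) {
  stopifnot(bin_width >= 1)
  vc <- signal_col(track)
  keys <- c("contig", if (by_strand) "strand", "bin")
  out <- as_tibble(track) |>
    mutate(bin = floor((.data$pos - 1) / bin_width)) |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(value = sum(.data[[vc]]), .groups = "drop")
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    grid <- purrr::map2(names(lens), lens, function(ct, l) {
      tibble(contig = ct, bin = 0:(ceiling(l / bin_width) - 1))
    }) |>
      bind_rows()
    if (by_strand) {
      grid <- tidyr::crossing(grid, strand = c("watson", "crick"))
    }
    out <- grid |>
      left_join(out, by = keys) |>
      mutate(value = tidyr::replace_na(.data$value, 0))
  }
  out |>
    mutate(bin_start0 = .data$bin * bin_width) |>
    arrange(.data$contig, .data$bin)
}

#' Aggregate a track around loci of interest
#'
#' Metagene-style aggregation: signal is collected at offsets `-flank..flank`
#' around each locus, summed over loci and divided by the number of loci to
#' give mean HpM (or counts) per locus. With `orient = TRUE`, minus-strand
#' loci contribute with negated offsets and swapped strands, so biological
#' upstream/downstream and same/opposite strand are preserved.
#'
#' @param track Track tibble (`contig`, `pos`, optionally `strand`, signal).
#' @param loci Tibble with `contig`, `pos` and optionally `strand`
#'   (`"+"`, `"-"`, or `"."`).
#' @param flank Half-window in bp.
#' @param orient Flip minus-strand loci (default TRUE).
#' @param bin_width Offset bin size in bp (default 1, nucleotide resolution).
#' @param genome Optional contig lengths; loci whose window leaves the contig
#'   are dropped with a message.
#' @return An `aggregate_profile` tibble: `offset`, `strand` (if the track is
#'   stranded), `mean_value`; attribute `n_loci`.
#' @export
aggregate_loci <- function(track, loci, flank, orient = TRUE, bin_width = 1,
                           genome = NULL) {
  loci <- as_tibble(loci)
  if (nrow(loci) == 0) {
    abort("aggregate_loci needs at least one locus")
  }
  if (!"strand" %in% names(loci)) {
    loci$strand <- "."
  }
  keep <- loci$pos - flank >= 1
  if (!is.null(genome)) {
    lens <- contig_lengths(genome)
    keep <- keep & loci$pos + flank <= lens[loci$contig]
  }
  if (any(!keep)) {
    inform(sprintf("dropped %d locus/loci whose window leaves the contig",
                   sum(!keep)))
  }
  loci <- loci[keep, , drop = FALSE]
  if (nrow(loci) == 0) {
    abort("no locus window fits inside the genome")
  }
  vc <- signal_col(track)
  stranded <- "strand" %in% names(track)
  loci$.locus_strand <- loci$strand
  hits <- as_tibble(track) |>
    inner_join(
      loci |> select("contig", locus_pos = "pos", ".locus_strand"),
      by = "contig", relationship = "many-to-many"
    ) |>
    mutate(offset = .data$pos - .data$locus_pos) |>
    filter(abs(.data$offset) <= flank)
  if (orient) {
    flip <- hits$.locus_strand == "-"
    hits$offset[flip] <- -hits$offset[flip]
    if (stranded) {
      hits$strand[flip] <- if_else(hits$strand[flip] == "watson",
                                   "crick", "watson")
    }
  }
  if (bin_width > 1) {
    hits$offset <- (floor((hits$offset + flank) / bin_width)) * bin_width -
      flank
  }
  keys <- c("offset", if (stranded) "strand")
  grid_off <- if (bin_width > 1) {
    unique((floor(((-flank):flank + flank) / bin_width)) * bin_width - flank)
  } else {
    (-flank):flank
  }
  grid <- if (stranded) {
    tidyr::crossing(offset = grid_off, strand = c("watson", "crick"))
  } else {
    tibble(offset = grid_off)
  }
  prof <- hits |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(total = sum(.data[[vc]]), .groups = "drop")
  prof <- grid |>
    left_join(prof, by = keys) |>
    mutate(
      total = tidyr::replace_na(.data$total, 0),
      mean_value = .data$total / nrow(loci)
    ) |>
    select(dplyr::all_of(keys), "mean_value") |>
    arrange(.data$offset)
  structure(prof,
    class = c("aggregate_profile", class(prof)),
    n_loci = nrow(loci)
  )
}

#' Stratify loci into covariate quantile groups
#'
#' Splits loci into `k` groups by a covariate (expression level, gene length,
#' ChIP strength ...), lowest first, sizes differing by at most one. Ties are
#' broken by stable input order; loci with missing covariates are dropped
#' with a message.
#'
#' @param loci Tibble of loci.
#' @param k Number of strata (e.g. 4 for quartiles).
#' @param covariate Column name holding the covariate (default "covariate").
#' @return `loci` with an integer `stratum` column (1 = lowest).
#' @export
stratify_loci <- function(loci, k, covariate = "covariate") {
  loci <- as_tibble(loci)
  if (!covariate %in% names(loci)) {
    abort(paste0("covariate column '", covariate, "' not found"))
  }
  cv <- loci[[covariate]]
  if (anyNA(cv)) {
    inform(sprintf("dropped %d locus/loci with missing covariate",
                   sum(is.na(cv))))
    loci <- loci[!is.na(cv), , drop = FALSE]
    cv <- loci[[covariate]]
  }
  n <- length(cv)
  sizes <- rep(n %/% k, k) + as.integer(seq_len(k) <= n %% k)
  ord <- order(cv) # radix sort: stable, preserving input order at ties
  stratum <- integer(n)
  stratum[ord] <- rep(seq_len(k), times = sizes)
  loci$stratum <- stratum
  loci
}

#' Spatial autocorrelation of a binned track
#'
#' Pearson correlation between bin values separated by `s` bins, for
#' `s = 0..max_separation_bins`, pooled over contigs. Requires complete
#' (zero-filled) bins as from [bin_track()] with `genome` set.
#'
#' @param binned Tibble `contig`, `bin`, `value` with contiguous bins.
#' @param max_separation_bins Largest separation in bins.
#' @return Tibble `separation`, `r`, `n_pairs`; `r` is `NA` (flagged by a
#'   warning) where a series has zero variance or fewer than 3 pairs.
#' @export
autocorrelate <- function(binned, max_separation_bins) {
  binned <- as_tibble(binned) |> arrange(.data$contig, .data$bin)
  per_contig <- split(binned$value, binned$contig)
  if (sum(lengths(per_contig)) < 3) {
    abort("autocorrelate needs at least 3 bins")
  }
  rows <- purrr::map(0:max_separation_bins, function(s) {
    x <- unlist(lapply(per_contig, function(v) {
      if (length(v) > s) head(v, length(v) - s) else numeric(0)
    }), use.names = FALSE)
    y <- unlist(lapply(per_contig, function(v) {
      if (length(v) > s) tail(v, length(v) - s) else numeric(0)
    }), use.names = FALSE)
    r <- if (length(x) >= 3 && stats::sd(x) > 0 && stats::sd(y) > 0) {
      cor(x, y)
    } else {
      NA_real_
    }
    tibble(separation = s, r = r, n_pairs = length(x))
  })
  out <- bind_rows(rows)
  if (anyNA(out$r)) {
    warn("autocorrelation undefined at some separations (zero variance or too few pairs)")
  }
  out
}

#' Watson-Crick cross-correlation over strand offsets
#'
#' For each offset `d` in `offset_range`, Watson positions `w` are paired
#' with Crick positions `w + d` (positive `d` means the Crick coordinate lies
#' 3', rightward, of the Watson coordinate, matching 5'-overhang geometry).
#' Only sites with signal above `min_threshold` on both strands enter the
#' Pearson correlation. The fraction of reads captured at each offset is
#' normalised over the offset range (after the both-strands filter).
#'
#' A map built from double-strand breaks with an `n`-nucleotide 5' overhang
#' peaks at offset `n - 1`: 3 for topoisomerase-II-like 4-nt overhangs,
#' 1 for Spo11-like 2-nt overhangs.
#'
#' @param map Break map or HpM track with both strands.
#' @param offset_range Integer vector of offsets (default -100..100).
#' @param min_threshold Sites must exceed this signal on both strands
#'   (default 0, i.e. any hit).
#' @return An `offset_correlation` tibble: `offset`, `r`, `n_sites`,
#'   `read_fraction`. `r` is `NA` where fewer than 3 sites qualify.
#' @export
strand_cross_correlation <- function(map, offset_range = -100:100,
                                     min_threshold = 0) {
  vc <- signal_col(map)
  w <- as_tibble(map) |>
    filter(.data$strand == "watson", .data[[vc]] > min_threshold) |>
    select("contig", "pos", w = dplyr::all_of(vc))
  c_ <- as_tibble(map) |>
    filter(.data$strand == "crick", .data[[vc]] > min_threshold) |>
    select("contig", "pos", c = dplyr::all_of(vc))
  rows <- purrr::map(offset_range, function(d) {
    paired <- inner_join(
      w, c_ |> mutate(pos = .data$pos - d),
      by = c("contig", "pos")
    )
    r <- if (nrow(paired) >= 3 && stats::sd(paired$w) > 0 &&
               stats::sd(paired$c) > 0) {
      cor(paired$w, paired$c)
    } else {
      NA_real_
    }
    tibble(
      offset = d, r = r, n_sites = nrow(paired),
      reads = sum(paired$w) + sum(paired$c)
    )
  })
  out <- bind_rows(rows) |>
    mutate(
      read_fraction = if (sum(.data$reads) > 0) {
        .data$reads / sum(.data$reads)
      } else {
        NA_real_
      }
    ) |>
    select("offset", "r", "n_sites", "read_fraction")
  structure(out, class = c("offset_correlation", class(out)))
}

#' Offsets with maximal Watson-Crick correlation
#'
#' @param oc An `offset_correlation` from [strand_cross_correlation()].
#' @return Integer vector of offsets attaining the maximal `r` (usually one;
#'   all maxima are reported on ties).
#' @export
peak_offset <- function(oc) {
  r <- oc$r
  if (all(is.na(r))) {
    abort("correlation undefined at every offset")
  }
  oc$offset[which(!is.na(r) & r == max(r, na.rm = TRUE))]
}

#' Classify intergenic regions by flanking gene orientation
#'
#' Gene extents (overlapping genes merged) are labelled `intragenic`; each
#' gap between consecutive merged extents is labelled by the strands of its
#' flanking genes: `(-,+)` divergent, `(+,-)` convergent, `(+,+)` or `(-,-)`
#' tandem. Contig ends (and all gaps on contigs with fewer than two genes)
#' are `unlabelled`.
#'
#' @param genes Tibble `contig`, `start`, `end` (1-based inclusive),
#'   `strand` (`"+"`/`"-"`).
#' @param genome Optional contig lengths so the trailing contig end appears.
#' @return Tibble `contig`, `start`, `end`, `label` partitioning each contig.
#' @export
classify_igrs <- function(genes, genome = NULL) {
  genes <- as_tibble(genes) |> arrange(.data$contig, .data$start, .data$end)
  lens <- if (!is.null(genome)) contig_lengths(genome) else NULL
  out <- lapply(split(genes, genes$contig), function(g) {
    ct <- g$contig[1]
    # merge overlapping gene extents; remember boundary-gene strands
    rows <- list()
    start <- g$start[1]; end <- g$end[1]
    s_left <- g$strand[1]; s_right <- g$strand[1]
    if (nrow(g) > 1) {
      for (i in 2:nrow(g)) {
        if (g$start[i] <= end) { # overlap: extend merged run
          if (g$end[i] > end) {
            end <- g$end[i]
            s_right <- g$strand[i]
          }
        } else {
          rows[[length(rows) + 1]] <- list(
            start = start, end = end, s_left = s_left, s_right = s_right
          )
          start <- g$start[i]; end <- g$end[i]
          s_left <- g$strand[i]; s_right <- g$strand[i]
        }
      }
    }
    rows[[length(rows) + 1]] <- list(
      start = start, end = end, s_left = s_left, s_right = s_right
    )
    m <- bind_rows(lapply(rows, as_tibble))
    few <- nrow(m) < 2
    if (few) {
      inform(sprintf("contig %s has < 2 gene extents; gaps left unlabelled", ct))
    }
    pieces <- list()
    if (m$start[1] > 1) {
      pieces[[length(pieces) + 1]] <- tibble(
        contig = ct, start = 1, end = m$start[1] - 1, label = "unlabelled"
      )
    }
    for (i in seq_len(nrow(m))) {
      pieces[[length(pieces) + 1]] <- tibble(
        contig = ct, start = m$start[i], end = m$end[i], label = "intragenic"
      )
      if (i < nrow(m) && m$start[i + 1] > m$end[i] + 1) {
        lab <- if (few) {
          "unlabelled"
        } else {
          sl <- m$s_right[i]   # gene ending the left flank
          sr <- m$s_left[i + 1] # gene starting the right flank
          dplyr::case_when(
            sl == "-" & sr == "+" ~ "IGR_divergent",
            sl == "+" & sr == "-" ~ "IGR_convergent",
            TRUE ~ "IGR_tandem"
          )
        }
        pieces[[length(pieces) + 1]] <- tibble(
          contig = ct, start = m$end[i] + 1, end = m$start[i + 1] - 1,
          label = lab
        )
      }
    }
    last_end <- m$end[nrow(m)]
    if (!is.null(lens) && !is.na(lens[ct]) && last_end < lens[ct]) {
      pieces[[length(pieces) + 1]] <- tibble(
        contig = ct, start = last_end + 1, end = unname(lens[ct]),
        label = "unlabelled"
      )
    }
    bind_rows(pieces)
  })
  bind_rows(out) |> arrange(.data$contig, .data$start)
}

#' Signal density per region, with box-and-whisker summary helpers
#'
#' Density is total signal in the region divided by region length in bp.
#'
#' @param track Track tibble.
#' @param regions Tibble `contig`, `start`, `end` (1-based inclusive), any
#'   extra columns (e.g. `label`) carried through.
#' @return `regions` with added `density`.
#' @export
region_density <- function(track, regions) {
  regions <- as_tibble(regions)
  if (any(regions$end < regions$start)) {
    abort("zero- or negative-length region")
  }
  vc <- signal_col(track)
  tr <- as_tibble(track)
  dens <- vapply(seq_len(nrow(regions)), function(i) {
    v <- tr[[vc]][tr$contig == regions$contig[i] &
                    tr$pos >= regions$start[i] & tr$pos <= regions$end[i]]
    sum(v) / (regions$end[i] - regions$start[i] + 1)
  }, numeric(1))
  regions$density <- dens
  regions
}

#' @rdname region_density
#' @param x Numeric vector of densities.
#' @return For `box_stats()`: one-row tibble with quartiles and Tukey
#'   whiskers (most extreme points within 1.5 IQR of the box).
#' @export
box_stats <- function(x) {
  qs <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- qs[3] - qs[1]
  lo_lim <- qs[1] - 1.5 * iqr
  hi_lim <- qs[3] + 1.5 * iqr
  tibble(
    q1 = qs[1], median = qs[2], q3 = qs[3],
    whisker_lo = min(x[x >= lo_lim]),
    whisker_hi = max(x[x <= hi_lim]),
    n = length(x)
  )
}

#' Threshold a track into peak positions
#'
#' Positions whose (strand-summed, by default) signal is greater than or
#' equal to `threshold` — the inclusive comparison keeps sites exactly at
#' the printed cutoff. The reference analysis used 0.05 HpM on pooled data.
#'
#' @param track Track tibble in HpM.
#' @param threshold Inclusive signal cutoff (default 0.05).
#' @param combine_strands Sum strands per position first (default TRUE).
#' @return Tibble `contig`, `pos`, `value` of peak positions.
#' @export
call_peaks <- function(track, threshold = 0.05, combine_strands = TRUE) {
  vc <- signal_col(track)
  x <- as_tibble(track)
  if (combine_strands || !"strand" %in% names(x)) {
    x <- x |>
      group_by(.data$contig, .data$pos) |>
      summarise(value = sum(.data[[vc]]), .groups = "drop")
  } else {
    x <- x |> rename(value = dplyr::all_of(vc))
  }
  x |>
    filter(.data$value >= threshold) |>
    arrange(.data$contig, .data$pos)
}

#' Correlate per-locus break signal with a covariate
#'
#' Tallies track signal in a window relative to each locus (oriented by locus
#' strand), then reports Pearson's r against the log-transformed covariate
#' and Spearman's rank correlation against the raw covariate. Loci with
#' nonpositive covariates cannot be log-transformed and are dropped with a
#' message.
#'
#' @param track Track tibble.
#' @param loci Tibble `contig`, `pos`, optional `strand`, and a covariate
#'   column.
#' @param window Length-2 integer vector: offsets (inclusive) of the tally
#'   window relative to the locus, e.g. `c(0, 5000)` for 5 kb downstream.
#' @param covariate Covariate column name.
#' @param log_base Base of the covariate log-transform (default 10).
#' @return A `covariate_quantification` object; `tidy()` gives the per-locus
#'   table, `glance()` the correlations.
#' @export
quantify_vs_covariate <- function(track, loci, window, covariate = "covariate",
                                  log_base = 10) {
  loci <- as_tibble(loci)
  if (!covariate %in% names(loci)) {
    abort(paste0("covariate column '", covariate, "' not found"))
  }
  bad <- is.na(loci[[covariate]]) | loci[[covariate]] <= 0
  if (any(bad)) {
    inform(sprintf("dropped %d locus/loci with nonpositive covariate", sum(bad)))
    loci <- loci[!bad, , drop = FALSE]
  }
  if (!"strand" %in% names(loci)) {
    loci$strand <- "+"
  }
  vc <- signal_col(track)
  tr <- as_tibble(track)
  signal <- vapply(seq_len(nrow(loci)), function(i) {
    sgn <- if (loci$strand[i] == "-") -1L else 1L
    offs <- sgn * (tr$pos - loci$pos[i])
    sum(tr[[vc]][tr$contig == loci$contig[i] &
                   offs >= window[1] & offs <= window[2]])
  }, numeric(1))
  per_locus <- loci |> mutate(signal = signal)
  res <- list(
    per_locus = per_locus,
    pearson_r = cor(log(per_locus[[covariate]], base = log_base),
                    per_locus$signal),
    spearman_rs = cor(per_locus[[covariate]], per_locus$signal,
                      method = "spearman"),
    n_loci = nrow(per_locus),
    covariate = covariate, window = window
  )
  structure(res, class = "covariate_quantification")
}

#' @export
print.covariate_quantification <- function(x, ...) {
  cat(sprintf(
    "<covariate_quantification> %d loci, window [%d, %d]: Pearson r = %.3f (log covariate), Spearman rs = %.3f\n",
    x$n_loci, x$window[1], x$window[2], x$pearson_r, x$spearman_rs
  ))
  invisible(x)
}

#' @export
tidy.covariate_quantification <- function(x, ...) {
  x$per_locus
}

#' @export
glance.covariate_quantification <- function(x, ...) {
  tibble(pearson_r = x$pearson_r, spearman_rs = x$spearman_rs,
         n_loci = x$n_loci)
}
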