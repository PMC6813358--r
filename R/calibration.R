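#' Normalise a break map to hits per million mapped read pairs (HpM)
#'
#' HpM is the package's depth-normalised unit: raw count multiplied by 10^6
#' and divided by the total mapped pairs of the library, per base pair.
#'
#' @param map A [break_map()] with a positive `total_mapped_pairs`.
#' @return An `hpm_track` tibble with columns `contig`, `pos`, `strand`,
#'   `hpm` and attributes `total_mapped_pairs` and `calibration_factor`
#'   (1 when uncalibrated).
#' @export
to_hpm <- function(map) {
  total <- attr(map, "total_mapped_pairs")
  if (is.null(total) || total <= 0) {
    abort("to_hpm needs a map with total_mapped_pairs > 0")
  }
  out <- as_tibble(map) |>
    mutate(hpm = .data$count * 1e6 / total) |>
    select("contig", "pos", "strand", "hpm")
  hpm_track(out,
    total_mapped_pairs = total, calibration_factor = 1,
    sample_id = attr(map, "sample_id")
  )
}

#' @rdname to_hpm
#' @param x Tibble with columns `contig`, `pos`, `strand`, `hpm`.
#' @param total_mapped_pairs,calibration_factor,sample_id Track metadata.
#' @export
hpm_track <- function(x, total_mapped_pairs, calibration_factor = 1,
                      sample_id = NA_character_) {
  structure(as_tibble(x),
    class = c("hpm_track", class(as_tibble(x))),
    total_mapped_pairs = as.numeric(total_mapped_pairs),
    calibration_factor = calibration_factor,
    sample_id = sample_id
  )
}

#' Spike-in calibration information
#'
#' Records how many read pairs aligned to the primary genome and how many to
#' the spike-in genome mixed in at a known molar ratio (1:100
#' spike:primary in the source protocol). Calibrated values are obtained by
#' multiplying by the reciprocal of the spike read fraction.
#'
#' @param reads_primary,reads_spike Pair counts aligned to each genome.
#' @return A `spike_info` list with `fraction_spike`.
#' @export
spike_info <- function(reads_primary, reads_spike) {
  if (reads_spike <= 0 || reads_primary <= 0) {
    abort("spike calibration needs positive read counts for both genomes")
  }
  structure(
    list(
      reads_primary = reads_primary,
      reads_spike = reads_spike,
      fraction_spike = reads_spike / (reads_primary + reads_spike)
    ),
    class = "spike_info"
  )
}

#' Calibrate an HpM track by its spike-in fraction
#'
#' Every value is multiplied by `1 / fraction_spike`, making peak heights
#' comparable between samples that recovered the spike genome with different
#' efficiency.
#'
#' @param track An `hpm_track`.
#' @param spike A [spike_info()] object, or a bare spike fraction in (0, 1).
#' @return The calibrated `hpm_track`; `calibration_factor` is updated.
#' @export
spike_calibrate <- function(track, spike) {
  frac <- if (inherits(spike, "spike_info")) spike$fraction_spike else spike
  if (!is.numeric(frac) || frac <= 0 || frac >= 1) {
    abort("spike fraction must lie strictly between 0 and 1")
  }
  vc <- signal_col(track)
  out <- as_tibble(track)
  out[[vc]] <- out[[vc]] / frac
  hpm_track(out,
    total_mapped_pairs = attr(track, "total_mapped_pairs"),
    calibration_factor = (attr(track, "calibration_factor") %||% 1) / frac,
    sample_id = attr(track, "sample_id")
  )
}

#' Estimate the background-noise ratio between two samples
#'
#' Adaptation of the NCIS background-scaling idea: both samples are binned
#' genome-wide, the `low_fraction` of bins with the lowest signal is selected
#' independently in each sample, and the mean signal density over that
#' subpopulation defines each sample's noise density. The returned ratio
#' `r = d_treated / d_control` scales the control (untreated) sample so its
#' background matches the treated one.
#'
#' @param track_treated,track_control Position-level tracks (any tibble with
#'   `contig`, `pos` and a signal column) on the same genome.
#' @param genome Genome or named contig-length vector; needed so empty bins
#'   participate.
#' @param bin_width Bin size in bp (default 10000).
#' @param low_fraction Fraction of lowest-signal bins defining the noise
#'   subpopulation (default 0.5).
#' @return A `noise_estimate` list: `d_treated`, `d_control`, `ratio`,
#'   `bin_width`, `low_fraction`, `n_bins`.
#' @export
estimate_noise_ratio <- function(track_treated, track_control, genome,
                                 bin_width = 10000, low_fraction = 0.5) {
  if (low_fraction <= 0 || low_fraction > 1) {
    abort("low_fraction must be in (0, 1]")
  }
  noise_density <- function(track) {
    bins <- bin_track(track, bin_width, genome = genome)
    v <- sort(bins$value)
    k <- max(1L, floor(length(v) * low_fraction))
    list(d = mean(v[seq_len(k)]), n = length(v))
  }
  t <- noise_density(track_treated)
  c_ <- noise_density(track_control)
  if (c_$d == 0) {
    abort("noise density of the control sample is zero; ratio undefined")
  }
  structure(
    list(
      d_treated = t$d, d_control = c_$d, ratio = t$d / c_$d,
      bin_width = bin_width, low_fraction = low_fraction, n_bins = t$n
    ),
    class = "noise_estimate"
  )
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf(
    "<noise_estimate> r = %.4g (d_treated %.4g / d_control %.4g), %d bins of %g bp, lowest %g%%\n",
    x$ratio, x$d_treated, x$d_control, x$n_bins, x$bin_width,
    100 * x$low_fraction
  ))
  invisible(x)
}

#' @export
glance.noise_estimate <- function(x, ...) {
  tibble(
    ratio = x$ratio, d_treated = x$d_treated, d_control = x$d_control,
    bin_width = x$bin_width, low_fraction = x$low_fraction, n_bins = x$n_bins
  )
}

#' Prepare a broad-scale binned track
#'
#' The broad-scale plotting pipeline: optional noise scaling, binning,
#' smoothing with a unit-sum Hann window, and subtraction of the genome-wide
#' median of the smoothed bins (zeros included).
#'
#' @param track Position-level track tibble.
#' @param genome Genome or contig-length vector (bins cover it completely).
#' @param bin_width Bin size in bp.
#' @param scale Multiplicative factor applied before binning; pass a
#'   [estimate_noise_ratio()] `ratio` to scale a control sample.
#' @param window Hann window length in bins (default 10).
#' @return Tibble `contig`, `bin_start0` (0-based), `value`.
#' @export
prepare_broadscale <- function(track, genome, bin_width = 10000, scale = 1,
                               window = 10) {
  bins <- bin_track(track, bin_width, genome = genome)
  bins$value <- bins$value * scale
  bins <- bins |>
    group_by(.data$contig) |>
    mutate(value = hann_smooth(.data$value, window)) |>
    ungroup()
  bins$value <- bins$value - median(bins$value)
  bins |> select("contig", "bin_start0", "value")
}
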