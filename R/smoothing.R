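# Smoothing kernels for binned and nucleotide-resolution tracks.

#' Unit-sum Hann (raised-cosine) kernel
#'
#' @param n Window length in bins (>= 1). The two end weights of the raw
#'   Hann window are zero, so the effective support is `n - 2` bins.
#' @return Numeric vector of length `n` summing to 1.
#' @export
hann_kernel <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) {
    return(1)
  }
  k <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  if (sum(k) == 0) k <- rep(1, n) # n = 2 degenerates; fall back to boxcar
  k / sum(k)
}

#' Smooth a numeric series with a Hann window
#'
#' Convolution with the unit-sum Hann kernel. At the edges the window is
#' truncated and renormalised, so a constant input is returned unchanged
#' everywhere. Even window lengths centre the kernel half a bin to the left;
#' the default broad-scale window of 10 bins inherits this half-bin
#' convention from the windowed-smoothing literature.
#'
#' @param x Numeric vector of bin values.
#' @param window_bins Window length in bins; 1 is the identity.
#' @return Smoothed vector, same length as `x`.
#' @export
hann_smooth <- function(x, window_bins = 10) {
  n <- length(x)
  if (window_bins <= 1 || n == 0) {
    return(x)
  }
  k <- hann_kernel(window_bins)
  m <- length(k)
  centre <- floor((m + 1) / 2)
  conv <- function(v) {
    y <- stats::convolve(v, rev(k), type = "open")
    y[centre:(centre + n - 1)]
  }
  num <- conv(x)
  den <- conv(rep(1, n))
  num / den
}

#' Density-adaptive kernel smoothing of a nucleotide-resolution track
#'
#' Fine-scale display smoother: each hit is spread by a Gaussian kernel whose
#' bandwidth shrinks where the local hit density is high, so dense clusters
#' stay sharp while isolated hits are spread wide. The bandwidth at a
#' position is `b0 / (1 + d)` where `d` is the summed signal within a
#' `window`-bp window centred there. Total mass is conserved exactly (each
#' hit's discrete kernel is normalised to its own value). This is a
#' display-oriented heuristic, not an inferential estimator.
#'
#' @param track Tibble with `pos` and a signal column (single contig/strand).
#' @param b0 Base bandwidth in bp at zero local density (default 5).
#' @param window Width in bp of the local-density window (default 50).
#' @return Tibble `pos`, `value` on the covering integer grid.
#' @export
density_smooth <- function(track, b0 = 5, window = 50) {
  vc <- signal_col(track)
  if (nrow(track) == 0) {
    abort("density_smooth needs a nonempty track")
  }
  pos <- track$pos
  val <- track[[vc]]
  half <- floor(window / 2)
  local_density <- vapply(pos, function(p) {
    sum(val[pos >= p - half & pos <= p + half])
  }, numeric(1))
  bw <- b0 / (1 + local_density)
  lo <- min(pos - ceiling(4 * bw + 1))
  hi <- max(pos + ceiling(4 * bw + 1))
  grid <- lo:hi
  out <- numeric(length(grid))
  for (i in seq_along(pos)) {
    span <- ceiling(4 * bw[i] + 1)
    cells <- (pos[i] - span):(pos[i] + span)
    w <- stats::dnorm(cells, mean = pos[i], sd = max(bw[i], 1e-9))
    w <- w / sum(w)
    out[cells - lo + 1] <- out[cells - lo + 1] + val[i] * w
  }
  tibble(pos = grid, value = out)
}
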