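# Cognate/noncognate fractionation: pairing Watson and Crick 5' termini at
# the overhang offset and testing each site's strand disparity with the
# exact two-sample Poisson test. Balanced sites (cognate) behave like
# double-strand breaks; significantly imbalanced sites (noncognate) carry the
# signature of strand-biased single-strand breaks.

#' Pair Watson and Crick positions at a fixed strand offset
#'
#' Every Watson position `w` and/or Crick position `w + offset` with a
#' nonzero count yields one site; a missing strand contributes zero. The
#' offset is the overhang length minus one: 3 for 4-nt (Top2-like), 1 for
#' 2-nt (Spo11-like) overhangs. With a fixed offset the pairing is unique:
#' no position can join two sites on the same strand.
#'
#' @param map Break map (counts, not HpM: the Poisson model lives on the
#'   count scale).
#' @param offset Crick-minus-Watson coordinate offset (default 3).
#' @return An `offset_sites` tibble: `contig`, `watson_pos`, `crick_pos`,
#'   `w`, `c`, `total`; attribute `offset`.
#' @export
pair_offset_sites <- function(map, offset = 3) {
  stopifnot(offset >= 0)
  vc <- signal_col(map)
  w <- as_tibble(map) |>
    filter(.data$strand == "watson") |>
    select("contig", watson_pos = "pos", w = dplyr::all_of(vc))
  c_ <- as_tibble(map) |>
    filter(.data$strand == "crick") |>
    mutate(watson_pos = .data$pos - offset) |>
    select("contig", "watson_pos", c = dplyr::all_of(vc))
  sites <- full_join(w, c_, by = c("contig", "watson_pos")) |>
    mutate(
      w = tidyr::replace_na(.data$w, 0),
      c = tidyr::replace_na(.data$c, 0),
      crick_pos = .data$watson_pos + offset,
      total = .data$w + .data$c
    ) |>
    select("contig", "watson_pos", "crick_pos", "w", "c", "total") |>
    arrange(.data$contig, .data$watson_pos)
  structure(sites,
    class = c("offset_sites", class(sites)),
    offset = offset
  )
}

#' Exact two-sample Poisson test of Watson-Crick disparity
#'
#' Tests H0: equal Poisson rates on the two strands with equal exposure.
#' Conditional on the total `n = w + c`, the Watson count is
#' Binomial(n, 1/2) under H0; the two-sided p-value follows the
#' minimum-likelihood rule (sum of probabilities of all outcomes no more
#' likely than the observed one), which for this symmetric null equals the
#' doubled smaller tail capped at 1:
#' `p = min(1, 2 * pbinom(min(w, c), n, 1/2))`.
#'
#' @param w,c Non-negative integer counts (vectorised); `w + c >= 1`.
#' @return p-values in (0, 1].
#' @export
#' @examples
#' poisson_exact_test(4, 4)  # 1
#' poisson_exact_test(8, 0)  # 0.0078125
poisson_exact_test <- function(w, c) {
  n <- max(length(w), length(c))
  w <- rep_len(w, n)
  c <- rep_len(c, n)
  total <- w + c
  if (any(total < 1)) {
    abort("poisson_exact_test needs w + c >= 1")
  }
  pmin(1, 2 * pbinom(pmin(w, c), total, 0.5))
}

#' Fractionate offset sites into cognate and noncognate classes
#'
#' Sites with fewer than `min_total` hits are excluded for lack of power.
#' Among tested sites, `p <= alpha` is noncognate (significant strand
#' disparity), `p > hi` is highly cognate, and the rest are cognate.
#' Defaults follow the published thresholds: `min_total = 8`,
#' `alpha = 0.05`, `hi = 0.95`. No multiple-testing correction is applied:
#' the per-site alpha is the classification rule.
#'
#' @param sites An `offset_sites` tibble (or a tibble with `w`, `c`).
#' @param alpha Noncognate significance threshold.
#' @param hi Highly-cognate p-value threshold.
#' @param min_total Minimum total hits for a site to be tested.
#' @return A `fractionation` object: `$sites` with `p_value` and `class`
#'   (`excluded` / `noncognate` / `cognate` / `highly_cognate`; the latter
#'   two together form the cognate fraction), `$summary` with per-class
#'   counts and percentages among tested sites, `$params`.
#' @export
fractionate <- function(sites, alpha = 0.05, hi = 0.95, min_total = 8) {
  sites <- as_tibble(sites)
  tested <- sites$total >= min_total
  p <- rep(NA_real_, nrow(sites))
  p[tested] <- poisson_exact_test(sites$w[tested], sites$c[tested])
  cls <- dplyr::case_when(
    !tested ~ "excluded",
    p <= alpha ~ "noncognate",
    p > hi ~ "highly_cognate",
    TRUE ~ "cognate"
  )
  sites$p_value <- p
  sites$class <- factor(cls,
    levels = c("excluded", "noncognate", "cognate", "highly_cognate")
  )
  n_tested <- sum(tested)
  summary <- sites |>
    count(.data$class, .drop = FALSE, name = "n") |>
    mutate(
      pct_of_tested = if_else(
        .data$class == "excluded", NA_real_,
        100 * .data$n / n_tested
      )
    )
  structure(
    list(
      sites = sites, summary = summary,
      params = list(
        offset = attr(sites, "offset", exact = TRUE),
        alpha = alpha, hi = hi, min_total = min_total
      )
    ),
    class = "fractionation"
  )
}

#' @export
print.fractionation <- function(x, ...) {
  s <- x$summary
  n_tested <- sum(s$n[s$class != "excluded"])
  cat(sprintf(
    "<fractionation> %d sites (%d tested): %.1f%% cognate (%.1f%% highly), %.1f%% noncognate [alpha=%g, hi=%g, min_total=%d]\n",
    sum(s$n), n_tested,
    sum(s$pct_of_tested[s$class %in% c("cognate", "highly_cognate")],
        na.rm = TRUE),
    s$pct_of_tested[s$class == "highly_cognate"],
    s$pct_of_tested[s$class == "noncognate"],
    x$params$alpha, x$params$hi, x$params$min_total
  ))
  invisible(x)
}

#' @export
tidy.fractionation <- function(x, ...) {
  x$sites
}

#' @export
glance.fractionation <- function(x, ...) {
  s <- x$summary
  pct <- function(cl) {
    v <- s$pct_of_tested[s$class == cl]
    if (length(v) == 0 || is.na(v)) 0 else v
  }
  tibble(
    n_sites = sum(s$n),
    n_tested = sum(s$n[s$class != "excluded"]),
    pct_cognate = pct("cognate") + pct("highly_cognate"),
    pct_highly_cognate = pct("highly_cognate"),
    pct_noncognate = pct("noncognate")
  )
}

#' Shuffle break amplitudes among occupied positions
#'
#' Randomisation control for the fractionation: per strand, the multiset of
#' per-position counts is permuted uniformly over that strand's occupied
#' positions (positions themselves are unchanged, and counts never move to
#' unoccupied coordinates). This destroys Watson-Crick pairing while
#' preserving each strand's amplitude distribution, giving the expectation
#' under independently distributed strands.
#'
#' @param map A break map.
#' @param seed Integer seed (the permutation is seed-deterministic).
#' @return A break map of the same shape with permuted counts.
#' @export
shuffle_amplitudes <- function(map, seed = NULL) {
  out <- as_tibble(map)
  vc <- signal_col(out)
  with_seed(seed, {
    for (s in unique(out$strand)) {
      idx <- which(out$strand == s)
      out[[vc]][idx] <- out[[vc]][idx][sample.int(length(idx))]
    }
  })
  if (inherits(map, "break_map")) {
    out <- rewrap_break_map(out, map)
  }
  out
}

#' Simulate a fully cognate dataset matched to an observed map
#'
#' The observed Watson and Crick counts at each offset site are averaged to a
#' site intensity `lambda = (w + c) / 2`; simulated Watson and Crick counts
#' are then drawn independently from Poisson(lambda). By construction every
#' simulated site is a balanced double-strand-break site, so fractionating
#' the simulation estimates the method's false-noncognate (type I) rate.
#'
#' @param map A break map, or an `offset_sites` tibble.
#' @param offset Strand offset used to pair sites when `map` is a break map.
#' @param seed Integer seed.
#' @return A `cognate_simulation`: an `offset_sites`-shaped tibble with
#'   simulated `w`, `c` and the `lambda` column; attributes `offset`, `seed`.
#' @export
simulate_fully_cognate <- function(map, offset = 3, seed = NULL) {
  sites <- if (inherits(map, "offset_sites")) {
    map
  } else {
    pair_offset_sites(map, offset)
  }
  offset <- attr(sites, "offset", exact = TRUE) %||% offset
  lambda <- (sites$w + sites$c) / 2
  out <- with_seed(seed, {
    sites |>
      mutate(
        lambda = lambda,
        w = rpois(length(lambda), lambda),
        c = rpois(length(lambda), lambda),
        total = .data$w + .data$c
      )
  })
  structure(out,
    class = c("cognate_simulation", "offset_sites", class(as_tibble(out))),
    offset = offset, seed = seed
  )
}

#' Compare observed, simulated and randomised fractionations
#'
#' @param observed,simulated,randomized `fractionation` objects produced
#'   with identical parameters (checked; mismatch is an error).
#' @return Tibble with one row per dataset and the per-class percentages.
#' @export
summarize_fractions <- function(observed, simulated, randomized) {
  frs <- list(
    observed = observed, simulated = simulated, randomized = randomized
  )
  keys <- c("alpha", "hi", "min_total")
  ref <- observed$params[keys]
  for (nm in names(frs)) {
    if (!identical(frs[[nm]]$params[keys], ref)) {
      abort("fractionation parameters differ between datasets")
    }
    if (sum(frs[[nm]]$summary$n) == 0) {
      abort(paste0("dataset '", nm, "' is empty"))
    }
  }
  purrr::imap(frs, function(fr, nm) {
    glance(fr) |> mutate(dataset = nm, .before = 1)
  }) |>
    bind_rows()
}
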