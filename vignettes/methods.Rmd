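---
title: "Models and methods behind ccbreakr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ccbreakr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccbreakr)
```

`ccbreakr` analyses sequencing libraries in which a protein — a type II
topoisomerase poisoned by etoposide, or Spo11 in meiosis — is covalently
linked to the 5′ terminus of the DNA break it created, and the library
chemistry marks that end: Read-1 of every concordant pair begins at the
protein-linked nucleotide, while Read-2 marks a sonication-derived end.
This vignette explains the models, parameters and numerical conventions the
package implements, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the method description left
room.

## 1. Terminal mapping

**Coordinate model.** All internal coordinates are 1-based inclusive on the
reference top (Watson) strand; bottom strand is Crick. bedGraph and BED
files are converted to and from their native 0-based half-open convention
only at the I/O boundary (`read_bed()`, `write_bedgraph()`).

**Informative pairs.** Only flag pairs (99, 147) and (83, 163) carry break
information. For a plus-strand Read-1 the 5′ terminus is the leftmost
aligned coordinate. For a minus-strand Read-1 the leftmost base is the 3′
end, so the 5′ coordinate is `leftmost + span − 1`, where the reference
span scores CIGAR operations `M = 1, D = 1, I = 0, S = 0`. Insertions are
ignored so that calls stay accurate to the reference; soft clips align to
nothing and contribute nothing. A read pair whose mates map to different
contigs is counted as flag-rejected; chimeric and supplementary alignments
are rejected by the flag rule itself.

**Ambiguous ends.** A terminus whose first bases disagree with the
reference cannot be placed confidently, so runs of ≥ 2 mismatched or
deleted bases at Read-1's 5′ end disqualify the pair (both reads' 5′ ends
in `mode = "double"`). The run is measured on the MD:Z walk, which runs
reference-left to reference-right — the read's 3′→5′ direction for minus
reads — so for minus reads the run is read from the right end of the walk.
Two conventions here are package decisions rather than published rules:
zero-length match tokens (`0`) do not interrupt a run, and 5′ soft-clipped
bases count toward the run, because a clipped terminus is just as
positionally uninformative as a mismatched one. The threshold is exposed as
`max_end_mismatch` (default 1, i.e. ≥ 2 disqualifies).

**Duplicates** are retained; the protocol includes no deduplication step,
and break maps legitimately pile many pairs on one coordinate.

**Masks.** `apply_region_mask()` treats intervals as 1-based half-open:
position `p` is inside `[start, end)` iff `start ≤ p < end`. `read_bed()`
shifts BED's 0-based starts and ends by +1 so the same bases are covered.
Masking never changes `total_mapped_pairs`: HpM stays a library-size unit.

## 2. Normalisation, calibration, noise

**HpM** (hits per million mapped read pairs, per bp) is
`count × 10⁶ / total_mapped_pairs`. Spike-in calibration multiplies every
value by the reciprocal of the spike read fraction, making peak heights
comparable across samples that recovered the spike genome with different
efficiency.

**Noise ratio.** The background scaling between a treated and an untreated
sample adapts the NCIS idea: bin both samples genome-wide (default 10 kb,
zeros included), take the `low_fraction` of bins with the lowest signal
*independently in each sample*, and call the mean bin value over that
subpopulation the sample's noise density `d`. The ratio
`r = d_treated / d_control` rescales the control. The size of the
low-signal subpopulation is not fixed by the method description; the
package exposes it as `low_fraction` with default 0.5 because quantile-type
background estimators are stable over a broad low quantile, and records the
value used in the returned object. Whether the published estimate averaged
per-bin densities or pooled reads over the subpopulation is also ambiguous;
the package uses the mean over bins, the reading most consistent with
"average density of the subpopulation of bins". Real-data noise factors
cannot be reproduced without the deposited libraries, so the estimator is
validated by parameter recovery on constructed mixtures (ratios
0.25–1.5 recovered within 5 % at 10³–10⁴ bins).

**Broad-scale tracks** are binned, optionally scaled by `r`, smoothed with
a unit-sum Hann window (default 10 bins) and median-subtracted over all
genome bins, zeros included. Edge windows are truncated and renormalised,
so constant tracks pass through unchanged. An even window length centres
the kernel half a bin to the left; the default of 10 keeps that convention
rather than silently changing the window width.

## 3. Signal analysis

**Binning** maps 1-based position `p` to bin `floor((p − 1) / width)` —
stated explicitly because off-by-one conventions here silently shift every
downstream plot. Binning and Hann smoothing both conserve total signal
(before median subtraction).

**Aggregation** around loci divides the summed, optionally
orientation-flipped window signal by the number of contributing loci.
Minus-strand loci contribute with negated offsets and swapped strands, so
"same strand as the gene" keeps its meaning. Loci whose window leaves the
contig are dropped and counted in a message.

**Strand cross-correlation.** For each offset `d ∈ [−100, 100]`, Watson
position `w` is paired with Crick position `w + d`; positive `d` means
Crick lies rightward, matching 5′-overhang geometry. Only sites with
signal above `min_threshold` on both strands enter the Pearson
correlation, and the read fraction per offset is normalised after that
filter (the alternative, normalising before filtering, is not
distinguishable from the published description; filtering first matches
the counts the correlation actually uses). An `n`-nt overhang peaks at
`d = n − 1`; ties in the argmax are all reported, though unimodal
simulations never produce them.

**Peak calling** uses an inclusive threshold (`value ≥ 0.05` HpM by
default) so boundary sites at exactly the printed cutoff are kept.

**Intergenic classification** merges overlapping gene extents first and
labels each gap by the strands of the genes that form its boundaries:
`(−,+)` divergent, `(+,−)` convergent, otherwise tandem. Contig ends, and
all gaps on contigs with fewer than two gene extents, are `unlabelled`.
The output partitions every base exactly once.

**Density-adaptive smoothing** (`density_smooth()`) is a display heuristic,
not an inferential estimator: each hit is spread by a Gaussian whose
bandwidth is `b0 / (1 + local density in a 50-bp window)`, each hit's
discrete kernel normalised to its own mass. The original fine-scale
variable smoother is only available as an external reference, so this
stand-in is deliberately simple and explicitly non-normative; dense
clusters stay sharp, isolated hits spread wide, and total mass is
conserved exactly.

## 4. Cognate fractionation

Watson and Crick positions are paired at the overhang offset (3 for Top2,
1 for Spo11); a position with signal on one strand only becomes a site
with a zero on the other strand — these are exactly the candidate
single-strand-break signatures, so they must not be dropped. With a fixed
offset the pairing is a bijection on coordinates; no greedy matching is
needed.

**The exact test.** Under H₀ (equal Poisson rates, equal exposure), the
Watson count conditional on the total `n = w + c` is Binomial(n, ½). The
two-sided p-value follows the minimum-likelihood rule — the summed
probability of all outcomes no more likely than the observed one — which
for this symmetric null collapses to `min(1, 2·P[X ≤ min(w, c)])`. The two
readings (minimum-likelihood vs doubled tail) coincide here; the package
fixes the rule anyway so the convention is explicit. The implementation is
the closed form; the test suite checks it against full enumeration for
every outcome with totals ≤ 30.

**Classification.** Sites with `total < 8` are excluded (too little power
to call disparity); among tested sites `p ≤ 0.05` is noncognate,
`p > 0.95` highly cognate, the remainder cognate. No multiple-testing
correction is applied — the per-site α is the published classification
rule, not an inference about any single site. Because the conditional test
is discrete and conservative at small totals, the false-noncognate rate on
fully cognate data sits below the nominal 5 % (the suite bounds it at
5.5 % over 10⁵ simulated sites with λ ≥ 4).

**Reference datasets.** The randomised control permutes the multiset of
per-position counts within each strand over that strand's *occupied*
positions only — shuffling onto empty coordinates would change the
marginal sparsity, not just the pairing. The fully cognate simulation sets
`λ = (w + c) / 2` per site from the observed raw counts (not HpM: the
Poisson model lives on the count scale) and draws both strands
independently from Poisson(λ). Published class percentages are not printed
numerically, so the simulation is validated by its type-I bound and by the
ordering `simulated ≥ observed ≥ randomised` on correlated data rather
than by value matching.

## 5. Sequence bias around the dyad

Per-site totals are first equalised to a common total (default 100)
without changing the Watson:Crick ratio, so strong sites do not dominate
the composition and the two strand weights encode the site's disparity.
The dyad axis — the two-fold symmetry centre of the cut, the midpoint of
the overhang's central two base pairs — is `watson_pos + (overhang − 1)/2`,
a half-integer. One-strand-only sites get the inferred dyad at the same
relative position; for Crick-only sites the mirrored convention gives the
identical coordinate, so no separate rule is needed.

Positions are labelled with signed offsets and no zero: −1/+1 are the two
central overhang bases, and for a 4-nt overhang the base 5′ of the Watson
scissile phosphate sits at −3. The default half-window is ±20 bp; the
window is a parameter because the method description quotes both ±20 bp
and a 32-bp display window.

Each site contributes its top-strand window with the Watson weight and the
reverse-complemented window (mirrored offsets, complemented bases) with
the Crick weight; the pooled matrix is therefore already in top-strand
orientation, and a palindromic preference appears rotationally symmetric
about the dyad. `N` bases are masked from numerator and denominator at the
affected position. Log₂ deviations are taken against each base's mean
fraction over the whole window (a position-local average would absorb the
very signal being measured); zero fractions are floored at a configurable
pseudo-fraction (default 10⁻⁴) before logging.

## 6. The synthetic-data generator

The generator exists so that every stage can be tested against a known
truth. It emulates:

- i.i.d. random genomes at a target GC (default 0.38, budding-yeast-like);
- cleavage sites placed uniformly with gamma-distributed intensities
  (default shape 1.5, scale 10 — mean 15 events per site, a realistic
  dynamic range between cold and hot sites);
- per-event outcomes: DSB (Watson hit at `p`, Crick at
  `p + overhang − 1`), or single-strand breaks on one strand, with
  per-site probabilities so strand-biased (noncognate-like) sites can be
  planted;
- sonication: Read-2 sits at the far end of a fragment drawn from a
  truncated normal (default 350 ± 50 bp, minimum 150), extending away
  from the protein-linked end — reproducing the adapter asymmetry;
- error injection: terminal mismatch runs at Read-1's 5′ end (exercising
  the ambiguity filter, with CIGAR/MD kept consistent) and mid-read 1-bp
  deletions (exercising CIGAR scoring);
- spike-genome mixing at a target read fraction;
- an optional planted base preference at a dyad-relative offset, planted
  symmetrically (complement at the mirrored offset) with configurable
  strength; where neighbouring site windows overlap, the later site's
  assignment wins.

It does **not** model base-call qualities, PCR duplicates,
sequence-dependent sonication bias, enrichment efficiency, or alignment
error: reads are emitted as already-aligned records. Passing round-trip
tests therefore demonstrates the correctness of the coordinate arithmetic
and filters, not robustness to aligner artefacts on real data.

Sites are kept `margin` bp (default 2000) from contig ends and at least
`overhang + 1` bp apart, so truth coordinates never collide and default
fragments always fit — out-of-range fragments are resampled with bounded
retries and otherwise dropped with a message. All generators are
deterministic given a seed, and seeded code paths restore the caller's RNG
state.

## 7. Problem sizes and reproducibility

The shipped test suite and acceptance script run entirely on synthetic
data at desk scale, chosen to make the statistics decisive while staying
quick: 100–200-kb genomes, 150–1000 sites, gamma intensities with means
15–20, 10⁴–10⁵ sites for type-I calibration of the exact test, and 2000
random CIGARs against the base-by-base oracle. Every stochastic stage
takes an explicit seed; `run_pipeline()` re-runs byte-identically from the
same configuration, which the suite asserts on a smoke config.

## 8. Known limitations

- The fine-scale variable-bandwidth smoother is a declared stand-in (see
  §3); its outputs should not be compared numerically to the original.
- The noise estimator's `low_fraction` default (0.5) is a reproducible
  convention, not a fitted value; samples whose signal occupies most of
  the genome would need a smaller fraction.
- `DOUBLE` library mode changes only the ambiguity filtering, mirroring
  the described behaviour; Read-2 5′ coordinates are never emitted as
  break positions.
- Percentages in the cognate comparison depend on sequencing depth through
  the `min_total` exclusion; comparisons are only meaningful between
  datasets fractionated with identical parameters (enforced by
  `summarize_fractions()`).
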