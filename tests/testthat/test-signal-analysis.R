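test_that("binning follows floor((pos-1)/width) and conserves signal", {
  tr <- tibble::tibble(contig = "c", pos = c(49L, 50L, 51L), value = c(1, 2, 4))
  b <- bin_track(tr, 50)
  expect_equal(b$bin[b$value == 3], 0) # 49 and 50 share bin 0
  expect_equal(b$bin[b$value == 4], 1) # 51 starts bin 1
  expect_equal(sum(b$value), sum(tr$value))
  # zero-filled bins with a genome
  b2 <- bin_track(tr, 50, genome = c(c = 500))
  expect_equal(nrow(b2), 10L)
  expect_equal(sum(b2$value), sum(tr$value))
  expect_equal(nrow(bin_track(tr[0, ], 50, genome = c(c = 500))), 10L)
})

test_that("Hann smoothing is mass-conserving, symmetric and identity-safe", {
  x <- c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  expect_equal(hann_smooth(x, 1), x)
  expect_equal(hann_smooth(rep(4.2, 25), 10), rep(4.2, 25))
  sm <- hann_smooth(x, 5)
  expect_equal(sum(sm), 1) # interior impulse: mass conserved
  expect_equal(sm[4:8], hann_kernel(5), tolerance = 1e-12) # kernel shape
  # symmetric input, odd window: output invariant under reversal
  y <- c(0, 1, 3, 7, 3, 1, 0)
  expect_equal(hann_smooth(y, 5), rev(hann_smooth(rev(y), 5)))
  expect_equal(sum(hann_kernel(10)), 1)
})

test_that("density-adaptive smoothing conserves mass and widens when sparse", {
  lone <- tibble::tibble(pos = 100L, value = 2)
  dense <- tibble::tibble(pos = 100:104, value = rep(2, 5))
  s_lone <- density_smooth(lone, b0 = 5)
  s_dense <- density_smooth(dense, b0 = 5)
  expect_equal(sum(s_lone$value), 2)
  expect_equal(sum(s_dense$value), 10)
  # isolated hit is spread wider than a hit inside a dense cluster
  peak_lone <- max(s_lone$value) / sum(s_lone$value)
  peak_dense <- max(s_dense$value) / 2 # per-hit sharpness
  expect_lt(peak_lone, peak_dense)
  expect_error(density_smooth(lone[0, ]), "nonempty")
})

test_that("locus aggregation equals a naive per-locus loop", {
  set.seed(61)
  tr <- tibble::tibble(
    contig = "c",
    pos = sample(1000:2000, 120),
    strand = sample(c("watson", "crick"), 120, replace = TRUE),
    value = runif(120, 0, 5)
  )
  loci <- tibble::tibble(
    contig = "c", pos = c(1200L, 1500L, 1800L),
    strand = c("+", "-", "+")
  )
  flank <- 50
  prof <- aggregate_loci(tr, loci, flank = flank, orient = TRUE)
  # naive oracle
  for (off in c(-50L, -7L, 0L, 13L, 50L)) {
    for (st in c("watson", "crick")) {
      tot <- 0
      for (i in seq_len(nrow(loci))) {
        if (loci$strand[i] == "-") {
          p <- loci$pos[i] - off
          st_i <- ifelse(st == "watson", "crick", "watson")
        } else {
          p <- loci$pos[i] + off
          st_i <- st
        }
        tot <- tot + sum(tr$value[tr$pos == p & tr$strand == st_i])
      }
      expect_equal(
        prof$mean_value[prof$offset == off & prof$strand == st],
        tot / nrow(loci),
        info = paste(off, st)
      )
    }
  }
  expect_equal(attr(prof, "n_loci"), 3L)
})

test_that("minus-strand loci contribute mirrored windows", {
  tr <- tibble::tibble(contig = "c", pos = c(98L, 99L, 100L, 101L),
                       strand = "watson", value = c(0, 1, 0, 7))
  plus <- aggregate_loci(tr, tibble::tibble(contig = "c", pos = 100L,
                                            strand = "+"), flank = 2)
  minus <- aggregate_loci(tr, tibble::tibble(contig = "c", pos = 100L,
                                             strand = "-"), flank = 2)
  pw <- dplyr::filter(plus, strand == "watson")
  mc <- dplyr::filter(minus, strand == "crick")
  expect_equal(pw$mean_value, rev(mc$mean_value))
})

test_that("out-of-bounds locus windows are dropped with a message", {
  tr <- tibble::tibble(contig = "c", pos = 50L, strand = "watson", value = 1)
  loci <- tibble::tibble(contig = "c", pos = c(10L, 50L, 500L))
  expect_message(
    prof <- aggregate_loci(tr, loci, flank = 20, genome = c(c = 400)),
    "dropped 2"
  )
  expect_equal(attr(prof, "n_loci"), 1L)
  expect_error(
    suppressMessages(
      aggregate_loci(tr, loci[c(1, 3), ], flank = 20, genome = c(c = 400))
    ),
    "no locus window"
  )
})

test_that("stratification matches a sort-and-slice oracle", {
  loci <- tibble::tibble(contig = "c", pos = 1:8 * 100L,
                         covariate = c(5, 1, 9, 3, 7, 2, 8, 4))
  s <- stratify_loci(loci, 4)
  expect_equal(as.vector(table(s$stratum)), rep(2L, 4))
  # lowest covariates in stratum 1
  expect_setequal(s$covariate[s$stratum == 1], c(1, 2))
  expect_setequal(s$covariate[s$stratum == 4], c(8, 9))
  # constant covariate: stable input-order split
  const <- tibble::tibble(contig = "c", pos = 1:5 * 10L, covariate = 1)
  sc <- stratify_loci(const, 2)
  expect_equal(sc$stratum, c(1L, 1L, 1L, 2L, 2L))
  # random covariates vs brute-force oracle
  set.seed(62)
  rnd <- tibble::tibble(contig = "c", pos = 1:103 * 7L,
                        covariate = runif(103))
  k <- 4
  sr <- stratify_loci(rnd, k)
  sizes <- rep(103L %/% k, k) + as.integer(seq_len(k) <= 103L %% k)
  oracle <- integer(103)
  oracle[order(rnd$covariate)] <- rep(seq_len(k), times = sizes)
  expect_equal(sr$stratum, oracle)
  expect_message(
    stratify_loci(
      tibble::tibble(contig = "c", pos = 1:4 * 10L,
                     covariate = c(1, NA, 3, 4)), 2),
    "missing covariate"
  )
})

test_that("autocorrelation recovers closed-form structure", {
  # s = 0 is always 1
  set.seed(63)
  b <- tibble::tibble(contig = "c", bin = 0:499, value = runif(500))
  ac <- autocorrelate(b, 5)
  expect_equal(ac$r[ac$separation == 0], 1)
  # i.i.d. noise: |r| below the 3/sqrt(n) sampling bound for s > 0
  expect_true(all(abs(ac$r[ac$separation > 0]) < 3 / sqrt(ac$n_pairs[ac$separation > 0])))
  # period-2 alternation: r(2) ~ 1, r(1) ~ -1
  alt <- tibble::tibble(contig = "c", bin = 0:199,
                        value = rep(c(0, 10), 100) + runif(200, 0, 0.01))
  ac2 <- autocorrelate(alt, 2)
  expect_gt(ac2$r[ac2$separation == 2], 0.99)
  expect_lt(ac2$r[ac2$separation == 1], -0.99)
  # zero-variance series flagged
  expect_warning(
    acz <- autocorrelate(
      tibble::tibble(contig = "c", bin = 0:9, value = rep(1, 10)), 1),
    "undefined"
  )
  expect_true(all(is.na(acz$r)))
  expect_error(autocorrelate(b[1:2, ], 1), "at least 3")
})

test_that("strand cross-correlation peaks at overhang minus one", {
  g <- make_genome(6e4, seed = 71)
  for (oh in c(2L, 4L)) {
    mod <- cleavage_model(g, 150, overhang = oh, lambda_shape = 4,
                          lambda_scale = 5, margin = 1000, seed = 72 + oh)
    truth <- simulate_break_map(mod, seed = 73 + oh)
    oc <- strand_cross_correlation(truth, -20:20)
    expect_equal(peak_offset(oc), oh - 1L)
    expect_equal(sum(oc$read_fraction, na.rm = TRUE), 1)
  }
})

test_that("cross-correlation is undefined without both strands", {
  w_only <- break_map(tibble::tibble(
    contig = "c", pos = c(10L, 20L, 30L), strand = "watson",
    count = c(3L, 4L, 5L)
  ))
  oc <- strand_cross_correlation(w_only, -5:5)
  expect_true(all(is.na(oc$r)))
})

test_that("IGR classification labels gaps by flanking orientations", {
  genes <- tibble::tibble(
    contig = "c",
    start = c(100L, 300L, 500L, 700L),
    end = c(200L, 400L, 600L, 800L),
    strand = c("-", "+", "+", "-")
  )
  cls <- classify_igrs(genes, genome = c(c = 1000))
  lab <- function(s) cls$label[cls$start == s]
  expect_equal(lab(201), "IGR_divergent")  # (-,+)
  expect_equal(lab(401), "IGR_tandem")     # (+,+)
  expect_equal(lab(601), "IGR_convergent") # (+,-)
  expect_equal(lab(1), "unlabelled")
  expect_equal(lab(801), "unlabelled")
  # partition: every base covered exactly once
  covered <- unlist(mapply(seq, cls$start, cls$end))
  expect_equal(sort(covered), 1:1000)
  # overlapping genes are merged before classification
  ov <- tibble::tibble(
    contig = "c", start = c(100L, 150L, 500L), end = c(250L, 300L, 600L),
    strand = c("+", "+", "-")
  )
  cls2 <- classify_igrs(ov, genome = c(c = 700))
  expect_equal(cls2$end[cls2$label == "intragenic"][1], 300L)
  expect_equal(cls2$label[cls2$start == 301], "IGR_convergent") # (+,-)
})

test_that("region density and box stats match brute-force quantiles", {
  tr <- tibble::tibble(contig = "c", pos = 1:100, value = rep(2, 100))
  regions <- tibble::tibble(contig = "c", start = c(1L, 51L), end = c(50L, 100L))
  rd <- region_density(tr, regions)
  expect_equal(rd$density, c(2, 2))
  peak <- tibble::tibble(contig = "c", pos = 25L, value = 10)
  expect_equal(region_density(peak, regions)$density, c(10 / 50, 0))
  expect_error(
    region_density(tr, tibble::tibble(contig = "c", start = 10L, end = 9L)),
    "length"
  )
  set.seed(64)
  x <- rgamma(200, 2, 1)
  bs <- box_stats(x)
  qs <- quantile(x, c(.25, .5, .75), names = FALSE)
  expect_equal(c(bs$q1, bs$median, bs$q3), qs)
  iqr <- qs[3] - qs[1]
  expect_equal(bs$whisker_lo, min(x[x >= qs[1] - 1.5 * iqr]))
  expect_equal(bs$whisker_hi, max(x[x <= qs[3] + 1.5 * iqr]))
})

test_that("peak calling keeps sites exactly at the threshold", {
  tr <- tibble::tibble(
    contig = "c", pos = c(10L, 20L, 30L),
    strand = c("watson", "crick", "watson"),
    hpm = c(0.049, 0.05, 0.2)
  )
  pk <- call_peaks(tr, threshold = 0.05, combine_strands = FALSE)
  expect_setequal(pk$pos, c(20L, 30L))
  expect_equal(nrow(call_peaks(tr, threshold = 10)), 0L)
  # strands pooled by default (0.049 + 0 stays out; brute-force scan oracle)
  tr2 <- tibble::tibble(
    contig = "c", pos = c(10L, 10L, 40L),
    strand = c("watson", "crick", "watson"),
    hpm = c(0.03, 0.03, 0.01)
  )
  pooled <- tapply(tr2$hpm, tr2$pos, sum)
  expect_equal(call_peaks(tr2, 0.05)$pos,
               as.integer(names(pooled)[pooled >= 0.05]))
})

test_that("covariate quantification reports Pearson and Spearman", {
  tr <- tibble::tibble(contig = "c", pos = c(100L, 200L, 300L, 400L),
                       strand = "watson", value = c(1, 2, 3, 4))
  loci <- tibble::tibble(contig = "c", pos = c(100L, 200L, 300L, 400L),
                         covariate = c(10, 100, 1000, 10000))
  q <- quantify_vs_covariate(tr, loci, window = c(0, 10))
  expect_equal(q$spearman_rs, 1)
  expect_equal(q$pearson_r, 1) # signal linear in the log covariate
  # monotone nonlinear covariate: rank correlation stays 1, Pearson drops
  loci2 <- dplyr::mutate(loci, covariate = c(1, 10, 11, 12))
  q2 <- quantify_vs_covariate(tr, loci2, window = c(0, 10))
  expect_equal(q2$spearman_rs, 1)
  expect_lt(q2$pearson_r, 1)
  # permuted covariate: small |r|
  set.seed(65)
  trn <- tibble::tibble(contig = "c", pos = 1:200 * 10L, strand = "watson",
                        value = runif(200))
  locn <- tibble::tibble(contig = "c", pos = 1:200 * 10L,
                         covariate = runif(200) + 0.1)
  qn <- quantify_vs_covariate(trn, locn, window = c(0, 5))
  expect_lt(abs(qn$pearson_r), 0.2)
  expect_message(
    quantify_vs_covariate(tr, dplyr::mutate(loci, covariate = c(-1, 2, 3, 4)),
                          window = c(0, 10)),
    "nonpositive"
  )
  expect_equal(glance(q)$n_loci, 4L)
  expect_equal(nrow(tidy(q)), 4L)
})
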