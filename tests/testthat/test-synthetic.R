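test_that("genome generation hits the target GC and is seed-deterministic", {
  g1 <- make_genome(20000, gc = 0.5, seed = 1)
  g2 <- make_genome(20000, gc = 0.5, seed = 1)
  expect_equal(as.character(g1), as.character(g2))
  freq <- Biostrings::alphabetFrequency(g1)[1, c("A", "C", "G", "T")]
  gc_obs <- sum(freq[c("C", "G")]) / sum(freq)
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 20000))
  g3 <- make_genome(5000, gc = 1, seed = 2)
  f3 <- Biostrings::alphabetFrequency(g3)[1, c("A", "T")]
  expect_equal(sum(f3), 0L)
  expect_false(identical(as.character(make_genome(5000, seed = 3)),
                         as.character(make_genome(5000, seed = 4))))
})

test_that("planted preferences appear at the configured strength", {
  g <- make_genome(1e5, gc = 0.5, seed = 11)
  for (strength in c(0, 1)) {
    mod <- cleavage_model(g, 200, overhang = 4, seed = 12,
                          planted_preference = list(base = "C", offset = -3,
                                                    strength = strength))
    g2 <- plant_preference(g, mod, seed = 13)
    # offset -3 with a 4-nt overhang sits 1 bp left of the Watson 5' base
    coords <- mod$sites$pos - 1
    bases <- strsplit(as.character(g2[[1]]), "")[[1]][coords]
    if (strength == 1) {
      # a later site's forward plant may overwrite a mirror of the site
      # before it; forward coordinates themselves are planted last
      chars <- strsplit(as.character(g2[[1]]), "")[[1]]
      expect_true(all(chars[coords] == "C"))
      mirror_pos <- mod$sites$pos + 4
      clear <- !mirror_pos %in% coords
      expect_true(all(chars[mirror_pos[clear]] == "G"))
    } else {
      expect_equal(as.character(g2), as.character(g)) # strength 0: identity
    }
  }
  # strength 0.5: frequency ~ 0.5 + 0.5 * background
  mod5 <- cleavage_model(g, 500, overhang = 4, seed = 14,
                         planted_preference = list(base = "C", offset = -3,
                                                   strength = 0.5))
  g5 <- plant_preference(g, mod5, seed = 15)
  b5 <- strsplit(as.character(g5[[1]]), "")[[1]][mod5$sites$pos - 1]
  p_exp <- 0.5 + 0.5 * 0.25
  expect_lt(abs(mean(b5 == "C") - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 500))
})

test_that("break-map simulation respects overhang geometry and SSB extremes", {
  g <- make_genome(50000, seed = 21)
  # no SSB: equal Watson/Crick counts at overhang - 1 spacing
  mod <- cleavage_model(g, 40, overhang = 4, margin = 1000, seed = 22)
  truth <- simulate_break_map(mod, seed = 23)
  w <- truth[truth$strand == "watson", ]
  c_ <- truth[truth$strand == "crick", ]
  expect_equal(w$count, c_$count)
  expect_equal(c_$pos - w$pos, rep(3L, nrow(w)))
  # ssb_w = 1: Crick strand empty
  mod_w <- cleavage_model(g, 40, overhang = 4, ssb_w = 1, margin = 1000,
                          seed = 24)
  truth_w <- simulate_break_map(mod_w, seed = 25)
  expect_equal(sum(truth_w$strand == "crick"), 0L)
  # spo11-like: spacing 1
  mod2 <- cleavage_model(g, 40, overhang = 2, margin = 1000, seed = 26)
  t2 <- simulate_break_map(mod2, seed = 27)
  w2 <- t2[t2$strand == "watson", ]
  c2 <- t2[t2$strand == "crick", ]
  expect_equal(c2$pos - w2$pos, rep(1L, nrow(w2)))
})

test_that("error-free simulated reads invert the mapper exactly", {
  g <- make_genome(1e5, seed = 31)
  mod <- cleavage_model(g, 60, overhang = 4, seed = 32)
  truth <- simulate_break_map(mod, seed = 33)
  recs <- simulate_read_pairs(truth, g, seed = 34)
  sam <- tempfile(fileext = ".sam")
  write_sam(recs, g, sam)
  res <- map_read_pairs(read_alignments(sam))
  a <- dplyr::arrange(tibble::as_tibble(res$map), pos, strand)
  b <- dplyr::arrange(tibble::as_tibble(truth), pos, strand)
  expect_equal(a$pos, b$pos)
  expect_equal(a$count, b$count)
  expect_equal(a$strand, b$strand)
  expect_equal(res$stats$pairs_seen, sum(truth$count))
  expect_equal(res$stats$pairs_counted, sum(truth$count))
})

test_that("injected terminal mismatches remove exactly those pairs", {
  g <- make_genome(8e4, seed = 41)
  mod <- cleavage_model(g, 50, overhang = 4, seed = 42)
  truth <- simulate_break_map(mod, seed = 43)
  recs <- simulate_read_pairs(truth, g, terminal_mismatch_prob = 0.25,
                              seed = 44)
  res <- map_read_pairs(recs)
  n_err <- attr(recs, "n_error_pairs")
  expect_gt(n_err, 0)
  expect_equal(res$stats$pairs_ambiguous_end, n_err)
  expect_equal(res$stats$pairs_counted, sum(truth$count) - n_err)
  # every surviving position is a truth position with count <= truth count
  joined <- dplyr::left_join(
    tibble::as_tibble(res$map), tibble::as_tibble(truth),
    by = c("contig", "pos", "strand"), suffix = c("_got", "_true")
  )
  expect_true(all(!is.na(joined$count_true)))
  expect_true(all(joined$count_got <= joined$count_true))
  # probability 1 filters everything
  recs_all <- simulate_read_pairs(truth, g, terminal_mismatch_prob = 1,
                                  seed = 45)
  res_all <- map_read_pairs(recs_all)
  expect_equal(res_all$stats$pairs_counted, 0L)
})

test_that("injected mid-read deletions keep 5' calls on target", {
  g <- make_genome(8e4, seed = 46)
  mod <- cleavage_model(g, 50, overhang = 4, seed = 47)
  truth <- simulate_break_map(mod, seed = 48)
  recs <- simulate_read_pairs(truth, g, indel_prob = 1, seed = 49)
  expect_true(all(grepl("1D", recs$cigar[recs$flag %in% c(99L, 83L)])))
  res <- map_read_pairs(recs)
  a <- dplyr::arrange(tibble::as_tibble(res$map), pos, strand)
  b <- dplyr::arrange(tibble::as_tibble(truth), pos, strand)
  expect_equal(a$pos, b$pos)
  expect_equal(a$count, b$count)
})

test_that("simulated flags encode the strand of origin", {
  g <- make_genome(5e4, seed = 51)
  mod <- cleavage_model(g, 30, overhang = 4, seed = 52)
  truth <- simulate_break_map(mod, seed = 53)
  recs <- simulate_read_pairs(truth, g, seed = 54)
  r1 <- recs[bitwAnd(recs$flag, 64L) > 0, ]
  called <- call_five_prime(r1$pos, r1$cigar, r1$flag == 83L)
  w_truth <- truth$pos[truth$strand == "watson"]
  c_truth <- truth$pos[truth$strand == "crick"]
  expect_true(all(called$pos[called$strand == "watson"] %in% w_truth))
  expect_true(all(called$pos[called$strand == "crick"] %in% c_truth))
})

test_that("spike mixing realises the requested fraction", {
  g <- make_genome(5e4, seed = 61, name = "primary")
  gs <- make_genome(5e4, seed = 62, name = "spike")
  mp <- cleavage_model(g, 60, lambda_shape = 6, lambda_scale = 6, seed = 63)
  ms <- cleavage_model(gs, 60, lambda_shape = 6, lambda_scale = 6, seed = 64)
  rp <- simulate_read_pairs(simulate_break_map(mp, seed = 65), g, seed = 66)
  rs <- simulate_read_pairs(simulate_break_map(ms, seed = 67), gs, seed = 68)
  mixed <- mix_spike(rp, rs, fraction = 0.0099, seed = 69)
  si <- mixed$spike
  expect_equal(si$reads_primary + si$reads_spike,
               length(unique(mixed$records$qname)))
  realized <- si$reads_spike / (si$reads_primary + si$reads_spike)
  expect_lt(abs(realized - 0.0099), 0.002)
  # same seed reproduces the mix
  mixed2 <- mix_spike(rp, rs, fraction = 0.0099, seed = 69)
  expect_equal(mixed$records, mixed2$records)
})

test_that("calibration recovers shared truth across spike recoveries", {
  # same primary cleavage truth, different spike recovery fractions
  g <- make_genome(5e4, seed = 71, name = "primary")
  mod <- cleavage_model(g, 50, lambda_shape = 8, lambda_scale = 6, seed = 72)
  truth <- simulate_break_map(mod, seed = 73)
  map <- break_map(tibble::as_tibble(truth))
  t1 <- spike_calibrate(to_hpm(map), 0.008)
  t2 <- spike_calibrate(to_hpm(map), 0.012)
  expect_equal(t1$hpm * 0.008, t2$hpm * 0.012)
})
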