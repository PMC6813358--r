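# Ground-truth simulation: genomes, cleavage models, break maps and
# paired-end reads. The generator mirrors the library design: Read-1's 5'
# terminus is the protein-linked end; Read-2 marks the sonication-derived
# fragment end on the opposite strand. Double-strand cleavage leaves a
# configurable 5' overhang (4 nt Top2-like, 2 nt Spo11-like); single-strand
# events emit a read pair on one strand only.

#' Generate a random genome
#'
#' I.i.d. bases at a target GC content; deterministic for a fixed seed.
#'
#' @param length Contig length in bp (>= 1000).
#' @param gc Target GC fraction (default 0.38, budding-yeast-like).
#' @param seed Integer seed.
#' @param name Contig name.
#' @return A `Biostrings::DNAStringSet` with one contig.
#' @export
make_genome <- function(length, gc = 0.38, seed = NULL, name = "chrS") {
  stopifnot(length >= 1000)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- with_seed(seed, {
    paste0(sample(DNA_BASES, length, replace = TRUE, prob = probs),
           collapse = "")
  })
  out <- Biostrings::DNAStringSet(seq)
  names(out) <- name
  out
}

#' Define a ground-truth cleavage model
#'
#' Sites are placed uniformly (without replacement) within the contig,
#' keeping `margin` bp clear of the ends so simulated fragments always fit.
#' Site intensities are gamma-distributed, giving the broad dynamic range of
#' real cleavage maps. Each cleavage event is a double-strand break with
#' probability `1 - ssb_w - ssb_c`, or a single-strand break on the Watson
#' (`ssb_w`) or Crick (`ssb_c`) strand alone.
#'
#' @param genome Genome the model lives on.
#' @param n_sites Number of cleavage sites.
#' @param overhang 5' overhang length in nt: 4 (Top2-like) or 2 (Spo11-like),
#'   any >= 1 accepted.
#' @param ssb_w,ssb_c Per-event single-strand-break probabilities, scalars
#'   or per-site vectors recycled to `n_sites` (`ssb_w + ssb_c <= 1`
#'   elementwise). Strand-biased noncognate sites are modelled by giving a
#'   site a one-sided SSB probability.
#' @param lambda_shape,lambda_scale Gamma parameters of site intensity
#'   (defaults shape 1.5, scale 10: mean 15 events per site at depth 1).
#' @param margin Minimum distance of a site from either contig end
#'   (default 2000 bp, ample for default fragment lengths).
#' @param planted_preference Optional `list(base, offset, strength)` for
#'   [plant_preference()].
#' @param seed Integer seed.
#' @return A `cleavage_model` list: `$sites` (tibble `contig`, `pos`,
#'   `lambda`, `ssb_w_prob`, `ssb_c_prob`), `$overhang`,
#'   `$planted_preference`.
#' @export
cleavage_model <- function(genome, n_sites, overhang = 4, ssb_w = 0,
                           ssb_c = 0, lambda_shape = 1.5, lambda_scale = 10,
                           margin = 2000, planted_preference = NULL,
                           seed = NULL) {
  ssb_w <- rep_len(ssb_w, n_sites)
  ssb_c <- rep_len(ssb_c, n_sites)
  stopifnot(overhang >= 1, all(ssb_w >= 0), all(ssb_c >= 0),
            all(ssb_w + ssb_c <= 1))
  lens <- contig_lengths(genome)
  ct <- names(lens)[1]
  lo <- margin + 1
  hi <- lens[[ct]] - margin - overhang
  if (hi - lo + 1 < n_sites * (overhang + 1)) {
    abort("genome too short for the requested number of sites")
  }
  sites <- with_seed(seed, {
    # keep sites at least `overhang` apart so truth positions never collide
    cand <- sort(sample(seq.int(as.integer(lo), as.integer(hi),
                                by = as.integer(overhang + 1)), n_sites))
    tibble(
      contig = ct,
      pos = cand,
      lambda = rgamma(n_sites, shape = lambda_shape, scale = lambda_scale),
      ssb_w_prob = ssb_w,
      ssb_c_prob = ssb_c
    )
  })
  structure(
    list(sites = sites, overhang = overhang,
         planted_preference = planted_preference),
    class = "cleavage_model"
  )
}

#' @export
print.cleavage_model <- function(x, ...) {
  cat(sprintf(
    "<cleavage_model> %d sites, %d-nt overhang, P(ssb) = %.2f + %.2f, mean lambda %.1f\n",
    nrow(x$sites), x$overhang,
    x$sites$ssb_w_prob[1], x$sites$ssb_c_prob[1], mean(x$sites$lambda)
  ))
  invisible(x)
}

#' Plant a base preference at a fixed offset from every dyad
#'
#' Rewrites the genome so that, at each model site, the base at the given
#' dyad-relative offset (no-zero convention: -1/+1 are the central overhang
#' bases) is the preferred base with probability `strength`. The complement
#' is planted at the mirrored offset, respecting the two-fold symmetry of a
#' double-strand cleavage site. Overlapping sites are rewritten in site
#' order, so a later site wins.
#'
#' @param genome Genome to modify.
#' @param model A [cleavage_model()] whose `planted_preference` is
#'   `list(base, offset, strength)`; e.g. `list(base = "C", offset = -3,
#'   strength = 0.8)` plants the cytosine preference 5' of the Watson
#'   scissile phosphate of a 4-nt-overhang site.
#' @param seed Integer seed.
#' @return The modified genome (`DNAStringSet`).
#' @export
plant_preference <- function(genome, model, seed = NULL) {
  pref <- model$planted_preference
  if (is.null(pref)) {
    abort("model has no planted_preference")
  }
  stopifnot(pref$base %in% DNA_BASES, pref$offset != 0,
            pref$strength >= 0, pref$strength <= 1)
  g <- genome_as_character(genome)
  dyad <- model$sites$pos + (model$overhang - 1) / 2
  coord_at <- function(off) {
    # offset -> reference coordinate under the no-zero labelling
    if (off > 0) dyad + off - 0.5 else dyad + off + 0.5
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  with_seed(seed, {
    for (ct in unique(model$sites$contig)) {
      idx <- which(model$sites$contig == ct)
      s <- strsplit(g[[ct]], "")[[1]]
      hit <- rbinom(length(idx), 1, pref$strength) == 1
      fwd <- coord_at(pref$offset)[idx]
      rev_ <- coord_at(-pref$offset)[idx]
      # sequential, site by site: where neighbouring windows overlap the
      # later site's assignment wins
      for (i in seq_along(idx)) {
        if (hit[i]) {
          s[fwd[i]] <- pref$base
          s[rev_[i]] <- comp[[pref$base]]
        }
      }
      g[[ct]] <- paste0(s, collapse = "")
    }
  })
  out <- Biostrings::DNAStringSet(unlist(g))
  names(out) <- names(g)
  out
}

#' Simulate a ground-truth break map from a cleavage model
#'
#' Per site, the event count is Poisson(`lambda * depth`); each event is a
#' DSB (one Watson hit at `pos` and one Crick hit at `pos + overhang - 1`),
#' a Watson-only or a Crick-only SSB, according to the model probabilities.
#'
#' @param model A [cleavage_model()].
#' @param depth Depth multiplier on the site intensities (default 1).
#' @param seed Integer seed.
#' @return A [break_map()]; `total_mapped_pairs` equals the number of hits
#'   (each hit yields exactly one read pair downstream). The per-site event
#'   table is attached as attribute `truth_sites`.
#' @export
simulate_break_map <- function(model, depth = 1, seed = NULL) {
  sites <- model$sites
  oh <- as.integer(model$overhang)
  out <- with_seed(seed, {
    n_events <- rpois(nrow(sites), sites$lambda * depth)
    p_dsb <- 1 - sites$ssb_w_prob - sites$ssb_c_prob
    split_types <- function(n, pd, pw, pc) {
      if (n == 0) return(c(0L, 0L, 0L))
      as.integer(rmultinom(1, n, c(pd, pw, pc)))
    }
    types <- mapply(split_types, n_events, p_dsb,
                    sites$ssb_w_prob, sites$ssb_c_prob)
    tibble(
      contig = sites$contig, pos = sites$pos,
      n_dsb = types[1, ], n_ssb_w = types[2, ], n_ssb_c = types[3, ]
    )
  })
  w_counts <- out$n_dsb + out$n_ssb_w
  c_counts <- out$n_dsb + out$n_ssb_c
  hits <- bind_rows(
    tibble(contig = out$contig, pos = out$pos, strand = "watson",
           count = w_counts),
    tibble(contig = out$contig, pos = out$pos + oh - 1L, strand = "crick",
           count = c_counts)
  ) |>
    filter(.data$count > 0)
  map <- break_map(hits, sample_id = "truth")
  attr(map, "truth_sites") <- out
  map
}

#' Simulate paired-end alignment records from a truth break map
#'
#' One read pair per hit. Read-1's 5' terminus sits exactly at the break
#' coordinate on the break strand (flags 99/147 for Watson, 83/163 for
#' Crick); the mate lies at the far end of a sonication fragment drawn from
#' a truncated normal, extending away from the protein-linked terminus.
#' Optional error injection: a terminal mismatch run at Read-1's 5' end
#' (exercising the ambiguity filter) or a 1-bp mid-read deletion
#' (exercising CIGAR/MD scoring); CIGAR and MD:Z stay consistent with the
#' emitted SEQ.
#'
#' @param truth A [break_map()] of true hit counts.
#' @param genome Genome the truth map lives on.
#' @param read_length Read length in bp (default 75).
#' @param fragment_mean,fragment_sd,fragment_min Fragment-length
#'   distribution (defaults 350/50/150 bp, sonication-like).
#' @param terminal_mismatch_prob Per-pair probability of a Read-1 5'
#'   mismatch run (default 0).
#' @param terminal_mismatch_run Length of the injected run (default 2, the
#'   smallest disqualifying run).
#' @param indel_prob Per-pair probability of a mid-read 1-bp deletion in
#'   Read-1 (default 0; mutually exclusive with the terminal mismatch).
#' @param mapq Reported mapping quality (default 42).
#' @param seed Integer seed.
#' @return An alignment-record tibble suitable for [write_sam()] or
#'   [map_read_pairs()], coordinate-sorted, with an attribute
#'   `n_error_pairs` counting pairs that carry an injected terminal run.
#' @export
simulate_read_pairs <- function(truth, genome, read_length = 75,
                                fragment_mean = 350, fragment_sd = 50,
                                fragment_min = 150,
                                terminal_mismatch_prob = 0,
                                terminal_mismatch_run = 2,
                                indel_prob = 0, mapq = 42, seed = NULL) {
  g <- genome_as_character(genome)
  lens <- nchar(g)
  hits <- as_tibble(truth) |>
    tidyr::uncount(.data$count) |>
    mutate(hit_id = row_number())
  rl <- as.integer(read_length)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

  with_seed(seed, {
    n <- nrow(hits)
    frag <- pmax(round(rnorm(n, fragment_mean, fragment_sd)),
                 max(fragment_min, rl + 1))
    # resample fragments that would leave the contig (bounded retries)
    for (attempt in 1:10) {
      over <- if_else(hits$strand == "watson",
                      hits$pos + frag - 1 > lens[hits$contig],
                      hits$pos - frag + 1 < 1)
      if (!any(over)) break
      frag[over] <- pmax(round(rnorm(sum(over), fragment_mean, fragment_sd)),
                         max(fragment_min, rl + 1))
    }
    dropped <- sum(over)
    if (dropped > 0) {
      inform(sprintf("dropped %d hit(s): fragment would leave the contig",
                     dropped))
      hits <- hits[!over, , drop = FALSE]
      frag <- frag[!over]
      n <- nrow(hits)
    }
    err_kind <- rep("none", n)
    u <- runif(n)
    err_kind[u < terminal_mismatch_prob] <- "mismatch"
    err_kind[u >= terminal_mismatch_prob &
               u < terminal_mismatch_prob + indel_prob] <- "indel"

    watson <- hits$strand == "watson"
    span1 <- rl + (err_kind == "indel") # a 1-bp deletion widens the ref span
    left1 <- if_else(watson, hits$pos, hits$pos - span1 + 1L)
    left2 <- if_else(watson, hits$pos + frag - rl, hits$pos - frag + 1L)
    ref1 <- substring(g[hits$contig], left1, left1 + span1 - 1L)
    ref2 <- substring(g[hits$contig], left2, left2 + rl - 1L)
    cigar1 <- rep(sprintf("%dM", rl), n)
    md1 <- rep(as.character(rl), n)
    seq1 <- ref1
    # mid-read 1-bp deletion: read skips reference base k+1
    idx_d <- which(err_kind == "indel")
    if (length(idx_d) > 0) {
      k <- rl %/% 2L
      cigar1[idx_d] <- sprintf("%dM1D%dM", k, rl - k)
      md1[idx_d] <- sprintf(
        "%d^%s%d", k, substring(ref1[idx_d], k + 1L, k + 1L), rl - k
      )
      seq1[idx_d] <- paste0(
        substring(ref1[idx_d], 1L, k),
        substring(ref1[idx_d], k + 2L, span1[idx_d])
      )
    }
    seq1[!watson] <- revcomp_chr(seq1[!watson])
    # terminal mismatch run at Read-1's 5' end; MD runs reference-left to
    # -right, so the run sits at the MD start for plus reads and the MD end
    # for minus reads
    run <- terminal_mismatch_run
    for (i in which(err_kind == "mismatch")) {
      chars <- strsplit(seq1[i], "")[[1]]
      for (j in seq_len(run)) {
        chars[j] <- sample(setdiff(DNA_BASES, chars[j]), 1)
      }
      seq1[i] <- paste0(chars, collapse = "")
      ref_chars <- strsplit(ref1[i], "")[[1]]
      md1[i] <- if (watson[i]) {
        paste0(paste0("0", ref_chars[seq_len(run)], collapse = ""), rl - run)
      } else {
        paste0(rl - run,
               paste0(ref_chars[(rl - run + 1):rl], "0", collapse = ""))
      }
    }
    seq2 <- if_else(watson, revcomp_chr(ref2), ref2)
    qn <- sprintf("sim%07d", hits$hit_id)
    out <- bind_rows(
      tibble(
        qname = qn, flag = if_else(watson, 99L, 83L), rname = hits$contig,
        pos = left1, mapq = mapq, cigar = cigar1, seq = seq1, md = md1
      ),
      tibble(
        qname = qn, flag = if_else(watson, 147L, 163L), rname = hits$contig,
        pos = left2, mapq = mapq, cigar = sprintf("%dM", rl), seq = seq2,
        md = as.character(rl)
      )
    ) |>
      arrange(.data$rname, .data$pos)
    structure(out, n_error_pairs = sum(err_kind == "mismatch"))
  })
}

#' Mix primary and spike-in alignment records at a target fraction
#'
#' Subsamples whole spike read pairs so they make up `fraction` of the
#' combined pairs (mimicking, e.g., the 1:100 molar spike-in design), and
#' reports the realised counts as a [spike_info()].
#'
#' @param records_primary,records_spike Alignment-record tibbles (mates
#'   share a `qname`).
#' @param fraction Target spike fraction of total pairs, in (0, 1).
#' @param seed Integer seed.
#' @return List with `records` (combined, spike qnames prefixed
#'   `"spike_"`) and `spike` (a [spike_info()]).
#' @export
mix_spike <- function(records_primary, records_spike, fraction, seed = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  qn_p <- unique(records_primary$qname)
  qn_s <- unique(records_spike$qname)
  target <- round(fraction / (1 - fraction) * length(qn_p))
  target <- min(target, length(qn_s))
  keep <- with_seed(seed, sample(qn_s, target))
  spike_kept <- records_spike |>
    filter(.data$qname %in% keep) |>
    mutate(qname = paste0("spike_", .data$qname))
  list(
    records = bind_rows(records_primary, spike_kept),
    spike = spike_info(
      reads_primary = length(qn_p),
      reads_spike = target
    )
  )
}
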