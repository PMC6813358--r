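# Umbrella pipeline: runs configured stages (simulate -> map -> normalise ->
# analyses) and writes artifacts plus a machine-readable JSON run log.

#' Run the break-mapping pipeline from a configuration
#'
#' Executes the configured stages in order: `simulate` (synthetic genome,
#' cleavage model, truth map, SAM records), `map` (alignments to break map,
#' bedGraph and stats outputs), `normalize` (HpM, optional spike
#' calibration), `cognate` (offset-site fractionation with randomised and
#' fully-cognate companions), `correlate_strands` (Watson-Crick offset
#' correlation) and `seqbias` (dyad-centred composition). Unknown
#' configuration keys are rejected; every stochastic stage takes an explicit
#' seed, so a config re-run reproduces its outputs byte for byte.
#'
#' @param config A named list, or path to a YAML file, with blocks
#'   `out_dir`, optionally `simulate` (`length`, `gc`, `n_sites`,
#'   `overhang`, `ssb_w`, `ssb_c`, `depth`, `seed`, ...), `map` (`sam`,
#'   `mode`, `mapq_min`, `mask_bed`), `normalize` (`spike_fraction`),
#'   `cognate` (`offset`, `alpha`, `hi`, `min_total`, `seed`),
#'   `correlate_strands` (`max_offset`, `min_threshold`), `seqbias`
#'   (`flank`, `overhang`, `classes`).
#' @return Invisibly, a list of in-memory artifacts plus the run log.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  known <- c("out_dir", "simulate", "map", "normalize", "cognate",
             "correlate_strands", "seqbias")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$out_dir)) {
    abort("config needs an out_dir")
  }
  if (!is.null(config$map) && is.null(config$map$sam) &&
        is.null(config$simulate)) {
    abort("map stage needs either map$sam or a simulate stage")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, ...) {
    log[[length(log) + 1]] <<- c(
      list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
      list(...)
    )
  }
  art <- list()

  if (!is.null(config$simulate)) {
    sc <- config$simulate
    genome <- make_genome(
      length = sc$length %||% 1e5, gc = sc$gc %||% 0.38,
      seed = sc$seed %||% 1
    )
    model <- cleavage_model(
      genome,
      n_sites = sc$n_sites %||% 100,
      overhang = sc$overhang %||% 4,
      ssb_w = sc$ssb_w %||% 0, ssb_c = sc$ssb_c %||% 0,
      margin = sc$margin %||% 2000,
      seed = (sc$seed %||% 1) + 1
    )
    truth <- simulate_break_map(model, depth = sc$depth %||% 1,
                                seed = (sc$seed %||% 1) + 2)
    records <- simulate_read_pairs(truth, genome,
                                   seed = (sc$seed %||% 1) + 3)
    sam_path <- file.path(config$out_dir, "simulated.sam")
    write_sam(records, genome, sam_path)
    fa_path <- file.path(config$out_dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fa_path)
    readr::write_tsv(model$sites, file.path(config$out_dir, "truth_sites.tsv"),
                     progress = FALSE)
    art$genome <- genome
    art$model <- model
    art$truth <- truth
    art$sam <- sam_path
    note("simulate", n_sites = nrow(model$sites), n_pairs = sum(truth$count))
  }

  if (!is.null(config$map)) {
    mc <- config$map
    sam <- mc$sam %||% art$sam
    records <- read_alignments(sam)
    res <- map_read_pairs(records,
      mode = mc$mode %||% "single",
      mapq_min = mc$mapq_min %||% 0
    )
    map <- res$map
    if (!is.null(mc$mask_bed)) {
      map <- apply_region_mask(map, read_bed(mc$mask_bed), mode = "exclude")
    }
    write_breaks_tsv(map, file.path(config$out_dir, "breaks.tsv"))
    write_bedgraph(map, file.path(config$out_dir, "watson.bedgraph"),
                   strand = "watson")
    write_bedgraph(map, file.path(config$out_dir, "crick.bedgraph"),
                   strand = "crick")
    readr::write_tsv(res$stats, file.path(config$out_dir, "mapping_stats.tsv"),
                     progress = FALSE)
    art$map <- map
    art$stats <- res$stats
    note("map", pairs_seen = res$stats$pairs_seen,
         pairs_counted = res$stats$pairs_counted)
  }

  if (!is.null(config$normalize) && !is.null(art$map)) {
    nc <- config$normalize
    track <- to_hpm(art$map)
    if (!is.null(nc$spike_fraction)) {
      track <- spike_calibrate(track, nc$spike_fraction)
    }
    write_breaks_tsv(track, file.path(config$out_dir, "hpm.tsv"))
    art$hpm <- track
    note("normalize", positions = nrow(track),
         calibration_factor = attr(track, "calibration_factor"))
  }

  if (!is.null(config$correlate_strands) && !is.null(art$map)) {
    cc <- config$correlate_strands
    oc <- strand_cross_correlation(
      art$map,
      offset_range = -(cc$max_offset %||% 100):(cc$max_offset %||% 100),
      min_threshold = cc$min_threshold %||% 0
    )
    readr::write_tsv(oc, file.path(config$out_dir, "offset_correlation.tsv"),
                     progress = FALSE)
    art$offset_correlation <- oc
    note("correlate_strands", peak_offset = peak_offset(oc)[1])
  }

  if (!is.null(config$cognate) && !is.null(art$map)) {
    gc_ <- config$cognate
    sites <- pair_offset_sites(art$map, offset = gc_$offset %||% 3)
    fr_obs <- fractionate(sites,
      alpha = gc_$alpha %||% 0.05, hi = gc_$hi %||% 0.95,
      min_total = gc_$min_total %||% 8
    )
    shuffled <- shuffle_amplitudes(art$map, seed = gc_$seed %||% 1)
    fr_rand <- fractionate(
      pair_offset_sites(shuffled, offset = gc_$offset %||% 3),
      alpha = gc_$alpha %||% 0.05, hi = gc_$hi %||% 0.95,
      min_total = gc_$min_total %||% 8
    )
    sim <- simulate_fully_cognate(sites, seed = (gc_$seed %||% 1) + 1)
    fr_sim <- fractionate(sim,
      alpha = gc_$alpha %||% 0.05, hi = gc_$hi %||% 0.95,
      min_total = gc_$min_total %||% 8
    )
    comparison <- summarize_fractions(fr_obs, fr_sim, fr_rand)
    readr::write_tsv(tidy(fr_obs), file.path(config$out_dir, "sites.tsv"),
                     progress = FALSE)
    jsonlite::write_json(comparison,
                         file.path(config$out_dir, "fractions.json"),
                         dataframe = "rows", digits = NA)
    art$fractionation <- fr_obs
    art$fraction_comparison <- comparison
    note("cognate", n_sites = nrow(sites),
         pct_cognate = glance(fr_obs)$pct_cognate)
  }

  if (!is.null(config$seqbias) && !is.null(art$fractionation) &&
        !is.null(art$genome)) {
    sb <- config$seqbias
    oh <- sb$overhang %||% 4
    keep <- sb$classes %||% c("cognate", "highly_cognate")
    sites <- tidy(art$fractionation) |>
      filter(.data$class %in% keep) |>
      normalize_site_weights() |>
      dyad_axis(overhang = oh)
    prof <- weighted_composition(sites, art$genome, flank = sb$flank %||% 20)
    readr::write_tsv(prof, file.path(config$out_dir, "composition.tsv"),
                     progress = FALSE)
    art$composition <- prof
    note("seqbias", n_sites = nrow(sites))
  }

  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  art$log <- log
  invisible(art)
}
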