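# End-to-end orchestration: simulate -> qc -> peaks -> differential ->
# regions/enrichment -> motifs/classify -> summits, with a reproducible
# manifest.

#' Pipeline run configuration
#'
#' @param output_dir where stage outputs are written.
#' @param sim a [sim_config()] (the pipeline runs on a simulated world), or
#'   `NULL` to supply `inputs` paths instead.
#' @param inputs named list of input paths (`genome`, `annotation`,
#'   `fragments` (named list stage -> replicate -> path), `input_control`,
#'   `states` (named list stage -> path), `motifs`); ignored when `sim` is
#'   given.
#' @param alpha FDR threshold for dynamics classes.
#' @param peak_config a [peak_call_config()].
#' @param bootstrap_B bootstrap iterations for state enrichment.
#' @param n_candidates enhancer candidates reported.
#' @param chip_factors named list factor -> class for simulated ChIP summit
#'   sets (classes as in [simulate_chip_summits()]).
#' @param summits_per_factor summits per simulated factor.
#' @param seed global seed; every stochastic stage derives its own sub-seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(output_dir = tempfile("atacdyn_run_"),
                       sim = sim_config(),
                       inputs = NULL,
                       alpha = 0.05,
                       peak_config = peak_call_config(),
                       bootstrap_B = 10000,
                       n_candidates = 13,
                       chip_factors = c(tf1 = "canonical_TF",
                                        tf2 = "canonical_TF",
                                        eor1_like = "nucleosome_proximal",
                                        hpl_like = "heterochromatin"),
                       summits_per_factor = 200,
                       seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (bootstrap_B < 100) stop("bootstrap_B must be >= 100")
  if (is.null(sim) && is.null(inputs))
    stop("either `sim` or `inputs` must be given")
  if (!is.null(inputs)) {
    flat <- unlist(inputs[c("genome", "annotation")], use.names = FALSE)
    missing <- flat[!file.exists(flat)]
    if (length(missing)) stop("input path(s) do not exist: ",
                              paste(missing, collapse = ", "))
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' Executes simulate (when configured) -> fragment QC -> replicate peak
#' calling with input masking -> consensus and catalog -> differential
#' accessibility per stage transition -> region classification, enhancer
#' candidates, chromatin-state and transition enrichment -> motif counting,
#' enrichment and boosting -> ChIP-summit fragment-size and occupancy
#' profiling.  Optional inputs that are absent (states, motifs, summits)
#' skip their stage with a logged warning.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return named list of results, including `manifest` (data frame of every
#'   written file with its md5 and the seeds used), also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_msg <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S"),
                                               " ", ...)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  manifest <- list()
  seed <- config$seed
  record <- function(path, stage) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)))
  }

  # --- inputs: simulate or load ---
  stage_wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  stages <- NULL; replicates <- NULL
  world <- NULL
  if (!is.null(config$sim)) {
    log_msg("simulating world (seed ", seed, ")")
    simcfg <- config$sim
    simcfg$seed <- derive_seed(seed, "world")
    world <- stage_wrap("simulate", simulate_world(simcfg))
    stages <- simcfg$stages; replicates <- simcfg$replicates
    genome <- world$genome
    annotation <- world$annotation
    states <- world$states
    pwms <- simcfg$motifs
    frag <- list()
    for (st in stages) for (rp in replicates) {
      frag[[paste(st, rp, sep = ".")]] <- simulate_atac_fragments(
        world, st, rp, seed = derive_seed(seed, paste("atac", st, rp)))
    }
    input_frags <- simulate_input_fragments(
      world, seed = derive_seed(seed, "input"))
    wpaths <- write_world(world, file.path(config$output_dir, "world"))
    for (p in wpaths) record(p, "simulate")
  } else {
    log_msg("loading inputs")
    genome <- stage_wrap("load", read_genome_fasta(config$inputs$genome))
    annotation <- stage_wrap("load",
                             read_gff3_lite(config$inputs$annotation))
    frag <- list()
    for (st in names(config$inputs$fragments))
      for (rp in names(config$inputs$fragments[[st]]))
        frag[[paste(st, rp, sep = ".")]] <- read_fragments(
          config$inputs$fragments[[st]][[rp]], "BED3", st, rp, genome)
    stages <- names(config$inputs$fragments)
    input_frags <- if (!is.null(config$inputs$input_control))
      read_fragments(config$inputs$input_control, "BED3", "input", "rep1",
                     genome) else NULL
    states <- NULL
    if (!is.null(config$inputs$states))
      states <- lapply(names(config$inputs$states), function(st)
        read_state_bed(config$inputs$states[[st]], st, genome))
    if (!is.null(states)) names(states) <- names(config$inputs$states)
    pwms <- if (!is.null(config$inputs$motifs))
      read_pwms_meme(config$inputs$motifs) else NULL
  }
  sample_stages <- setNames(sub("\\..*$", "", names(frag)), names(frag))

  # --- fragment QC ---
  log_msg("fragment QC")
  out$qc <- stage_wrap("qc", {
    hist1 <- insert_size_histogram(frag[[1]])
    per <- estimate_periodicity(hist1, seed = derive_seed(seed, "period"))
    prof <- tss_profile(frag[[1]], annotation$tss)
    list(periodicity = per, tss_score = prof$score, tss_profile = prof)
  })

  # --- peak calling ---
  log_msg("peak calling (", length(frag), " libraries)")
  input_events <- if (!is.null(input_frags))
    cutsite_coverage(input_frags, genome) else NULL
  stage_peaks <- list()
  for (st in stages) {
    reps <- grep(paste0("^", st, "\\."), names(frag), value = TRUE)
    rep_peaks <- lapply(reps, function(s) {
      ev <- cutsite_coverage(frag[[s]], genome)
      pk <- call_peaks_replicate(ev, config$peak_config, stage = st,
                                 replicate = sub("^.*\\.", "", s))
      mask_by_input(pk, input_events, config$peak_config,
                    sample_total = attr(ev, "total"))
    })
    stage_peaks[[st]] <- stage_wrap("consensus",
                                    replicate_consensus(rep_peaks, st))
    p <- file.path(config$output_dir, sprintf("peaks_%s.bed", st))
    write_peaks(stage_peaks[[st]], p); record(p, "peaks")
  }
  catalog <- stage_wrap("catalog", build_catalog(stage_peaks))
  out$catalog <- catalog
  p <- file.path(config$output_dir, "catalog.bed")
  write_peaks(transform(catalog, summit_offset = summit - start), p)
  record(p, "peaks")

  # --- counts, sample correlation, differential ---
  log_msg("quantification and differential accessibility")
  counts <- stage_wrap("counts", peak_counts(catalog, frag))
  out$counts <- counts
  out$correlation <- stage_wrap("qc",
    sample_correlation_clustering(peak_signal_matrix(counts)))
  out$differential <- list()
  for (i in seq_len(length(stages) - 1)) {
    key <- paste0(stages[i], "_", stages[i + 1])
    res <- stage_wrap("differential",
      differential_test(counts, sample_stages, stages[i], stages[i + 1],
                        alpha = config$alpha))
    out$differential[[key]] <- res
    p <- file.path(config$output_dir, sprintf("differential_%s.tsv", key))
    write_differential(res, p); record(p, "differential")
  }

  # --- region classes, enhancer candidates, enrichment ---
  log_msg("region classification and enrichment")
  out$region_classes <- stage_wrap("annotate",
                                   classify_region(catalog, annotation))
  out$enhancer_candidates <- stage_wrap("annotate",
    rank_enhancer_candidates(out$differential, out$region_classes,
                             config$n_candidates))
  p <- file.path(config$output_dir, "enhancer_candidates.tsv")
  write.table(out$enhancer_candidates, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  record(p, "annotate")
  if (is.null(states)) {
    warning("no chromatin-state segmentations supplied; enrichment stage ",
            "skipped")
  } else {
    out$state_enrichment <- list()
    for (st in names(states)) {
      pk <- stage_peaks[[st]]
      if (is.null(pk) || nrow(pk) == 0) next
      out$state_enrichment[[st]] <- stage_wrap("enrich",
        bootstrap_state_enrichment(pk, states[[st]], genome,
                                   B = config$bootstrap_B,
                                   seed = derive_seed(seed,
                                                      paste("boot", st))))
      p <- file.path(config$output_dir,
                     sprintf("state_enrichment_%s.tsv", st))
      write_enrichment(out$state_enrichment[[st]], p); record(p, "enrich")
    }
    key <- paste0(stages[1], "_", stages[2])
    dyn <- out$differential[[key]]
    dyn_peaks <- catalog[catalog$name %in%
                           dyn$peak[dyn$class != "no-change"], ]
    if (nrow(dyn_peaks))
      out$transition_enrichment <- stage_wrap("enrich",
        transition_enrichment(dyn_peaks, catalog, states[[stages[1]]],
                              states[[stages[2]]]))
  }

  # --- motifs and boosting ---
  if (is.null(pwms) || is.null(genome$sequence)) {
    warning("no motif library or genome sequence; motif stage skipped")
  } else {
    log_msg("motif counting and boosting")
    mcm <- stage_wrap("motifs", motif_count_matrix(catalog, genome, pwms))
    out$motif_counts <- mcm
    key <- paste0(stages[1], "_", stages[2])
    labels <- out$differential[[key]]$class
    out$motif_enrichment <- stage_wrap("motifs",
      motif_enrichment(mcm, labels, "increase", "no-change"))
    if (length(unique(labels)) >= 3 && nrow(mcm) >= 50) {
      out$boost <- stage_wrap("classify",
        fit_boost(mcm, labels, seed = derive_seed(seed, "boost")))
      out$relative_influence <- relative_influence(out$boost)
      p <- file.path(config$output_dir, "relative_influence.tsv")
      write.table(out$relative_influence, p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      record(p, "classify")
    } else {
      warning("fewer than 3 dynamics classes or 50 peaks; boosting skipped")
    }
  }

  # --- ChIP summit profiling (simulated factors) ---
  if (!is.null(world) && length(config$chip_factors)) {
    log_msg("summit profiling")
    l3_frags <- do.call(rbind, frag[grep("^L3\\.", names(frag))])
    summit_sets <- list(); statsl <- list()
    for (f in names(config$chip_factors)) {
      summit_sets[[f]] <- simulate_chip_summits(
        world, config$chip_factors[[f]], config$summits_per_factor,
        seed = derive_seed(seed, paste("chip", f)))
      statsl[[f]] <- summit_fragstats(l3_frags, summit_sets[[f]])
    }
    out$summit_stats <- statsl
    out$fragsize_histograms <- stage_wrap("summits",
      factor_fragsize_histogram(l3_frags, summit_sets,
                                classes = config$chip_factors))
    np <- names(config$chip_factors)[config$chip_factors ==
                                       "nucleosome_proximal"]
    if (length(np))
      out$fragsize_comparison <- stage_wrap("summits",
        compare_fragsize(statsl, np[1]))
    h3_a <- normalize_track(simulate_h3_tracks(
      world, stages[1], seed = derive_seed(seed, "h3A")))
    h3_b <- normalize_track(simulate_h3_tracks(
      world, stages[2], seed = derive_seed(seed, "h3B")))
    out$occupancy_change <- lapply(summit_sets, function(s)
      occupancy_change(h3_a, h3_b, s, genome,
                       seed = derive_seed(seed, "occ")))
    out$peakset_jaccard <- peakset_overlap(lapply(summit_sets, function(s)
      data.frame(chrom = s$chrom, start = pmax(s$start - 50, 0),
                 end = s$start + 51)))
  }

  # --- manifest ---
  manifest <- do.call(rbind, manifest)
  manifest$seed <- seed
  out$manifest <- manifest
  mp <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  log_msg("done in ", sprintf("%.1f", as.numeric(difftime(Sys.time(), t0,
                                                          units = "secs"))),
          " s; outputs in ", config$output_dir)
  invisible(out)
}
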