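# Synthetic three-stage world: genome, genes, truth peaks with planted
# motifs, chromatin states, nucleosome-laddered ATAC fragments, input
# control, ChIP summits and histone tracks.

#' Default motif library for simulations
#'
#' Small built-in PWM set: a dimeric GAGA-repeat motif (the gain-associated
#' motif of the simulated world) plus GATA-, T-box-, nuclear-receptor-,
#' bZIP- (palindromic) and POU-like decoys.
#'
#' @param sharp probability of the consensus base per column.
#' @param threshold hit threshold passed to [pwm()].
#' @return named list of [pwm()] objects.
#' @export
default_motif_library <- function(sharp = 0.85, threshold = 0.8) {
  mk <- function(id, consensus) {
    bases <- strsplit(consensus, "")[[1]]
    mat <- vapply(bases, function(b) {
      col <- rep((1 - sharp) / 3, 4)
      col[match(b, c("A", "C", "G", "T"))] <- sharp
      col
    }, numeric(4))
    pwm(id, mat, threshold = threshold)
  }
  list(
    GAGA_dimer = mk("GAGA_dimer", "GAGAGAGAGAGAGAGA"),
    GATA_1     = mk("GATA_1", "AGATAAGA"),
    TBX_1      = mk("TBX_1", "AGGTGTGA"),
    NHR_1      = mk("NHR_1", "TGACCTTGACCT"),
    BZIP_1     = mk("BZIP_1", "TGACGTCA"),
    POU_1      = mk("POU_1", "ATGCAAAT"))
}

#' Default motif-planting map
#'
#' Planting probability per motif and dynamics class (the class of the
#' first stage transition).  The GAGA dimer is strongly enriched in
#' gain-of-accessibility peaks.
#'
#' @return data frame with columns `motif`, `class`, `prob`.
#' @export
default_planting_map <- function() {
  base <- expand.grid(
    motif = c("GAGA_dimer", "GATA_1", "TBX_1", "NHR_1", "BZIP_1", "POU_1"),
    class = c("increase", "decrease", "no-change"),
    stringsAsFactors = FALSE)
  base$prob <- 0.05
  base$prob[base$motif == "GAGA_dimer" & base$class == "increase"] <- 0.80
  base$prob[base$motif == "GATA_1" & base$class == "increase"] <- 0.25
  base$prob[base$motif == "TBX_1" & base$class == "decrease"] <- 0.25
  base
}

#' Simulation configuration
#'
#' Defaults describe the standard simulated world: 2 chromosomes x 1 Mb,
#' 200 genes, 600 truth peaks, three stages (EE, L3, YA) x three replicates
#' of 120,000 fragments each, insert sizes from a sub-nucleosomal
#' exponential plus Gaussians laddered every `nucleosome_period` bp, 40% of
#' peaks dynamic between the first two stages and 5% between the last two.
#'
#' @param genome_size total genome size in bp.
#' @param n_chroms number of chromosomes.
#' @param n_genes number of genes.
#' @param n_truth_peaks number of accessible truth peaks.
#' @param frac_dynamic named fractions of peaks that change per transition.
#' @param frac_promoter_peaks fraction of truth peaks placed promoter-proximal.
#' @param peak_width min/max truth-peak width (bp).
#' @param nucleosome_period ladder period P in bp (>= 50).
#' @param subnuc_scale,subnuc_offset exponential scale and offset (bp) of the
#'   sub-nucleosomal insert component.
#' @param ladder_mu0,ladder_sd first Gaussian mean offset and common sd (bp);
#'   ladder means are `ladder_mu0 + k * nucleosome_period`, k = 0, 1, 2.
#' @param mix_peak,mix_background mixture weights (sub, k0, k1, k2) for
#'   fragments originating in peaks vs background.
#' @param frag_signal_frac scales the fraction of fragments drawn from peaks
#'   (realised fraction is `frag_signal_frac * mean(stage level)`).
#' @param fragments_per_replicate sequencing depth per replicate.
#' @param input_depth fragments in the input control.
#' @param n_hotspots,hotspot_width,hotspot_rate artifact hotspots in the
#'   input control (count, width bp, rate multiple over background).
#' @param motifs named list of [pwm()] objects to plant.
#' @param planting data frame `motif`/`class`/`prob` of planting probabilities.
#' @param stages ordered stage labels.
#' @param replicates replicate labels.
#' @param level_fold_threshold fold change in accessibility level that
#'   defines a dynamic truth peak.
#' @param seed master seed; recorded in every output header.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_size = 2e6,
                       n_chroms = 2,
                       n_genes = 200,
                       n_truth_peaks = 600,
                       frac_dynamic = c(EE_L3 = 0.40, L3_YA = 0.05),
                       frac_promoter_peaks = 0.30,
                       peak_width = c(150, 400),
                       nucleosome_period = 147,
                       subnuc_scale = 40,
                       subnuc_offset = 20,
                       ladder_mu0 = 60,
                       ladder_sd = 20,
                       mix_peak = c(sub = 0.70, k0 = 0.15, k1 = 0.10,
                                    k2 = 0.05),
                       mix_background = c(sub = 0.15, k0 = 0.15, k1 = 0.45,
                                          k2 = 0.25),
                       frag_signal_frac = 0.6,
                       fragments_per_replicate = 120000,
                       input_depth = 60000,
                       n_hotspots = 5,
                       hotspot_width = 1000,
                       hotspot_rate = 50,
                       motifs = default_motif_library(),
                       planting = default_planting_map(),
                       stages = c("EE", "L3", "YA"),
                       replicates = c("rep1", "rep2", "rep3"),
                       level_fold_threshold = 2,
                       seed = 1) {
  cfg <- as.list(environment())
  fr <- c(cfg$frac_dynamic, cfg$frac_promoter_peaks, cfg$frag_signal_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$nucleosome_period < 50) stop("nucleosome_period must be >= 50")
  if (length(cfg$frac_dynamic) != length(cfg$stages) - 1)
    stop("frac_dynamic needs one entry per stage transition")
  stopifnot(abs(sum(cfg$mix_peak) - 1) < 1e-6,
            abs(sum(cfg$mix_background) - 1) < 1e-6)
  structure(cfg, class = "sim_config")
}

# dynamics class of a level change under the configured fold threshold
level_class <- function(a, b, fold) {
  eps <- 0.02
  ifelse(b >= fold * (a + eps) & b - a >= 0.2, "increase",
  ifelse(a >= fold * (b + eps) & a - b >= 0.2, "decrease", "no-change"))
}

#' Simulate a complete world
#'
#' Generates (deterministically for a given seed) a genome with sequence,
#' gene annotation, truth peaks with per-stage accessibility levels and
#' dynamics classes, planted motif occurrences (gain-class peaks carry the
#' GAGA dimer at the configured probability), per-stage chromatin-state
#' segmentations consistent with the levels, input-control artifact
#' hotspots, and a background nucleosome-position grid.
#'
#' @param config a [sim_config()].
#' @return an object of class `atac_world`.
#' @export
simulate_world <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chrom <- config$n_chroms
  chrlen <- rep(floor(config$genome_size / n_chrom), n_chrom)
  names(chrlen) <- paste0("chr", utils::as.roman(seq_len(n_chrom)))
  bases <- c("A", "C", "G", "T")
  sequence <- vapply(chrlen, function(L)
    paste(sample(bases, L, replace = TRUE), collapse = ""), "")
  genome <- genome_model(chrlen, sequence)

  # --- genes on an even slot grid so intergenic room is guaranteed ---
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = n_chrom + 1)))
  tss_rows <- list(); exon_rows <- list(); gene_spans <- list()
  gi <- 0
  for (ci in seq_len(n_chrom)) {
    ch <- names(chrlen)[ci]
    ng <- per_chrom[ci]
    if (ng == 0) next
    slot <- floor(chrlen[ci] / ng)
    if (slot < 6000) stop("genome too small for ", ng, " genes on ", ch,
                          " (need >= 6 kb per gene slot)")
    for (g in seq_len(ng)) {
      gi <- gi + 1
      id <- sprintf("gene_%03d", gi)
      n_ex <- sample(2:4, 1)
      ex_w <- sample(150:400, n_ex, replace = TRUE)
      in_w <- sample(100:300, n_ex - 1, replace = TRUE)
      span <- sum(ex_w) + sum(in_w)
      lo <- (g - 1) * slot + 1500
      hi <- g * slot - 1500 - span
      if (hi <= lo) stop("gene slot too small on ", ch)
      s0 <- sample(lo:hi, 1)
      strand <- sample(c("+", "-"), 1)
      offs <- cumsum(c(0, head(as.vector(rbind(ex_w, c(in_w, 0))), -1)))
      ex_start <- s0 + offs[seq(1, by = 2, length.out = n_ex)]
      ex <- data.frame(chrom = ch, start = ex_start,
                       end = ex_start + ex_w, strand = strand, name = id)
      tss_pos <- if (strand == "+") s0 else s0 + span - 1
      tss_rows[[gi]] <- data.frame(chrom = ch, start = tss_pos,
                                   end = tss_pos + 1, strand = strand,
                                   name = id)
      exon_rows[[gi]] <- ex
      gene_spans[[gi]] <- data.frame(chrom = ch, start = s0, end = s0 + span,
                                     strand = strand, name = id)
    }
  }
  tss <- do.call(rbind, tss_rows)
  exons <- do.call(rbind, exon_rows)
  spans <- do.call(rbind, gene_spans)
  annotation <- gene_annotation(tss, exons)

  # --- truth peaks: promoter-proximal and distal ---
  n_peaks <- config$n_truth_peaks
  n_prom <- min(round(config$frac_promoter_peaks * n_peaks), nrow(tss))
  widths <- sample(config$peak_width[1]:config$peak_width[2], n_peaks,
                   replace = TRUE)
  peaks <- data.frame(chrom = character(n_peaks), start = numeric(n_peaks),
                      end = numeric(n_peaks), summit = numeric(n_peaks),
                      promoter = logical(n_peaks), stringsAsFactors = FALSE)
  prom_genes <- sample(nrow(tss), n_prom)
  for (i in seq_len(n_prom)) {
    t <- tss[prom_genes[i], ]
    off <- sample(seq(-300, -20), 1)   # just upstream: non-exonic summit,
                                       # peak body overlapping the TSS
    sgn <- if (t$strand == "+") 1 else -1
    summit <- t$start + sgn * off
    w <- widths[i]
    peaks[i, ] <- list(t$chrom, summit - floor(w / 2),
                       summit - floor(w / 2) + w, summit, TRUE)
  }
  # distal placement: outside gene spans +/- 1 kb, apart from other peaks;
  # per-chromosome start/end vectors keep the rejection test cheap
  excl <- merge_intervals(data.frame(chrom = spans$chrom,
                                     start = pmax(spans$start - 1000, 0),
                                     end = spans$end + 1000), gap = 0)
  occ <- lapply(setNames(names(chrlen), names(chrlen)), function(ch) {
    e <- excl[excl$chrom == ch, ]
    p <- peaks[seq_len(n_prom), ][peaks$chrom[seq_len(n_prom)] == ch, ]
    list(start = c(e$start, p$start), end = c(e$end, p$end))
  })
  for (i in seq(n_prom + 1, n_peaks)) {
    w <- widths[i]
    ok <- FALSE
    for (try in seq_len(200)) {
      ch <- sample(names(chrlen), 1, prob = chrlen)
      summit <- sample.int(chrlen[[ch]] - 2 * w - 2000, 1) + w + 1000
      s0 <- summit - floor(w / 2) - 300
      e0 <- summit - floor(w / 2) + w + 300
      if (any(occ[[ch]]$start < e0 & occ[[ch]]$end > s0)) next
      peaks[i, ] <- list(ch, summit - floor(w / 2),
                         summit - floor(w / 2) + w, summit, FALSE)
      occ[[ch]]$start <- c(occ[[ch]]$start, s0)
      occ[[ch]]$end <- c(occ[[ch]]$end, e0)
      ok <- TRUE
      break
    }
    if (!ok) stop("genome too small to place ", n_peaks,
                  " non-overlapping truth peaks; increase genome_size or ",
                  "reduce n_truth_peaks")
  }
  peaks$name <- sprintf("truth_%04d", seq_len(n_peaks))

  # --- per-stage accessibility levels and dynamics classes ---
  stages <- config$stages
  levels <- matrix(rep(runif(n_peaks, 0.3, 1), length(stages)),
                   ncol = length(stages),
                   dimnames = list(NULL, stages))
  remaining <- seq_len(n_peaks)
  for (tr in seq_along(config$frac_dynamic)) {
    n_dyn <- round(config$frac_dynamic[tr] * n_peaks)
    dyn <- if (n_dyn > 0) sample(remaining, min(n_dyn, length(remaining)))
           else integer()
    remaining <- setdiff(remaining, dyn)
    up <- dyn[runif(length(dyn)) < 0.5]
    dn <- setdiff(dyn, up)
    lo <- function(n) runif(n, 0.02, 0.12)
    hi <- function(n) runif(n, 0.6, 1)
    # set the two flanking stages; later stages inherit the new value
    levels[up, tr] <- lo(length(up))
    levels[up, (tr + 1):length(stages)] <- hi(length(up))
    levels[dn, tr] <- hi(length(dn))
    levels[dn, (tr + 1):length(stages)] <- lo(length(dn))
    if (tr > 1) {  # earlier stages inherit the pre-transition value
      levels[c(up, dn), seq_len(tr - 1)] <- levels[c(up, dn), tr]
    }
  }
  classes <- sapply(seq_along(config$frac_dynamic), function(tr)
    level_class(levels[, tr], levels[, tr + 1], config$level_fold_threshold))
  colnames(classes) <- paste0(stages[-length(stages)], "_", stages[-1])
  for (j in seq_len(ncol(levels)))
    peaks[[paste0("level_", stages[j])]] <- levels[, j]
  for (j in seq_len(ncol(classes)))
    peaks[[paste0("class_", colnames(classes)[j])]] <- classes[, j]

  # --- plant motif sites (consensus sequence, random strand) ---
  plant <- list()
  first_class <- classes[, 1]
  for (i in seq_len(n_peaks)) {
    used_s <- numeric(); used_e <- numeric()
    for (m in names(config$motifs)) {
      p <- config$planting$prob[config$planting$motif == m &
                                config$planting$class == first_class[i]]
      p <- if (length(p)) p[1] else 0
      if (runif(1) >= p) next
      n_occ <- 1 + (runif(1) < 0.25)
      mot <- config$motifs[[m]]
      L <- ncol(mot$mat)
      site <- pwm_consensus(mot)
      for (k in seq_len(n_occ)) {
        lo <- peaks$start[i] + 10
        hi <- peaks$end[i] - 10 - L
        if (hi <= lo) next
        pos <- NA
        for (try in seq_len(20)) {
          cand <- lo + sample.int(hi - lo + 1, 1) - 1
          if (!any(used_s < cand + L & used_e > cand)) {
            pos <- cand
            used_s <- c(used_s, cand); used_e <- c(used_e, cand + L)
            break
          }
        }
        if (is.na(pos)) next
        strand <- sample(c("+", "-"), 1)
        written <- if (strand == "+") site else
          as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(site)))
        plant[[length(plant) + 1]] <- data.frame(
          peak = peaks$name[i], motif = m, chrom = peaks$chrom[i],
          start = pos, end = pos + L, strand = strand, site = written)
      }
    }
  }
  motif_occurrences <- if (length(plant)) do.call(rbind, plant) else
    data.frame(peak = character(), motif = character(), chrom = character(),
               start = numeric(), end = numeric(), strand = character(),
               site = character())
  # write all planted sites into the sequence in one pass per chromosome
  for (ch in unique(motif_occurrences$chrom)) {
    chars <- strsplit(sequence[[ch]], "")[[1]]
    oc <- motif_occurrences[motif_occurrences$chrom == ch, ]
    for (r in seq_len(nrow(oc)))
      chars[(oc$start[r] + 1):oc$end[r]] <- strsplit(oc$site[r], "")[[1]]
    sequence[[ch]] <- paste(chars, collapse = "")
  }
  motif_occurrences$site <- NULL
  genome <- genome_model(chrlen, sequence)

  # --- chromatin states per stage, painted then run-length encoded ---
  state_levels <- c("heterochromatin", "H3K27me3_repressed", "transcribed",
                    "repressed_enhancer", "active_enhancer", "promoter")
  k27 <- list()
  for (ch in names(chrlen)) {
    st <- sort(sample.int(chrlen[[ch]] - 9000, 12))
    k27[[ch]] <- data.frame(chrom = ch, start = st,
                            end = st + sample(2000:8000, 12, replace = TRUE))
  }
  k27 <- do.call(rbind, k27)
  states <- list()
  for (st_i in seq_along(stages)) {
    segs <- list()
    for (ch in names(chrlen)) {
      paint <- rep(1L, chrlen[[ch]])
      kk <- k27[k27$chrom == ch, ]
      for (r in seq_len(nrow(kk)))
        paint[(kk$start[r] + 1):kk$end[r]] <- 2L
      sp <- spans[spans$chrom == ch, ]
      for (r in seq_len(nrow(sp)))
        paint[(sp$start[r] + 1):sp$end[r]] <- 3L
      pk <- peaks[peaks$chrom == ch, ]
      lv <- pk[[paste0("level_", stages[st_i])]]
      code <- ifelse(lv >= 0.5, ifelse(pk$promoter, 6L, 5L),
              ifelse(lv >= 0.15, 4L, NA))
      for (r in seq_len(nrow(pk)))
        if (!is.na(code[r]))
          paint[(pk$start[r] + 1):pk$end[r]] <- code[r]
      rl <- rle(paint)
      ends <- cumsum(rl$lengths)
      segs[[ch]] <- data.frame(chrom = ch, start = c(0, ends[-length(ends)]),
                               end = ends, state = state_levels[rl$values])
    }
    states[[stages[st_i]]] <- state_segmentation(do.call(rbind, segs),
                                                 stages[st_i])
  }

  # --- input artifact hotspots: half on peaks, half in background ---
  n_hot <- config$n_hotspots
  hots <- NULL
  if (n_hot > 0) {
    hw <- config$hotspot_width
    on_peak <- ceiling(n_hot / 2)
    pk_pick <- sample(n_peaks, min(on_peak, n_peaks))
    h1 <- data.frame(chrom = peaks$chrom[pk_pick],
                     start = pmax(peaks$summit[pk_pick] - floor(hw / 2), 0))
    h1$end <- h1$start + hw
    n_bg <- n_hot - nrow(h1)
    h2 <- NULL
    if (n_bg > 0) {
      ch <- sample(names(chrlen), n_bg, replace = TRUE, prob = chrlen)
      st <- vapply(ch, function(c) sample.int(chrlen[[c]] - hw, 1), 1)
      h2 <- data.frame(chrom = ch, start = st, end = st + hw)
    }
    hots <- rbind(h1, h2)
    rownames(hots) <- NULL
  }

  # --- nucleosome-position grid in background (for summit placement) ---
  nuc <- list()
  for (ch in names(chrlen)) {
    grid <- seq(sample.int(config$nucleosome_period, 1), chrlen[[ch]] - 1,
                by = config$nucleosome_period)
    near_peak <- data.frame(chrom = peaks$chrom,
                            start = pmax(peaks$start - 300, 0),
                            end = peaks$end + 300)
    gr <- data.frame(chrom = ch, start = grid, end = grid + 1)
    hit <- interval_overlap(gr, near_peak)
    keep <- setdiff(seq_along(grid), unique(hit$query))
    nuc[[ch]] <- grid[keep]
  }

  structure(list(config = config, genome = genome, annotation = annotation,
                 peaks = peaks, motif_occurrences = motif_occurrences,
                 states = states, hotspots = hots, nucleosome_grid = nuc),
            class = "atac_world")
}

#' @export
print.atac_world <- function(x, ...) {
  cat("atac_world:", nrow(x$peaks), "truth peaks on",
      length(x$genome$chrom_names), "chromosome(s);",
      "stages:", paste(x$config$stages, collapse = ", "),
      "; seed", x$config$seed, "\n")
  invisible(x)
}

# draw insert lengths for a mixture assignment (1=sub, 2..4 = ladder k=0..2)
draw_insert_lengths <- function(comp, cfg) {
  n <- length(comp)
  len <- numeric(n)
  sub <- comp == 1
  len[sub] <- round(rexp(sum(sub), 1 / cfg$subnuc_scale)) + cfg$subnuc_offset
  for (k in 0:2) {
    i <- comp == k + 2
    len[i] <- round(rnorm(sum(i), cfg$ladder_mu0 + k * cfg$nucleosome_period,
                          cfg$ladder_sd))
  }
  pmin(pmax(len, 10), 1500)
}

#' Simulate an ATAC-seq fragment library
#'
#' Fragment midpoints concentrate in accessible truth peaks in proportion to
#' the stage level over a uniform background.  Insert lengths come from a
#' sub-nucleosomal exponential plus Gaussians laddered every
#' `nucleosome_period` bp; peak-origin fragments are mostly sub-nucleosomal
#' and background fragments mostly mono/di-nucleosomal.  Replicates differ
#' only by seed.
#'
#' @param world an [simulate_world()] result.
#' @param stage stage label.
#' @param replicate replicate label.
#' @param depth fragment count (> 0).
#' @param seed RNG seed for this library.
#' @return fragment data frame (see [fragments()]).
#' @export
simulate_atac_fragments <- function(world, stage, replicate,
                                    depth = world$config$fragments_per_replicate,
                                    seed = derive_seed(world$config$seed,
                                      paste("atac", stage, replicate))) {
  cfg <- world$config
  if (!stage %in% cfg$stages) stop("unknown stage: ", stage)
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  chrlen <- world$genome$chrom_lengths
  pk <- world$peaks
  w <- pk[[paste0("level_", stage)]]
  p_signal <- if (sum(w) > 0) cfg$frag_signal_frac * mean(w) else 0
  is_sig <- runif(depth) < p_signal
  n_sig <- sum(is_sig)
  mid <- numeric(depth)
  chrom <- character(depth)
  if (n_sig > 0) {
    idx <- sample.int(nrow(pk), n_sig, replace = TRUE, prob = w)
    width <- pk$end[idx] - pk$start[idx]
    m <- round(rnorm(n_sig, pk$summit[idx], width / 5))
    mid[is_sig] <- pmin(pmax(m, pk$start[idx] + 2), pk$end[idx] - 2)
    chrom[is_sig] <- pk$chrom[idx]
  }
  n_bg <- depth - n_sig
  if (n_bg > 0) {
    ch <- sample(names(chrlen), n_bg, replace = TRUE, prob = chrlen)
    chrom[!is_sig] <- ch
    mid[!is_sig] <- floor(runif(n_bg) * (chrlen[ch] - 2)) + 1
  }
  comp <- integer(depth)
  if (n_sig > 0) comp[is_sig] <- sample.int(4, n_sig, replace = TRUE,
                                            prob = cfg$mix_peak)
  if (n_bg > 0) comp[!is_sig] <- sample.int(4, n_bg, replace = TRUE,
                                            prob = cfg$mix_background)
  len <- draw_insert_lengths(comp, cfg)
  start <- mid - len %/% 2
  maxend <- chrlen[chrom]
  start <- pmin(pmax(start, 0), pmax(maxend - len, 0))
  len <- pmin(len, maxend)
  fragments(chrom, start, start + len, stage, replicate)
}

#' Simulate an input-control fragment library
#'
#' Uniform coverage plus the world's artifact hotspots at
#' `hotspot_rate`-fold elevated per-bp rate.
#'
#' @param world an [simulate_world()] result.
#' @param depth fragment count (> 0).
#' @param seed RNG seed.
#' @return fragment data frame with `sample_id = "input"`.
#' @export
simulate_input_fragments <- function(world,
                                     depth = world$config$input_depth,
                                     seed = derive_seed(world$config$seed,
                                                        "input")) {
  cfg <- world$config
  if (depth <= 0) stop("depth must be positive")
  set.seed(seed)
  chrlen <- world$genome$chrom_lengths
  G <- sum(chrlen)
  hots <- world$hotspots
  H <- if (is.null(hots)) 0 else sum(hots$end - hots$start)
  p_hot <- if (H > 0) cfg$hotspot_rate * H /
                        (cfg$hotspot_rate * H + (G - H)) else 0
  in_hot <- runif(depth) < p_hot
  n_hot <- sum(in_hot)
  chrom <- character(depth); mid <- numeric(depth)
  if (n_hot > 0) {
    hi <- sample.int(nrow(hots), n_hot, replace = TRUE)
    chrom[in_hot] <- hots$chrom[hi]
    mid[in_hot] <- hots$start[hi] +
      floor(runif(n_hot) * (hots$end[hi] - hots$start[hi]))
  }
  n_bg <- depth - n_hot
  if (n_bg > 0) {
    ch <- sample(names(chrlen), n_bg, replace = TRUE, prob = chrlen)
    chrom[!in_hot] <- ch
    mid[!in_hot] <- floor(runif(n_bg) * (chrlen[ch] - 2)) + 1
  }
  comp <- sample.int(4, depth, replace = TRUE, prob = cfg$mix_background)
  len <- draw_insert_lengths(comp, cfg)
  start <- mid - len %/% 2
  maxend <- chrlen[chrom]
  start <- pmin(pmax(start, 0), pmax(maxend - len, 0))
  len <- pmin(len, maxend)
  fragments(chrom, start, start + len, "input", "rep1")
}

#' Simulate ChIP-seq summits for a factor class
#'
#' `canonical_TF` summits land inside accessible (stage L3 level >= 0.5)
#' truth peaks; `nucleosome_proximal` summits sit next to background
#' nucleosome-grid positions away from peaks; `heterochromatin` summits fall
#' in heterochromatin-state segments away from peaks.
#'
#' @param world an [simulate_world()] result.
#' @param factor_class one of `"canonical_TF"`, `"nucleosome_proximal"`,
#'   `"heterochromatin"`.
#' @param n number of summits (> 0).
#' @param seed RNG seed.
#' @return 1-bp summit interval data frame.
#' @export
simulate_chip_summits <- function(world, factor_class, n,
                                  seed = derive_seed(world$config$seed,
                                    paste("chip", factor_class))) {
  stopifnot(n > 0)
  factor_class <- match.arg(factor_class,
    c("canonical_TF", "nucleosome_proximal", "heterochromatin"))
  set.seed(seed)
  pk <- world$peaks
  pos <- NULL; chrom <- NULL
  if (factor_class == "canonical_TF") {
    elig <- which(pk$level_L3 >= 0.5)
    if (!length(elig)) stop("insufficient eligible positions: no accessible ",
                            "peaks at L3")
    idx <- sample(elig, n, replace = TRUE)
    jit <- round(rnorm(n, 0, 10))
    pos <- pmin(pmax(pk$summit[idx] + jit, pk$start[idx] + 1),
                pk$end[idx] - 2)
    chrom <- pk$chrom[idx]
  } else if (factor_class == "nucleosome_proximal") {
    grid <- world$nucleosome_grid
    all_pos <- unlist(grid, use.names = FALSE)
    all_ch <- rep(names(grid), lengths(grid))
    if (length(all_pos) < 1) stop("insufficient eligible positions: empty ",
                                  "nucleosome grid")
    i <- sample.int(length(all_pos), n, replace = TRUE)
    pos <- all_pos[i] + sample(c(-20:-5, 5:20), n, replace = TRUE)
    chrom <- all_ch[i]
    pos <- pmax(pos, 1)
  } else {
    seg <- world$states[["L3"]]$segments
    het <- seg[seg$state == "heterochromatin" & seg$end - seg$start > 400, ]
    near_peak <- data.frame(chrom = pk$chrom,
                            start = pmax(pk$start - 300, 0),
                            end = pk$end + 300)
    hit <- interval_overlap(het, near_peak)
    if (length(unique(hit$query)) == nrow(het))
      stop("insufficient eligible positions in heterochromatin")
    het <- het[setdiff(seq_len(nrow(het)), unique(hit$query)), ]
    i <- sample.int(nrow(het), n, replace = TRUE,
                    prob = het$end - het$start)
    pos <- het$start[i] + 200 +
      floor(runif(n) * (het$end[i] - het$start[i] - 400))
    chrom <- het$chrom[i]
  }
  data.frame(chrom = chrom, start = pos, end = pos + 1,
             strand = ".", name = factor_class,
             stringsAsFactors = FALSE)
}

#' Simulate a histone H3 occupancy track
#'
#' Occupancy is anti-correlated with the stage accessibility level at truth
#' peaks (scaled by `1 - 0.8 * level`) over a positive noisy baseline of
#' mean `baseline`.
#'
#' @param world an [simulate_world()] result.
#' @param stage stage label.
#' @param seed RNG seed.
#' @param bin_size track bin width in bp.
#' @param baseline genome-wide mean occupancy.
#' @return a [score_track()].
#' @export
simulate_h3_tracks <- function(world, stage,
                               seed = derive_seed(world$config$seed,
                                                  paste("h3", stage)),
                               bin_size = 10, baseline = 1) {
  cfg <- world$config
  if (!stage %in% cfg$stages) stop("unknown stage: ", stage)
  set.seed(seed)
  chrlen <- world$genome$chrom_lengths
  pk <- world$peaks
  lv <- pk[[paste0("level_", stage)]]
  values <- list()
  for (ch in names(chrlen)) {
    nb <- ceiling(chrlen[[ch]] / bin_size)
    scale <- rep(baseline, nb)
    sel <- which(pk$chrom == ch)
    for (r in sel) {
      b0 <- floor(pk$start[r] / bin_size) + 1
      b1 <- min(floor((pk$end[r] - 1) / bin_size) + 1, nb)
      scale[b0:b1] <- baseline * (1 - 0.8 * lv[r])
    }
    values[[ch]] <- scale * rgamma(nb, shape = 50, rate = 50)
  }
  score_track(values, bin_size, world$genome)
}

#' Write a simulated world to disk
#'
#' Emits FASTA, GFF3-lite, per-stage state BEDs, truth-peak BED, hotspot
#' BED, the motif library (MEME format) and a JSON truth sidecar (consumed
#' only by tests, never by the pipeline).
#'
#' @param world an [simulate_world()] result.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "annotation.gff3"),
    truth_peaks = file.path(dir, "truth_peaks.bed"),
    motifs = file.path(dir, "motifs.meme"),
    truth = file.path(dir, "truth.json"))
  write_genome_fasta(world$genome, paths["genome"])
  write_gff3_lite(world$annotation, paths["annotation"])
  pk <- world$peaks
  extra <- setdiff(names(pk), c("chrom", "start", "end", "name"))
  write_bed(pk, paths["truth_peaks"], extra = extra)
  write_pwms_meme(world$config$motifs, paths["motifs"])
  for (st in world$config$stages) {
    p <- file.path(dir, sprintf("states_%s.bed", st))
    write_state_bed(world$states[[st]], p)
    paths[paste0("states_", st)] <- p
  }
  if (!is.null(world$hotspots)) {
    paths["hotspots"] <- file.path(dir, "hotspots.bed")
    write_bed(world$hotspots, paths["hotspots"])
  }
  truth <- list(seed = world$config$seed,
                stages = world$config$stages,
                peaks = world$peaks,
                motif_occurrences = world$motif_occurrences)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
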