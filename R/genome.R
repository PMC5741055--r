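#' Genome model
#'
#' Ordered chromosome names with lengths and (optionally) nucleotide
#' sequence.  Sequence, when present, must match the declared lengths.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param sequence optional named character vector of A/C/G/T(/N) strings.
#' @return an object of class `genome_model`.
#' @export
#' @examples
#' genome_model(c(chrI = 1000, chrII = 800))
genome_model <- function(chrom_lengths, sequence = NULL) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  if (any(duplicated(names(chrom_lengths)))) stop("duplicate chromosome names")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be positive")
  if (!is.null(sequence)) {
    sequence <- vapply(sequence, as.character, "")
    if (!setequal(names(sequence), names(chrom_lengths)))
      stop("sequence names do not match chromosome names")
    sequence <- sequence[names(chrom_lengths)]
    if (!all(nchar(sequence) == chrom_lengths))
      stop("sequence length does not match declared chromosome length")
  }
  structure(list(chrom_names = names(chrom_lengths),
                 chrom_lengths = chrom_lengths,
                 sequence = sequence),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_names), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp",
      if (!is.null(x$sequence)) "(with sequence)" else "(lengths only)", "\n")
  invisible(x)
}

#' Gene annotation: TSSs and exons
#'
#' @param tss stranded 1-bp interval data frame with `name` = gene id.
#' @param exons interval data frame with `name` = gene id.
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(tss, exons) {
  validate_intervals(tss); validate_intervals(exons)
  if (nrow(tss) == 0) stop("annotation needs at least one TSS")
  if (any(!tss$strand %in% c("+", "-"))) stop("every TSS must be stranded")
  if (any(tss$end - tss$start != 1)) stop("TSS intervals must be 1 bp")
  if (nrow(exons) && (!"name" %in% names(exons) || anyNA(exons$name)))
    stop("every exon must carry its gene id in `name`")
  structure(list(tss = tss, exons = exons), class = "gene_annotation")
}

#' Chromatin-state segmentation for one stage
#'
#' Segments must be non-overlapping within the stage.  When a genome is
#' supplied, gaps are filled with the label `"unannotated"` so the
#' segmentation covers the genome.
#'
#' @param segments interval data frame with a `state` column.
#' @param stage stage label.
#' @param genome optional [genome_model()] used to fill gaps.
#' @return an object of class `state_segmentation`.
#' @export
state_segmentation <- function(segments, stage, genome = NULL) {
  validate_intervals(segments, genome)
  if (!"state" %in% names(segments)) stop("segments need a `state` column")
  segments <- segments[order(segments$chrom, segments$start), ]
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments on ", ch)
  }
  if (!is.null(genome)) {
    fill <- list(segments)
    for (ch in genome$chrom_names) {
      s <- segments[segments$chrom == ch, ]
      len <- genome$chrom_lengths[[ch]]
      starts <- c(0, s$end); ends <- c(s$start, len)
      gap <- which(starts < ends)
      if (length(gap))
        fill[[length(fill) + 1]] <- data.frame(
          chrom = ch, start = starts[gap], end = ends[gap],
          state = "unannotated", stringsAsFactors = FALSE)
    }
    segments <- do.call(rbind, lapply(fill, function(d)
      d[, c("chrom", "start", "end", "state")]))
    segments <- segments[order(segments$chrom, segments$start), ]
  }
  rownames(segments) <- NULL
  structure(list(segments = segments, stage = stage),
            class = "state_segmentation")
}

# state label at 0-based positions, vectorised; segmentation must cover them
state_at <- function(seg, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  s <- seg$segments
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    si <- which(s$chrom == ch)
    if (!length(si)) next
    idx <- findInterval(pos[i], s$start[si])
    ok <- idx >= 1 & pos[i] < s$end[si][pmax(idx, 1)]
    out[i[ok]] <- s$state[si][idx[ok]]
  }
  out
}

#' Binned score track
#'
#' Per-chromosome numeric values in fixed-width bins (`bin_size` bp); bin `i`
#' covers `[(i-1) * bin_size, i * bin_size)`.
#'
#' @param values named list of numeric vectors, one per chromosome.
#' @param bin_size bin width in bp.
#' @param genome [genome_model()] the track spans.
#' @return an object of class `score_track`.
#' @export
score_track <- function(values, bin_size, genome) {
  stopifnot(is.list(values), bin_size >= 1)
  if (!setequal(names(values), genome$chrom_names))
    stop("track chromosomes do not match genome")
  for (ch in genome$chrom_names) {
    need <- ceiling(genome$chrom_lengths[[ch]] / bin_size)
    if (length(values[[ch]]) != need)
      stop("track on ", ch, " has ", length(values[[ch]]),
           " bins; expected ", need)
  }
  structure(list(values = values[genome$chrom_names], bin_size = bin_size),
            class = "score_track")
}

# mean track value over 0-based half-open interval(s); vectorised
track_mean <- function(track, chrom, start, end) {
  out <- numeric(length(start))
  bs <- track$bin_size
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- track$values[[ch]]
    if (is.null(v)) stop("track lacks chromosome ", ch)
    cs <- cumsum(v)
    b0 <- pmax(floor(start[i] / bs) + 1, 1)       # first bin, 1-based
    b1 <- pmin(floor((end[i] - 1) / bs) + 1, length(v))
    out[i] <- (cs[b1] - ifelse(b0 > 1, cs[b0 - 1], 0)) / (b1 - b0 + 1)
  }
  out
}

track_genome_mean <- function(track) {
  mean(unlist(track$values, use.names = FALSE))
}
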