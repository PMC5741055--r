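# Readers and writers for the plain-text formats the pipeline touches.
# All writers emit sorted output; all coordinates are BED-style 0-based
# half-open.

read_tsv_lines <- function(path, n_min_fields, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_min_fields)
  if (length(bad))
    stop("malformed ", what, " line ", bad[1], " in ", path,
         ": expected >= ", n_min_fields, " fields, got ", nf[bad[1]])
  fields
}

num_or_stop <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop("non-numeric ", what, " at line ", bad[1], " in ", path)
  out
}

#' Read intervals from a BED file
#'
#' Accepts BED3 and BED6 (and wider; extra columns ignored).
#'
#' @param path file path.
#' @param genome optional [genome_model()] for bounds checking.
#' @return interval data frame.
#' @export
read_bed <- function(path, genome = NULL) {
  fields <- read_tsv_lines(path, 3, "BED")
  n <- length(fields)
  get <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[i] else default, "")
  x <- data.frame(chrom = get(1, NA),
                  start = num_or_stop(get(2, NA), "start", path),
                  end = num_or_stop(get(3, NA), "end", path),
                  stringsAsFactors = FALSE)
  if (all(lengths(fields) >= 4)) x$name <- get(4, NA)
  if (all(lengths(fields) >= 5))
    x$score <- suppressWarnings(as.numeric(get(5, NA)))
  if (all(lengths(fields) >= 6)) x$strand <- get(6, ".")
  validate_intervals(x, genome)
  x
}

#' Write intervals as BED
#'
#' @param x interval data frame.
#' @param path output path.
#' @param extra character vector of additional column names of `x` to append
#'   after the BED6 fields.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra = character()) {
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  cols <- data.frame(chrom = x$chrom,
                     start = format(x$start, scientific = FALSE, trim = TRUE),
                     end = format(x$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(x) || length(extra) || "score" %in% names(x) ||
      "strand" %in% names(x)) {
    cols$name <- if ("name" %in% names(x)) ifelse(is.na(x$name), ".", x$name)
                 else "."
    cols$score <- if ("score" %in% names(x))
      ifelse(is.na(x$score), "0", format(x$score, trim = TRUE)) else "0"
    cols$strand <- if ("strand" %in% names(x)) x$strand else "."
  }
  for (e in extra) cols[[e]] <- x[[e]]
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ATAC fragments
#'
#' BED3 records become one fragment each; BEDPE mate pairs are collapsed to
#' the outer Tn5-to-Tn5 insert span.  Fragments are strandless.
#'
#' @param path file path.
#' @param format `"BED3"` or `"BEDPE"`.
#' @param sample_id stage label (e.g. `"EE"`, `"L3"`, `"YA"`, `"input"`).
#' @param replicate replicate identifier.
#' @param genome optional [genome_model()] for bounds checking.
#' @return fragment data frame with columns `chrom`, `start`, `end`,
#'   `sample_id`, `replicate`, `insert_length`.
#' @export
read_fragments <- function(path, format = c("BED3", "BEDPE"),
                           sample_id = "sample", replicate = "rep1",
                           genome = NULL) {
  format <- match.arg(format)
  if (format == "BED3") {
    x <- read_bed(path, genome)[, c("chrom", "start", "end")]
  } else {
    fields <- read_tsv_lines(path, 6, "BEDPE")
    get <- function(i) vapply(fields, `[`, "", i)
    c1 <- get(1); c2 <- get(4)
    bad <- which(c1 != c2)
    if (length(bad))
      stop("BEDPE mates on different chromosomes at line ", bad[1],
           " in ", path)
    s1 <- num_or_stop(get(2), "start1", path)
    e1 <- num_or_stop(get(3), "end1", path)
    s2 <- num_or_stop(get(5), "start2", path)
    e2 <- num_or_stop(get(6), "end2", path)
    x <- data.frame(chrom = c1, start = pmin(s1, s2), end = pmax(e1, e2),
                    stringsAsFactors = FALSE)
    validate_intervals(x, genome)
  }
  fragments(x$chrom, x$start, x$end, sample_id, replicate)
}

#' Build a fragment table
#'
#' @param chrom,start,end fragment coordinates (0-based half-open).
#' @param sample_id stage label.
#' @param replicate replicate id.
#' @return fragment data frame; `insert_length` is derived as `end - start`.
#' @export
fragments <- function(chrom, start, end, sample_id, replicate) {
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end),
                  sample_id = as.character(sample_id),
                  replicate = as.character(replicate),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x$insert_length <- x$end - x$start
  x
}

#' Write fragments as BED3
#' @param x fragment data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(x, path) {
  write_bed(x[, c("chrom", "start", "end")], path)
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return [genome_model()] with sequence.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  s <- as.character(seqs)
  names(s) <- sub("\\s.*$", "", names(seqs))
  genome_model(setNames(nchar(s), names(s)), sequence = s)
}

#' Write a genome FASTA
#' @param genome [genome_model()] with sequence.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.null(genome$sequence)) stop("genome has no sequence")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$sequence), path)
  invisible(path)
}

#' Read gene annotation from GFF3-lite
#'
#' Understands `TSS` and `exon` feature rows with a `gene_id=` attribute.
#' GFF coordinates (1-based closed) are converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @return [gene_annotation()].
#' @export
read_gff3_lite <- function(path) {
  fields <- read_tsv_lines(path, 9, "GFF3")
  get <- function(i) vapply(fields, `[`, "", i)
  type <- get(3)
  gene <- sub(".*gene_id=([^;]+).*", "\\1", get(9))
  x <- data.frame(chrom = get(1),
                  start = num_or_stop(get(4), "start", path) - 1,
                  end = num_or_stop(get(5), "end", path),
                  strand = get(7), name = gene, stringsAsFactors = FALSE)
  gene_annotation(tss = x[type == "TSS", ], exons = x[type == "exon", ])
}

#' Write gene annotation as GFF3-lite
#' @param annotation [gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3_lite <- function(annotation, path) {
  row <- function(x, type) {
    if (nrow(x) == 0) return(NULL)
    x <- x[order(x$chrom, x$start), ]
    paste(x$chrom, "atacdyn", type,
          format(x$start + 1, scientific = FALSE, trim = TRUE),
          format(x$end, scientific = FALSE, trim = TRUE),
          ".", x$strand, ".", paste0("gene_id=", x$name), sep = "\t")
  }
  writeLines(c("##gff-version 3",
               row(annotation$tss, "TSS"), row(annotation$exons, "exon")),
             path)
  invisible(path)
}

#' Read a chromatin-state segmentation BED
#' @param path 4-column BED (`chrom`, `start`, `end`, `state`).
#' @param stage stage label.
#' @param genome optional [genome_model()]; gaps filled as `"unannotated"`.
#' @return [state_segmentation()].
#' @export
read_state_bed <- function(path, stage, genome = NULL) {
  fields <- read_tsv_lines(path, 4, "state BED")
  get <- function(i) vapply(fields, `[`, "", i)
  seg <- data.frame(chrom = get(1),
                    start = num_or_stop(get(2), "start", path),
                    end = num_or_stop(get(3), "end", path),
                    state = get(4), stringsAsFactors = FALSE)
  state_segmentation(seg, stage, genome)
}

#' Write a chromatin-state segmentation BED
#' @param seg [state_segmentation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_state_bed <- function(seg, path) {
  s <- seg$segments[order(seg$segments$chrom, seg$segments$start), ]
  writeLines(paste(s$chrom,
                   format(s$start, scientific = FALSE, trim = TRUE),
                   format(s$end, scientific = FALSE, trim = TRUE),
                   s$state, sep = "\t"), path)
  invisible(path)
}

#' Read a score track from TSV
#'
#' Expects a header line `# bin_size=<n>` followed by `chrom<TAB>bin<TAB>value`
#' rows (bin is 1-based).
#'
#' @param path TSV file.
#' @param genome [genome_model()].
#' @return [score_track()].
#' @export
read_score_track <- function(path, genome) {
  lines <- readLines(path)
  hdr <- grep("^# bin_size=", lines, value = TRUE)
  if (!length(hdr)) stop("score track lacks '# bin_size=' header: ", path)
  bs <- as.numeric(sub("^# bin_size=", "", hdr[1]))
  dat <- read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                    col.names = c("chrom", "bin", "value"))
  values <- lapply(setNames(genome$chrom_names, genome$chrom_names),
                   function(ch) {
    d <- dat[dat$chrom == ch, ]
    v <- numeric(ceiling(genome$chrom_lengths[[ch]] / bs))
    v[d$bin] <- d$value
    v
  })
  score_track(values, bs, genome)
}

#' Write a score track as TSV
#' @param track [score_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_track <- function(track, path) {
  rows <- lapply(names(track$values), function(ch)
    data.frame(chrom = ch, bin = seq_along(track$values[[ch]]),
               value = track$values[[ch]]))
  dat <- do.call(rbind, rows)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# bin_size=%d", as.integer(track$bin_size)), con)
  write.table(dat, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
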