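# Position weight matrices, motif scanning and motif-count features.

#' Construct a position weight matrix
#'
#' @param id motif identifier.
#' @param mat 4 x L probability matrix with rows A, C, G, T; columns must sum
#'   to 1 (tolerance 1e-6) and L must be at least 4.
#' @param background base frequencies (A, C, G, T); default uniform.
#' @param threshold hit threshold as a fraction of the maximal achievable
#'   log-odds score.
#' @return an object of class `pwm`.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4), threshold = 0.8) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(mat) < 4) stop("PWM must have length >= 4")
  if (any(abs(colSums(mat) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-6,
            threshold > 0, threshold <= 1)
  dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
  structure(list(id = id, mat = mat, background = background,
                 threshold = threshold), class = "pwm")
}

# log2-odds matrix with a floor so zero probabilities stay finite
pwm_logodds <- function(p) {
  log2(pmax(p$mat, 1e-4) / p$background)
}

pwm_revcomp <- function(p) {
  m <- p$mat[4:1, ncol(p$mat):1, drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  pwm(p$id, m, p$background[4:1], p$threshold)
}

#' Consensus sequence of a PWM (maximum-probability base per column)
#' @param p a [pwm()].
#' @return character scalar.
#' @export
pwm_consensus <- function(p) {
  paste(c("A", "C", "G", "T")[apply(p$mat, 2, which.max)], collapse = "")
}

#' Scan a sequence with a PWM on both strands
#'
#' Computes the log-odds score of every window on the forward and reverse
#' strand; a window is a hit when its score reaches
#' `threshold * max achievable score`.  `N` bases score as background (zero
#' log-odds contribution).
#'
#' @param sequence character scalar over A/C/G/T/N.
#' @param p a [pwm()].
#' @return data frame of hits with `position` (0-based window start),
#'   `strand` and `score`; empty when the sequence is shorter than the motif.
#' @export
scan_pwm <- function(sequence, p) {
  L <- ncol(p$mat)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  empty <- data.frame(position = integer(), strand = character(),
                      score = numeric())
  if (n < L) return(empty)
  if (!all(chars %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains characters outside A/C/G/T/N")
  codes <- match(chars, c("A", "C", "G", "T"))   # N -> NA
  score_strand <- function(q) {
    lo <- pwm_logodds(q)
    s <- numeric(n - L + 1)
    for (j in seq_len(L)) {
      col <- lo[, j][codes[j:(n - L + j)]]
      col[is.na(col)] <- 0
      s <- s + col
    }
    s
  }
  fwd <- score_strand(p)
  rev <- score_strand(pwm_revcomp(p))
  max_score <- sum(apply(pwm_logodds(p), 2, max))
  cut <- p$threshold * max_score
  fi <- which(fwd >= cut); ri <- which(rev >= cut)
  hits <- rbind(
    data.frame(position = fi - 1L, strand = rep("+", length(fi)),
               score = fwd[fi]),
    data.frame(position = ri - 1L, strand = rep("-", length(ri)),
               score = rev[ri]))
  hits[order(hits$position), , drop = FALSE]
}

#' Count motif occurrences in catalog peaks
#'
#' Counts distinct hit window positions per peak per motif; a window matching
#' on both strands (e.g. a palindrome) counts once.
#'
#' @param peaks interval data frame (the catalog).
#' @param genome [genome_model()] with sequence.
#' @param pwms list of [pwm()] objects.
#' @return a `peaks x motifs` integer matrix; row names are peak names (or
#'   row indices), column names motif ids.
#' @export
motif_count_matrix <- function(peaks, genome, pwms) {
  if (is.null(genome$sequence)) stop("genome has no sequence")
  validate_intervals(peaks, genome)
  ids <- vapply(pwms, function(p) p$id, "")
  counts <- matrix(0L, nrow(peaks), length(pwms),
                   dimnames = list(peaks$name %||% NULL, ids))
  if (!is.null(peaks$name)) rownames(counts) <- peaks$name
  for (i in seq_len(nrow(peaks))) {
    s <- substr(genome$sequence[[peaks$chrom[i]]],
                peaks$start[i] + 1, peaks$end[i])
    for (j in seq_along(pwms)) {
      h <- scan_pwm(s, pwms[[j]])
      counts[i, j] <- length(unique(h$position))
    }
  }
  counts
}

#' Read PWMs from minimal MEME text format
#' @param path MEME file (`MEME version`, `MOTIF`, `letter-probability matrix`).
#' @param threshold hit threshold passed to [pwm()].
#' @return named list of [pwm()] objects.
#' @export
read_pwms_meme <- function(path, threshold = 0.8) {
  lines <- trimws(readLines(path))
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("no MOTIF blocks in ", path)
  out <- list()
  bg <- rep(0.25, 4)
  bgline <- grep("^Background letter frequencies", lines)
  if (length(bgline) && bgline[1] < length(lines)) {
    tok <- strsplit(lines[bgline[1] + 1], "\\s+")[[1]]
    freq <- suppressWarnings(as.numeric(tok[c(2, 4, 6, 8)]))
    if (!anyNA(freq)) bg <- freq
  }
  for (s in starts) {
    id <- strsplit(lines[s], "\\s+")[[1]][2]
    hdr <- s + which(grepl("^letter-probability matrix",
                           lines[(s + 1):length(lines)]))[1]
    if (is.na(hdr)) stop("motif ", id, " lacks a probability matrix")
    rows <- list()
    i <- hdr + 1
    while (i <= length(lines) && grepl("^[-0-9.eE+ \t]+$", lines[i]) &&
           nzchar(lines[i])) {
      rows[[length(rows) + 1]] <-
        as.numeric(strsplit(lines[i], "\\s+")[[1]])
      i <- i + 1
    }
    mat <- t(do.call(rbind, rows))
    out[[id]] <- pwm(id, mat, background = bg, threshold = threshold)
  }
  out
}

#' Write PWMs in minimal MEME text format
#' @param pwms named list of [pwm()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwms_meme <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(p$mat)), con)
    writeLines(apply(p$mat, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from a long-format TSV
#'
#' Expects columns `motif`, `pos`, `A`, `C`, `G`, `T` (with header).
#'
#' @param path TSV file.
#' @param threshold hit threshold passed to [pwm()].
#' @return named list of [pwm()] objects.
#' @export
read_pwms_tsv <- function(path, threshold = 0.8) {
  dat <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("motif", "pos", "A", "C", "G", "T")
  if (!all(need %in% names(dat)))
    stop("PWM TSV needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (id in unique(dat$motif)) {
    d <- dat[dat$motif == id, ]
    d <- d[order(d$pos), ]
    out[[id]] <- pwm(id, t(as.matrix(d[, c("A", "C", "G", "T")])),
                     threshold = threshold)
  }
  out
}
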