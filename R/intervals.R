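#' Build an interval table
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end` and
#' optionally `strand`, `name`, `score`.  Coordinates are 0-based half-open.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param strand one of `"+"`, `"-"`, `"."` (recycled).
#' @param name optional identifiers.
#' @param score optional numeric scores.
#' @return a validated interval data frame.
#' @export
#' @examples
#' intervals("chrI", 0, 10)
intervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                      score = NA_real_) {
  x <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                  end = as.numeric(end), strand = as.character(strand),
                  name = as.character(name), score = as.numeric(score),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  x
}

#' Validate an interval table
#'
#' Checks the half-open coordinate invariants and, when a genome is given,
#' that every interval lies on a declared chromosome within its length.
#'
#' @param x interval data frame (columns `chrom`, `start`, `end`).
#' @param genome optional [genome_model()].
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x))
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss)) stop("interval table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
    stop("non-finite interval coordinates")
  if (any(x$start < 0)) stop("negative start coordinate")
  bad <- which(x$start >= x$end)
  if (length(bad)) stop("start >= end at row ", bad[1],
                        " (", x$chrom[bad[1]], ":", x$start[bad[1]], "-",
                        x$end[bad[1]], ")")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), genome$chrom_names)
    if (length(unknown)) stop("chromosome(s) not in genome: ",
                              paste(unknown, collapse = ", "))
    lens <- genome$chrom_lengths[x$chrom]
    over <- which(x$end > lens)
    if (length(over)) stop("interval exceeds chromosome length at row ",
                           over[1])
  }
  invisible(x)
}

# 0-based half-open data frame -> GRanges (1-based closed) and back.
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) ifelse(x$strand == ".", "*", x$strand)
            else "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(x$start + 1, x$end),
                         strand = strand)
}

from_granges <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = ifelse(s == "*", ".", s),
             stringsAsFactors = FALSE)
}

#' Overlapping pairs between two interval sets
#'
#' Half-open overlap arithmetic: intervals sharing only a boundary do not
#' overlap; the overlap width of a pair is `min(end) - max(start)`.
#'
#' @param a,b interval data frames on the same chromosome namespace.
#' @return data frame with `query` (row in `a`), `subject` (row in `b`) and
#'   `overlap_bp`.
#' @export
#' @examples
#' interval_overlap(intervals("chrI", 0, 10), intervals("chrI", 5, 8))
interval_overlap <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) && nrow(b) &&
      length(intersect(unique(a$chrom), unique(b$chrom))) == 0)
    stop("interval sets share no chromosome names; mismatched namespaces?")
  hits <- GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                      ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  data.frame(query = q, subject = s,
             overlap_bp = pmin(a$end[q], b$end[s]) -
                          pmax(a$start[q], b$start[s]))
}

#' Merge intervals within a gap
#'
#' Any two intervals separated by at most `gap` bp (overlapping, adjacent, or
#' closer than the gap) are merged.  Output is sorted and non-overlapping.
#'
#' @param x interval data frame.
#' @param gap non-negative merge distance in bp.
#' @return merged interval data frame (`chrom`, `start`, `end`).
#' @export
merge_intervals <- function(x, gap = 0) {
  stopifnot(gap >= 0)
  validate_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(as_granges(x), min.gapwidth = gap + 1,
                              ignore.strand = TRUE)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  out <- from_granges(gr)
  out[, c("chrom", "start", "end")]
}

# Point coordinate of an interval: its start for 1-bp intervals (summits,
# TSSs), otherwise the floor midpoint.
interval_point <- function(x) {
  ifelse(x$end - x$start == 1L, x$start, floor((x$start + x$end) / 2))
}

#' Nearest stranded feature with signed distance
#'
#' For each query interval, finds the feature minimising the absolute
#' point-to-point distance (query midpoint to feature position).  Distance is
#' signed relative to the FEATURE's strand: negative means the query lies
#' upstream of the feature.  Queries overlapping a feature get distance 0.
#'
#' @param query interval data frame.
#' @param features stranded interval data frame (e.g. TSSs), non-empty.
#' @return data frame with `feature` (row index into `features`),
#'   `feature_name` and `distance`.
#' @export
nearest_feature <- function(query, features) {
  validate_intervals(query)
  validate_intervals(features)
  if (nrow(features) == 0) stop("feature set is empty")
  if (!"strand" %in% names(features) || any(features$strand == "."))
    stop("features must be stranded")
  qp <- interval_point(query)
  fp <- interval_point(features)
  out <- data.frame(feature = rep(NA_integer_, nrow(query)),
                    feature_name = NA_character_, distance = NA_real_)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    if (!length(fi)) next
    # nearest by point distance
    ord <- fi[order(fp[fi])]
    pos <- fp[ord]
    idx <- findInterval(qp[qi], pos)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(pos))
    pick <- ifelse(abs(qp[qi] - pos[lo]) <= abs(qp[qi] - pos[hi]), lo, hi)
    f <- ord[pick]
    d <- ifelse(features$strand[f] == "-", fp[f] - qp[qi], qp[qi] - fp[f])
    ovl <- query$start[qi] < features$end[f] & features$start[f] < query$end[qi]
    d[ovl] <- 0
    out$feature[qi] <- f
    out$distance[qi] <- d
  }
  if (anyNA(out$feature))
    stop("no feature on chromosome(s): ",
         paste(unique(query$chrom[is.na(out$feature)]), collapse = ", "))
  if ("name" %in% names(features))
    out$feature_name <- features$name[out$feature]
  out
}
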