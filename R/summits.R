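# Fragment-size and signal statistics at ChIP summits, per-factor histograms
# with class aggregation, pairwise comparisons, nucleosome-occupancy change,
# and peak-set overlap.

# fragments overlapping [summit - w, summit + w] for every summit
summit_overlaps <- function(frags, summits, w) {
  win <- data.frame(chrom = summits$chrom,
                    start = pmax(summits$start - w, 0),
                    end = summits$start + w + 1)
  interval_overlap(win, frags)
}

#' Fragment statistics at ChIP summits
#'
#' Per summit: the median insert length and depth-normalised signal
#' (fragments per million) over fragments overlapping `summit +/- w`.
#' Summits with no overlapping fragment are flagged `covered = FALSE` and
#' excluded from the factor-level medians.
#'
#' @param frags fragment data frame.
#' @param summits 1-bp summit interval data frame.
#' @param w half-window in bp (> 0).
#' @return list with `per_summit` (data frame: `summit`, `n_fragments`,
#'   `median_insert`, `signal_fpm`, `covered`), `factor_median_insert`
#'   (median of per-summit medians) and `factor_median_signal`.
#' @export
summit_fragstats <- function(frags, summits, w = 50) {
  if (w <= 0) stop("w must be positive")
  if (nrow(summits) == 0) stop("empty summit set")
  hits <- summit_overlaps(frags, summits, w)
  len <- frags$insert_length %||% (frags$end - frags$start)
  med <- rep(NA_real_, nrow(summits))
  nfr <- integer(nrow(summits))
  if (nrow(hits)) {
    agg <- split(len[hits$subject], hits$query)
    idx <- as.integer(names(agg))
    med[idx] <- vapply(agg, median, numeric(1))
    nfr[idx] <- lengths(agg)
  }
  per <- data.frame(summit = seq_len(nrow(summits)),
                    chrom = summits$chrom, pos = summits$start,
                    n_fragments = nfr,
                    median_insert = med,
                    signal_fpm = nfr / nrow(frags) * 1e6,
                    covered = nfr > 0)
  list(per_summit = per,
       factor_median_insert = median(per$median_insert[per$covered]),
       factor_median_signal = median(per$signal_fpm[per$covered]),
       w = w)
}

#' Fragment-size histograms per factor, aggregated by class
#'
#' Per factor, the percentage histogram (1-bp bins, 1-1000) of insert
#' lengths of fragments overlapping its summit windows; class aggregation is
#' the mean of member-factor percentage vectors per bin.
#'
#' @param frags fragment data frame.
#' @param summits_by_factor named list of summit data frames.
#' @param classes named character vector mapping factor -> class (optional).
#' @param w half-window in bp.
#' @return list with `percent` (factors x 1000 matrix of percentages) and
#'   `class_percent` (classes x 1000, when classes given).
#' @export
factor_fragsize_histogram <- function(frags, summits_by_factor,
                                      classes = NULL, w = 50) {
  if (!length(summits_by_factor)) stop("need at least one factor")
  len <- frags$insert_length %||% (frags$end - frags$start)
  rows <- list()
  for (f in names(summits_by_factor)) {
    hits <- summit_overlaps(frags, summits_by_factor[[f]], w)
    if (nrow(hits) == 0) {
      warning("factor ", f, " has no covered summits; excluded")
      next
    }
    l <- len[hits$subject]
    counts <- tabulate(l[l >= 1 & l <= 1000], nbins = 1000)
    rows[[f]] <- 100 * counts / sum(counts)
  }
  if (!length(rows)) stop("no factor has covered summits")
  percent <- do.call(rbind, rows)
  colnames(percent) <- seq_len(1000)
  out <- list(percent = percent, w = w)
  if (!is.null(classes)) {
    cls <- classes[rownames(percent)]
    out$class_percent <- do.call(rbind, lapply(unique(cls), function(cl)
      colMeans(percent[cls == cl, , drop = FALSE])))
    rownames(out$class_percent) <- unique(cls)
  }
  out
}

#' Compare fragment sizes of one factor against others
#'
#' Two-sided Mann-Whitney tests of the per-summit median insert lengths of a
#' reference factor against every other factor, BH-adjusted.
#'
#' @param stats_list named list of [summit_fragstats()] results.
#' @param reference name of the reference factor.
#' @param min_summits minimal covered summits per factor.
#' @return data frame per comparison: `factor`, `median_ref`, `median_other`,
#'   `direction` (`ref_larger`/`ref_smaller`/`none`), `p`, `q`.
#' @export
compare_fragsize <- function(stats_list, reference, min_summits = 10) {
  if (!reference %in% names(stats_list))
    stop("reference factor not in stats list")
  meds <- lapply(stats_list, function(s) {
    p <- s$per_summit
    p$median_insert[p$covered]
  })
  short <- names(meds)[lengths(meds) < min_summits]
  if (length(short))
    stop("factor(s) with fewer than ", min_summits, " covered summits: ",
         paste(short, collapse = ", "))
  others <- setdiff(names(stats_list), reference)
  if (!length(others)) stop("self-comparison only; nothing to compare")
  rows <- lapply(others, function(f) {
    wt <- wilcox.test(meds[[reference]], meds[[f]], exact = FALSE)
    dm <- median(meds[[reference]]) - median(meds[[f]])
    data.frame(factor = f,
               median_ref = median(meds[[reference]]),
               median_other = median(meds[[f]]),
               direction = if (dm > 0) "ref_larger"
                           else if (dm < 0) "ref_smaller" else "none",
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Nucleosome-occupancy change at summits
#'
#' Per summit, the difference of depth-normalised H3 occupancy (track B
#' minus track A) averaged over `summit +/- w`.  Both tracks must be
#' normalised to genome-wide mean 1 (5% tolerance).  The factor-level
#' summary is the median difference with a bootstrap percentile CI.
#'
#' @param h3_A,h3_B [score_track()]s for the two stages.
#' @param summits 1-bp summit interval data frame.
#' @param genome a [genome_model()].
#' @param w half-window in bp.
#' @param B bootstrap iterations for the CI of the median.
#' @param seed RNG seed.
#' @return list with `per_summit` (`delta` per summit), `median_delta`,
#'   `ci_lo`, `ci_hi`.
#' @export
occupancy_change <- function(h3_A, h3_B, summits, genome, w = 100,
                             B = 1000, seed = 1) {
  mA <- track_genome_mean(h3_A); mB <- track_genome_mean(h3_B)
  if (abs(mA - 1) > 0.05 || abs(mB - 1) > 0.05)
    stop("tracks must be depth-normalised to mean 1 (observed means ",
         sprintf("%.3f, %.3f", mA, mB), "); see normalize_track()")
  lo <- pmax(summits$start - w, 0)
  hi <- pmin(summits$start + w + 1, genome$chrom_lengths[summits$chrom])
  delta <- track_mean(h3_B, summits$chrom, lo, hi) -
           track_mean(h3_A, summits$chrom, lo, hi)
  set.seed(seed)
  boot <- vapply(seq_len(B), function(b)
    median(delta[sample.int(length(delta), replace = TRUE)]), numeric(1))
  list(per_summit = data.frame(chrom = summits$chrom, pos = summits$start,
                               delta = delta),
       median_delta = median(delta),
       ci_lo = quantile(boot, 0.025, names = FALSE),
       ci_hi = quantile(boot, 0.975, names = FALSE),
       w = w, B = B)
}

#' Normalise a score track to genome-wide mean 1
#' @param track a [score_track()].
#' @return the normalised track.
#' @export
normalize_track <- function(track) {
  m <- track_genome_mean(track)
  if (m <= 0) stop("track mean must be positive")
  track$values <- lapply(track$values, function(v) v / m)
  track
}

#' Pairwise Jaccard overlap of peak sets
#'
#' Jaccard index in base pairs (`intersection bp / union bp`) for every pair
#' of peak sets; symmetric with unit diagonal.
#'
#' @param peak_sets named list of >= 2 interval data frames.
#' @return symmetric matrix of Jaccard indices.
#' @export
peakset_overlap <- function(peak_sets) {
  if (length(peak_sets) < 2) stop("need at least 2 peak sets")
  empty <- names(peak_sets)[vapply(peak_sets, nrow, 1L) == 0]
  if (length(empty)) stop("empty peak set(s): ", paste(empty, collapse = ", "))
  n <- length(peak_sets)
  merged <- lapply(peak_sets, merge_intervals)
  bp <- vapply(merged, function(x) sum(x$end - x$start), numeric(1))
  J <- diag(1, n)
  dimnames(J) <- list(names(peak_sets), names(peak_sets))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ov <- interval_overlap(merged[[i]], merged[[j]])
    inter <- sum(ov$overlap_bp)
    J[i, j] <- J[j, i] <- inter / (bp[i] + bp[j] - inter)
  }
  J
}
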