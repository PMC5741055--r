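# Library quality metrics: insert-size periodicity, TSS enrichment profile,
# cross-sample correlation clustering.

#' Insert-size histogram
#'
#' Counts per 1-bp insert-length bin over the range 1-1000; longer fragments
#' are accumulated in an `overflow` attribute and excluded from periodicity
#' estimation.
#'
#' @param frags fragment data frame.
#' @return an object of class `insert_size_histogram`: integer vector of
#'   length 1000 (bin i = count of fragments with insert length i).
#' @export
insert_size_histogram <- function(frags) {
  if (nrow(frags) == 0) stop("no fragments")
  len <- frags$insert_length %||% (frags$end - frags$start)
  counts <- tabulate(len[len >= 1 & len <= 1000], nbins = 1000)
  structure(counts, overflow = sum(len > 1000),
            class = "insert_size_histogram")
}

# lagged autocorrelation of a vector at the given lags
acf_at_lags <- function(x, lags) {
  n <- length(x)
  vapply(lags, function(L) {
    a <- x[seq_len(n - L)]
    b <- x[seq_len(n - L) + L]
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }, numeric(1))
}

#' Estimate nucleosome periodicity of an insert-size distribution
#'
#' Log counts over the informative length range (up to the 99.9th percentile
#' insert length plus 50 bp) are detrended with a 201-bp running median; the
#' period is the lag of maximal autocorrelation of the nucleosomal-range
#' residual (lengths >= 100 bp) in the 100-200 bp lag window.  Significance
#' is the z-score of that maximal autocorrelation against `n_perm`
#' permutations of the residual (the same max-over-window statistic on
#' shuffled values); a period is reported only at z >= `z_min` and when the
#' best lag is interior to the window.
#'
#' @param hist an [insert_size_histogram()].
#' @param lag_range lag window searched (bp).
#' @param n_perm number of permutations.
#' @param z_min minimal z-score to report a period.
#' @param seed RNG seed for the permutations.
#' @return list with `period` (bp, or `NA` when not significant or the
#'   histogram has fewer than 10,000 fragments), `z` and `acf_max`.
#' @export
estimate_periodicity <- function(hist, lag_range = c(100, 200),
                                 n_perm = 1000, z_min = 3, seed = 1) {
  counts <- as.numeric(hist)
  if (sum(counts) < 10000) {
    warning("fewer than 10,000 fragments in range; periodicity not estimated")
    return(list(period = NA_real_, z = NA_real_, acf_max = NA_real_))
  }
  upper <- max(which(cumsum(counts) <= 0.999 * sum(counts))) + 50
  upper <- min(max(upper, 300), length(counts))
  lc <- log1p(counts[seq_len(upper)])
  resid <- (lc - runmed(lc, 201))[100:upper]
  lags <- seq(lag_range[1], lag_range[2])
  ac <- acf_at_lags(resid, lags)
  obs <- max(ac)
  best <- which.max(ac)
  period <- lags[best]
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(b)
    max(acf_at_lags(sample(resid), lags)), numeric(1))
  z <- (obs - mean(perm)) / sd(perm)
  edge <- best == 1L || best == length(lags)
  if (!is.finite(z) || z < z_min || edge)
    return(list(period = NA_real_, z = z, acf_max = obs))
  list(period = period, z = z, acf_max = obs)
}

#' Tn5 insertion-event positions of a fragment set
#'
#' Each fragment contributes an event at `start` and at `end - 1` (the two
#' cut sites).
#'
#' @param frags fragment data frame.
#' @return data frame with `chrom` and `pos` (0-based), two rows per fragment.
#' @export
cutsites <- function(frags) {
  data.frame(chrom = rep(frags$chrom, 2),
             pos = c(frags$start, frags$end - 1))
}

#' ATAC signal profile around TSSs
#'
#' Mean insertion-event count per position in `[-flank, +flank]` around each
#' TSS, oriented by TSS strand (upstream on the left), normalised to the
#' mean of the outer 100 bp of each flank.  The enrichment score is the
#' normalised value at position 0.
#'
#' @param frags fragment data frame.
#' @param tss stranded 1-bp TSS interval data frame.
#' @param flank half-window in bp.
#' @return list with `position`, `profile` (normalised), `raw` (mean counts)
#'   and `score`.
#' @export
tss_profile <- function(frags, tss, flank = 500) {
  if (nrow(tss) == 0) stop("empty TSS set")
  cuts <- cutsites(frags)
  counts <- numeric(2 * flank + 1)
  for (ch in unique(tss$chrom)) {
    tp <- tss$start[tss$chrom == ch]
    tstr <- tss$strand[tss$chrom == ch]
    cp <- sort(cuts$pos[cuts$chrom == ch])
    if (!length(cp)) next
    for (i in seq_along(tp)) {
      lo <- findInterval(tp[i] - flank - 1, cp) + 1
      hi <- findInterval(tp[i] + flank, cp)
      if (hi < lo) next
      rel <- cp[lo:hi] - tp[i]
      if (tstr[i] == "-") rel <- -rel
      counts <- counts + tabulate(rel + flank + 1, nbins = 2 * flank + 1)
    }
  }
  raw <- counts / nrow(tss)
  edge <- c(seq_len(100), seq(2 * flank - 98, 2 * flank + 1))
  base <- mean(raw[edge])
  profile <- if (base > 0) raw / base else raw
  list(position = seq(-flank, flank), profile = profile, raw = raw,
       score = profile[flank + 1])
}

#' Cross-sample correlation and clustering of peak signal
#'
#' Pairwise Spearman correlation of per-peak signal between samples, plus
#' average-linkage hierarchical clustering on `1 - rho`.
#'
#' @param signal numeric matrix, samples in rows, consensus peaks in columns.
#' @return list with `rho` (correlation matrix), `hclust` and `order`
#'   (leaf order, sample names).
#' @export
sample_correlation_clustering <- function(signal) {
  if (nrow(signal) < 2) stop("need at least 2 samples")
  if (ncol(signal) < 10) stop("need at least 10 peaks")
  sds <- apply(signal, 1, sd)
  if (any(sds == 0))
    stop("constant signal (zero variance) in sample(s): ",
         paste(rownames(signal)[sds == 0], collapse = ", "))
  rho <- cor(t(signal), method = "spearman")
  hc <- hclust(as.dist(1 - rho), method = "average")
  list(rho = rho, hclust = hc, order = rownames(signal)[hc$order])
}

#' Log-scale depth-normalised peak signal matrix
#'
#' The signal used for sample correlation:
#' `log2(1 + 1e6 * count / depth)` per consensus peak.
#'
#' @param counts peaks x samples count matrix with a `depth` attribute (or
#'   `depth` supplied).
#' @param depth per-sample fragment totals (named).
#' @return samples x peaks signal matrix.
#' @export
peak_signal_matrix <- function(counts, depth = attr(counts, "depth")) {
  if (is.null(depth)) stop("sample depths required")
  cpm <- t(t(counts) / depth[colnames(counts)] * 1e6)
  t(log2(1 + cpm))
}
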