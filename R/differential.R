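# Per-peak quantification and stage-vs-stage differential accessibility
# with FDR-based three-class dynamics labels.

#' Fragment counts per catalog peak
#'
#' A fragment is assigned to the single catalog peak containing its midpoint
#' (floor of start+end over 2; half-open, so a midpoint on a peak start is
#' counted).
#'
#' @param catalog non-overlapping catalog peak data frame with `name`.
#' @param frag_list named list of fragment data frames (one per sample).
#' @return peaks x samples integer matrix with attribute `depth` (per-sample
#'   fragment totals).
#' @export
peak_counts <- function(catalog, frag_list) {
  if (nrow(catalog) == 0) stop("catalog is empty")
  orig <- order(order(catalog$chrom, catalog$start))  # restores input order
  catalog <- catalog[order(catalog$chrom, catalog$start), ]
  counts <- matrix(0L, nrow(catalog), length(frag_list),
                   dimnames = list(catalog$name, names(frag_list)))
  for (s in names(frag_list)) {
    fr <- frag_list[[s]]
    mid <- (fr$start + fr$end) %/% 2
    for (ch in unique(catalog$chrom)) {
      ci <- which(catalog$chrom == ch)
      fi <- which(fr$chrom == ch)
      if (!length(fi)) next
      idx <- findInterval(mid[fi], catalog$start[ci])
      ok <- idx >= 1
      ok[ok] <- mid[fi][ok] < catalog$end[ci][idx[ok]]
      tab <- tabulate(idx[ok], nbins = length(ci))
      counts[ci, s] <- counts[ci, s] + tab
    }
  }
  counts <- counts[orig, , drop = FALSE]
  attr(counts, "depth") <- vapply(frag_list, nrow, numeric(1))
  counts
}

#' Differential accessibility between two stages
#'
#' Per-peak Welch t-test on `log2(CPM + 1)` across replicates, BH-adjusted
#' across the catalog.  `log2FC` is the depth-normalised fold change of
#' stage B over stage A with pseudocount 1 on mean CPM.  Dynamics class:
#' `increase` iff `q < alpha` and `log2FC > 0`; `decrease` iff `q < alpha`
#' and `log2FC < 0`; otherwise `no-change`.
#'
#' @param counts peaks x samples matrix from [peak_counts()] (or with a
#'   `depth` attribute).
#' @param sample_stages named character vector mapping sample (column) names
#'   to stage labels.
#' @param stageA,stageB the two stages compared (B vs A).
#' @param alpha FDR threshold for class assignment.
#' @return data frame: `peak`, `baseMeanA`, `baseMeanB`, `log2FC`, `p`, `q`,
#'   `class`.
#' @export
differential_test <- function(counts, sample_stages, stageA, stageB,
                              alpha = 0.05) {
  depth <- attr(counts, "depth")
  if (is.null(depth)) stop("counts need a `depth` attribute")
  a_cols <- names(sample_stages)[sample_stages == stageA]
  b_cols <- names(sample_stages)[sample_stages == stageB]
  if (length(a_cols) < 2 || length(b_cols) < 2)
    stop("need at least 2 replicates per stage")
  cpm <- t(t(counts[, c(a_cols, b_cols), drop = FALSE]) /
             depth[c(a_cols, b_cols)] * 1e6)
  x <- log2(cpm + 1)
  xa <- x[, a_cols, drop = FALSE]; xb <- x[, b_cols, drop = FALSE]
  na <- length(a_cols); nb <- length(b_cols)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  se2 <- va / na + vb / nb
  t_stat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  p <- 2 * pt(-abs(t_stat), df)
  # degenerate zero-variance rows: identical means -> 1, separated -> 0
  zero <- se2 == 0
  p[zero] <- ifelse(mb[zero] == ma[zero], 1, 0)
  p[is.na(p)] <- 1
  q <- p.adjust(p, method = "BH")
  mca <- rowMeans(cpm[, a_cols, drop = FALSE])
  mcb <- rowMeans(cpm[, b_cols, drop = FALSE])
  log2fc <- log2((mcb + 1) / (mca + 1))
  cls <- ifelse(q < alpha & log2fc > 0, "increase",
         ifelse(q < alpha & log2fc < 0, "decrease", "no-change"))
  data.frame(peak = rownames(counts), baseMeanA = mca, baseMeanB = mcb,
             log2FC = log2fc, p = p, q = q, class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Peaks in one dynamics class
#'
#' @param results a [differential_test()] result.
#' @param class one of `"increase"`, `"decrease"`, `"no-change"`.
#' @return character vector of peak ids.
#' @export
subset_by_class <- function(results, class) {
  if (!class %in% c("increase", "decrease", "no-change"))
    stop("unknown dynamics class: ", class)
  results$peak[results$class == class]
}

#' Write differential results as TSV
#' @param results a [differential_test()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
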