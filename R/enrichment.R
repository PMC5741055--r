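# Distal-noncoding classification, enhancer-candidate ranking, bootstrap
# enrichment in chromatin states, state-transition enrichment, and the
# small-sample exact statistics.

#' Classify peaks by position relative to genes
#'
#' The rule is applied at the peak SUMMIT: `promoter_proximal` when the
#' summit lies within (-1,000, +500) bp of some TSS (signed relative to the
#' TSS strand, negative = upstream); `exonic` (overriding) when the summit
#' falls in an exon; `distal_noncoding` when the summit is at least 1 kb
#' upstream or at least 0.5 kb downstream of EVERY TSS and not exonic.
#'
#' @param peaks peak data frame with a `summit` column (absolute bp).
#' @param annotation a [gene_annotation()].
#' @param upstream,downstream the promoter window bounds in bp.
#' @return data frame: `peak`, `class`, `nearest_tss`, `distance` (signed,
#'   feature-strand-aware).
#' @export
classify_region <- function(peaks, annotation, upstream = 1000,
                            downstream = 500) {
  if (nrow(annotation$tss) == 0) stop("annotation has no TSS")
  if (!"summit" %in% names(peaks)) stop("peaks need a `summit` column")
  summit <- data.frame(chrom = peaks$chrom, start = peaks$summit,
                       end = peaks$summit + 1)
  near <- nearest_feature(summit, annotation$tss)
  # a peak is promoter-proximal if ANY TSS is within the window, not just
  # the nearest by absolute distance; check all TSSs within `upstream` bp
  tss <- annotation$tss
  prox <- logical(nrow(peaks))
  win <- data.frame(chrom = tss$chrom,
                    start = ifelse(tss$strand == "+",
                                   tss$start - upstream + 1,
                                   tss$start - downstream + 1),
                    end = ifelse(tss$strand == "+",
                                 tss$start + downstream,
                                 tss$start + upstream))
  win$start <- pmax(win$start, 0)
  hit <- interval_overlap(summit, win)
  prox[unique(hit$query)] <- TRUE
  exonic <- logical(nrow(peaks))
  if (nrow(annotation$exons)) {
    hit <- interval_overlap(summit, annotation$exons)
    exonic[unique(hit$query)] <- TRUE
  }
  cls <- ifelse(exonic, "exonic",
         ifelse(prox, "promoter_proximal", "distal_noncoding"))
  data.frame(peak = peaks$name %||% as.character(seq_len(nrow(peaks))),
             class = cls, nearest_tss = near$feature_name,
             distance = near$distance, stringsAsFactors = FALSE)
}

#' Rank distal peaks as enhancer candidates
#'
#' Among `distal_noncoding` peaks, ranks by the largest absolute log2 fold
#' change over all stage-pair comparisons (descending); ties broken by the
#' smaller q of the best pair, then by genomic position.
#'
#' @param results_list list of [differential_test()] results (one per stage
#'   pair).
#' @param classes a [classify_region()] result.
#' @param k number of candidates (>= 1); if fewer distal peaks exist, all
#'   are returned with a warning.
#' @return data frame: `peak`, `max_abs_log2FC`, `best_pair`, `q`, ordered.
#' @export
rank_enhancer_candidates <- function(results_list, classes, k) {
  stopifnot(k >= 1)
  if (is.data.frame(results_list)) results_list <- list(results_list)
  pairs <- names(results_list) %||% paste0("pair", seq_along(results_list))
  distal <- classes$peak[classes$class == "distal_noncoding"]
  tab <- NULL
  for (i in seq_along(results_list)) {
    r <- results_list[[i]]
    r <- r[r$peak %in% distal, c("peak", "log2FC", "q")]
    r$pair <- pairs[i]
    tab <- rbind(tab, r)
  }
  if (is.null(tab) || nrow(tab) == 0)
    stop("no distal peaks with differential results")
  tab$absfc <- abs(tab$log2FC)
  tab <- tab[order(tab$peak, -tab$absfc, tab$q), ]
  best <- tab[!duplicated(tab$peak), ]
  ord <- order(-best$absfc, best$q, best$peak)
  best <- best[ord, c("peak", "absfc", "pair", "q")]
  names(best) <- c("peak", "max_abs_log2FC", "best_pair", "q")
  rownames(best) <- NULL
  if (nrow(best) < k) {
    warning("only ", nrow(best), " distal peaks available (requested ", k,
            ")")
    return(best)
  }
  best[seq_len(k), ]
}

# state of each peak summit under a segmentation
summit_states <- function(peaks, segmentation) {
  state_at(segmentation, peaks$chrom, peaks$summit)
}

#' Bootstrap enrichment of peaks in chromatin states
#'
#' The observed statistic per state is the number of peak summits in that
#' state.  Each of `B` bootstrap draws places length-matched intervals
#' uniformly at random within the original peak's chromosome (keeping the
#' summit offset) and recounts.  Fold is observed over mean null; the 95% CI
#' is the 2.5/97.5 percentile of the observed/null fold distribution;
#' empirical p is `(1 + #(null >= obs)) / (B + 1)` for enrichment (mirrored
#' for depletion) and is reported as the floor `1/B` when no draw reaches
#' the observed value.
#'
#' @param peaks peak data frame with `summit`.
#' @param segmentation a [state_segmentation()] covering the genome.
#' @param genome a [genome_model()].
#' @param B bootstrap iterations.
#' @param seed RNG seed.
#' @return data frame per state: `state`, `observed`, `expected_mean`,
#'   `fold`, `ci_lo`, `ci_hi`, `p`, `p_is_floor`, `direction`, `B`, `seed`.
#' @export
bootstrap_state_enrichment <- function(peaks, segmentation, genome,
                                       B = 10000, seed = 1) {
  if (nrow(peaks) == 0) stop("empty peak set")
  set.seed(seed)
  n <- nrow(peaks)
  obs_state <- summit_states(peaks, segmentation)
  states <- sort(unique(segmentation$segments$state))
  width <- peaks$end - peaks$start
  offset <- peaks$summit - peaks$start
  chrlen <- genome$chrom_lengths[peaks$chrom]
  span <- pmax(chrlen - width, 1)
  # null summit positions: n x B matrix of state codes, per-peak chromosome
  null_codes <- matrix(NA_integer_, n, B)
  seg <- segmentation$segments
  seg_code <- match(seg$state, states)
  for (ch in unique(peaks$chrom)) {
    i <- which(peaks$chrom == ch)
    si <- which(seg$chrom == ch)
    starts <- seg$start[si]; codes <- seg_code[si]
    pos <- floor(runif(length(i) * B) * span[i]) + offset[i]
    idx <- findInterval(pos, starts)
    idx[idx < 1] <- 1
    null_codes[i, ] <- codes[idx]
  }
  rows <- lapply(states, function(st) {
    O <- sum(obs_state == st, na.rm = TRUE)
    Nb <- colSums(null_codes == match(st, states))
    fold_b <- O / ifelse(Nb == 0, NA, Nb)
    n_ge <- sum(Nb >= O); n_le <- sum(Nb <= O)
    enriched <- O >= mean(Nb)
    count <- if (enriched) n_ge else n_le
    p <- (1 + count) / (B + 1)
    floor_hit <- count == 0
    data.frame(state = st, observed = O, expected_mean = mean(Nb),
               fold = if (mean(Nb) > 0) O / mean(Nb) else NA_real_,
               ci_lo = quantile(fold_b, 0.025, na.rm = TRUE, names = FALSE),
               ci_hi = quantile(fold_b, 0.975, na.rm = TRUE, names = FALSE),
               p = if (floor_hit) 1 / B else p,
               p_is_floor = floor_hit,
               direction = if (enriched) "enrichment" else "depletion",
               B = B, seed = seed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' State-transition enrichment of dynamic peaks
#'
#' For every ordered pair of chromatin states (state at stage A -> state at
#' stage B, assigned at the peak summit), tests whether dynamic peaks
#' carry that transition more often than the remaining catalog peaks
#' (one-sided Fisher), BH-adjusted across pairs.
#'
#' @param dynamic_peaks peak data frame (subset of the catalog).
#' @param background_peaks catalog peak data frame (superset of dynamic).
#' @param segA,segB [state_segmentation()] for the two stages.
#' @return data frame per observed transition: `from`, `to`, `n_dynamic`,
#'   `n_background`, `odds_ratio`, `p`, `q`.
#' @export
transition_enrichment <- function(dynamic_peaks, background_peaks,
                                  segA, segB) {
  if (nrow(dynamic_peaks) == 0) stop("empty dynamic peak set")
  if (!all(dynamic_peaks$name %in% background_peaks$name))
    stop("dynamic peaks must be a subset of the background catalog")
  pair_of <- function(pk) paste(summit_states(pk, segA),
                                summit_states(pk, segB), sep = "->")
  dyn <- pair_of(dynamic_peaks)
  is_dyn <- background_peaks$name %in% dynamic_peaks$name
  rest <- pair_of(background_peaks[!is_dyn, , drop = FALSE])
  pairs <- sort(unique(c(dyn, rest)))
  rows <- lapply(pairs, function(pr) {
    a <- sum(dyn == pr);  b <- sum(dyn != pr)
    c_ <- sum(rest == pr); d <- sum(rest != pr)
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    data.frame(from = sub("->.*", "", pr), to = sub(".*->", "", pr),
               n_dynamic = a, n_background = a + c_,
               odds_ratio = or,
               p = fisher_one_sided(matrix(c(a, c_, b, d), 2)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p, -out$odds_ratio), ]
}

#' One-sided Fisher's exact test (enrichment of the top-left cell)
#'
#' Hypergeometric upper-tail probability of observing the top-left cell or
#' a more extreme (larger) value with all margins fixed.
#'
#' @param table 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`; the tested direction is `a` large relative
#'   to its margins.
#' @return the one-sided p-value.
#' @export
#' @examples
#' fisher_one_sided(rbind(c(5, 8), c(0, 10)))   # 0.038
fisher_one_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)))
  if (any(table < 0)) stop("negative count in contingency table")
  if (any(table != round(table))) stop("counts must be integers")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  if (sum(table) == 0) return(1)
  # X ~ Hypergeometric(m = a+b, n = c+d, k = a+c); p = P(X >= a)
  phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Bootstrap enrichment of a score track over peaks
#'
#' The observed statistic is the mean track value over peak base pairs; the
#' null re-places length-matched intervals uniformly within each peak's
#' chromosome, as in [bootstrap_state_enrichment()].
#'
#' @param peaks peak data frame.
#' @param track a [score_track()].
#' @param genome a [genome_model()].
#' @param B bootstrap iterations.
#' @param seed RNG seed.
#' @return one-row data frame: `observed`, `expected_mean`, `fold`, `ci_lo`,
#'   `ci_hi`, `p`, `p_is_floor`, `direction`, `B`, `seed`.
#' @export
score_enrichment <- function(peaks, track, genome, B = 1000, seed = 1) {
  if (nrow(peaks) == 0) stop("empty peak set")
  if (is.null(track$values) || !length(track$values)) stop("empty track")
  set.seed(seed)
  width <- peaks$end - peaks$start
  obs <- mean(track_mean(track, peaks$chrom, peaks$start, peaks$end))
  chrlen <- genome$chrom_lengths[peaks$chrom]
  span <- pmax(chrlen - width, 1)
  Nb <- vapply(seq_len(B), function(b) {
    st <- floor(runif(nrow(peaks)) * span)
    mean(track_mean(track, peaks$chrom, st, st + width))
  }, numeric(1))
  fold_b <- obs / ifelse(Nb == 0, NA, Nb)
  n_ge <- sum(Nb >= obs); n_le <- sum(Nb <= obs)
  enriched <- obs >= mean(Nb)
  count <- if (enriched) n_ge else n_le
  floor_hit <- count == 0
  data.frame(observed = obs, expected_mean = mean(Nb),
             fold = obs / mean(Nb),
             ci_lo = quantile(fold_b, 0.025, na.rm = TRUE, names = FALSE),
             ci_hi = quantile(fold_b, 0.975, na.rm = TRUE, names = FALSE),
             p = if (floor_hit) 1 / B else (1 + count) / (B + 1),
             p_is_floor = floor_hit,
             direction = if (enriched) "enrichment" else "depletion",
             B = B, seed = seed)
}

#' Write enrichment results as TSV
#' @param x a [bootstrap_state_enrichment()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
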