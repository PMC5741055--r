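# Replicate-level Poisson peak calling on Tn5 insertion events, input
# masking, majority-vote consensus and the cross-stage catalog.

#' Per-base Tn5 insertion-event coverage
#'
#' Every fragment contributes one event at its start and one at `end - 1`,
#' so total events are exactly twice the fragment count.
#'
#' @param frags fragment data frame.
#' @param genome [genome_model()].
#' @return an object of class `coverage_events`: named list of integer
#'   vectors (one per chromosome, per-base event counts).
#' @export
cutsite_coverage <- function(frags, genome) {
  validate_intervals(frags, genome)
  ev <- cutsites(frags)
  out <- lapply(setNames(genome$chrom_names, genome$chrom_names),
                function(ch) {
    pos <- ev$pos[ev$chrom == ch]
    tabulate(pos + 1, nbins = genome$chrom_lengths[[ch]])
  })
  structure(out, class = "coverage_events", total = 2L * nrow(frags))
}

#' Peak-calling configuration
#'
#' @param window scan window width w in bp.
#' @param step scan step in bp.
#' @param local_windows local background window sizes (bp) whose rates,
#'   together with the genome-wide rate, give the Poisson lambda (the
#'   maximum is used).
#' @param q_threshold BH-adjusted significance threshold per window.
#' @param min_events minimal events in a significant window.
#' @param merge_gap gap (bp) within which significant windows are merged.
#' @param min_total_events minimal genome-wide events required to call.
#' @return an object of class `peak_call_config`.
#' @export
peak_call_config <- function(window = 150, step = 20,
                             local_windows = c(1000, 5000, 10000),
                             q_threshold = 0.01, min_events = 8,
                             merge_gap = 100, min_total_events = 10000) {
  stopifnot(window >= 10, step >= 1, q_threshold > 0, q_threshold < 1,
            min_events >= 0, merge_gap >= 0,
            all(diff(local_windows) > 0), all(local_windows > window))
  structure(as.list(environment()), class = "peak_call_config")
}

#' Call peaks on one replicate
#'
#' Slides a window of `config$window` bp at `config$step` bp steps; each
#' window's event count is tested against a Poisson upper tail with lambda
#' equal to the maximum of the genome-wide rate and local rates (window
#' excluded) times the window width.  P-values are BH-adjusted across all
#' windows genome-wide; significant windows are merged within
#' `config$merge_gap` bp.  Peak summits are the maxima of 51-bp-smoothed
#' event counts.
#'
#' @param events a [cutsite_coverage()] result.
#' @param config a [peak_call_config()].
#' @param stage,replicate labels attached to the output.
#' @return peak data frame: `chrom`, `start`, `end`, `name`, `score`
#'   (`-10 log10 q`), `strand`, `summit` (absolute bp), `q`, `n_events`,
#'   `summit_events`, `stage`, `replicate`.
#' @export
call_peaks_replicate <- function(events, config = peak_call_config(),
                                 stage = NA_character_,
                                 replicate = NA_character_) {
  total <- sum(vapply(events, sum, numeric(1)))
  if (total < config$min_total_events && total > 0)
    stop("only ", total, " insertion events genome-wide; at least ",
         config$min_total_events, " are required - increase sequencing depth")
  genome_len <- sum(lengths(events))
  rate <- total / genome_len
  w <- config$window
  win <- list()
  for (ch in names(events)) {
    v <- events[[ch]]
    n <- length(v)
    if (n < w) next
    cs <- c(0, cumsum(v))   # cs[i+1] = sum of first i bases
    starts <- seq(0, n - w, by = config$step)
    cnt <- cs[starts + w + 1] - cs[starts + 1]
    lam <- rate * w
    for (lw in config$local_windows) {
      half <- (lw - w) / 2
      lo <- pmax(starts - half, 0)
      hi <- pmin(starts + w + half, n)
      loc <- (cs[hi + 1] - cs[lo + 1]) - cnt        # local count, window excl.
      lam <- pmax(lam, loc / pmax(hi - lo - w, 1) * w)
    }
    win[[ch]] <- data.frame(chrom = ch, start = starts, count = cnt,
                            lambda = lam)
  }
  win <- do.call(rbind, win)
  if (is.null(win) || nrow(win) == 0 || total == 0) return(empty_peaks())
  p <- ppois(win$count - 1, win$lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  keep <- q < config$q_threshold & win$count >= config$min_events
  if (!any(keep)) return(empty_peaks())
  sig <- win[keep, ]
  sig$q <- q[keep]
  merged <- merge_intervals(data.frame(chrom = sig$chrom, start = sig$start,
                                       end = sig$start + w),
                            gap = config$merge_gap)
  hit <- interval_overlap(merged,
                          data.frame(chrom = sig$chrom, start = sig$start,
                                     end = sig$start + w))
  qmin <- tapply(sig$q[hit$subject], hit$query, min)
  merged$q <- as.numeric(qmin[as.character(seq_len(nrow(merged)))])
  merged$summit <- NA_real_
  merged$summit_events <- NA_real_
  merged$n_events <- NA_real_
  cs_chrom <- lapply(events, function(v) c(0, cumsum(v)))
  for (i in seq_len(nrow(merged))) {
    ch <- merged$chrom[i]
    cs <- cs_chrom[[ch]]
    n <- length(events[[ch]])
    seg <- (merged$start[i] + 1):merged$end[i]   # 1-based positions
    lo <- pmax(seg - 26, 0)                      # exclusive lower bound
    hi <- pmin(seg + 25, n)
    smooth <- (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
    best <- which.max(smooth)
    merged$summit[i] <- seg[best] - 1
    merged$summit_events[i] <- smooth[best]
    merged$n_events[i] <- cs[merged$end[i] + 1] - cs[merged$start[i] + 1]
  }
  merged$name <- sprintf("peak_%05d", seq_len(nrow(merged)))
  merged$score <- round(-10 * log10(pmax(merged$q, 1e-300)), 2)
  merged$strand <- "."
  merged$stage <- stage
  merged$replicate <- replicate
  merged[, peak_cols()]
}

peak_cols <- function() c("chrom", "start", "end", "name", "score", "strand",
                          "summit", "q", "n_events", "summit_events",
                          "stage", "replicate")

empty_peaks <- function() {
  out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                    name = character(), score = numeric(),
                    strand = character(), summit = numeric(), q = numeric(),
                    n_events = numeric(), summit_events = numeric(),
                    stage = character(), replicate = character())
  out
}

#' Significant windows in an input control
#'
#' Poisson scan of the input events against the input's genome-wide rate
#' only (no local background), BH-adjusted; returns merged significant
#' regions.  Used by [mask_by_input()].
#'
#' @param input_events [cutsite_coverage()] of the input control.
#' @param config a [peak_call_config()]; `q_threshold` applies.
#' @return merged interval data frame of artifactual regions.
#' @export
input_significant_regions <- function(input_events,
                                      config = peak_call_config()) {
  total <- sum(vapply(input_events, sum, numeric(1)))
  if (total == 0) return(data.frame(chrom = character(), start = numeric(),
                                    end = numeric()))
  genome_len <- sum(lengths(input_events))
  w <- config$window
  rows <- list()
  for (ch in names(input_events)) {
    v <- input_events[[ch]]
    n <- length(v)
    if (n < w) next
    cs <- c(0, cumsum(v))
    starts <- seq(0, n - w, by = config$step)
    cnt <- cs[starts + w + 1] - cs[starts + 1]
    rows[[ch]] <- data.frame(chrom = ch, start = starts, count = cnt)
  }
  win <- do.call(rbind, rows)
  lam <- total / genome_len * w
  q <- p.adjust(ppois(win$count - 1, lam, lower.tail = FALSE), "BH")
  keep <- q < config$q_threshold
  if (!any(keep)) return(data.frame(chrom = character(), start = numeric(),
                                    end = numeric()))
  merge_intervals(data.frame(chrom = win$chrom[keep],
                             start = win$start[keep],
                             end = win$start[keep] + w),
                  gap = config$merge_gap)
}

#' Mask peaks by input-control signal
#'
#' Removes peaks overlapping regions with significant signal in the input
#' control (Poisson vs the input genome-wide rate, BH q < threshold).
#' Removed peaks are attached as the `"removed"` attribute.
#'
#' @param peaks peak data frame.
#' @param input_events [cutsite_coverage()] of the input, or `NULL` (a
#'   prominent warning is emitted and peaks pass unmasked).
#' @param config a [peak_call_config()].
#' @param sample_total optional sample event total; a warning is emitted if
#'   the input has fewer than 10% as many events.
#' @return filtered peak data frame with attribute `removed`.
#' @export
mask_by_input <- function(peaks, input_events, config = peak_call_config(),
                          sample_total = NULL) {
  if (is.null(input_events)) {
    warning("NO INPUT CONTROL: peaks are not masked for accessibility-",
            "independent artifacts")
    attr(peaks, "removed") <- empty_peaks()
    return(peaks)
  }
  in_total <- sum(vapply(input_events, sum, numeric(1)))
  if (!is.null(sample_total) && in_total < 0.1 * sample_total)
    warning("input depth is below 10% of sample depth; masking may be ",
            "underpowered")
  bad <- input_significant_regions(input_events, config)
  if (nrow(bad) == 0 || nrow(peaks) == 0) {
    attr(peaks, "removed") <- empty_peaks()
    return(peaks)
  }
  hit <- interval_overlap(peaks, bad)
  drop <- unique(hit$query)
  out <- peaks[setdiff(seq_len(nrow(peaks)), drop), , drop = FALSE]
  attr(out, "removed") <- peaks[drop, , drop = FALSE]
  out
}

#' Majority-vote consensus peaks across replicates
#'
#' Merges all replicate peaks and keeps regions supported by peaks from more
#' than half of the replicates.  Each kept region becomes the union of its
#' supporting peaks; its summit is the supporting summit with the highest
#' smoothed event count.
#'
#' @param peak_sets list of per-replicate peak data frames (>= 2).
#' @param stage stage label for the output.
#' @return consensus peak data frame with `replicate_support` (comma-joined
#'   replicate ids) and `n_support`.
#' @export
replicate_consensus <- function(peak_sets, stage = NA_character_) {
  if (length(peak_sets) < 2)
    stop("replicate consensus needs at least 2 replicates")
  reps <- vapply(seq_along(peak_sets), function(i)
    peak_sets[[i]]$replicate[1] %||% NA_character_, "")
  reps[is.na(reps)] <- paste0("rep", which(is.na(reps)))
  need <- floor(length(peak_sets) / 2) + 1
  all_pk <- do.call(rbind, lapply(seq_along(peak_sets), function(i) {
    x <- peak_sets[[i]]
    if (nrow(x)) x$rep_idx <- i else x$rep_idx <- integer(0)
    x
  }))
  if (is.null(all_pk) || nrow(all_pk) == 0) return(empty_peaks())
  merged <- merge_intervals(all_pk, gap = 0)
  hit <- interval_overlap(merged, all_pk)
  out <- list()
  for (i in seq_len(nrow(merged))) {
    sub <- all_pk[hit$subject[hit$query == i], , drop = FALSE]
    support <- unique(sub$rep_idx)
    if (length(support) < need) next
    region <- merge_intervals(sub, gap = 0)   # union of supporting peaks
    for (r in seq_len(nrow(region))) {
      inside <- sub$summit >= region$start[r] & sub$summit < region$end[r]
      sup <- sub[inside, , drop = FALSE]
      if (nrow(sup) == 0) next
      best <- which.max(sup$summit_events)
      out[[length(out) + 1]] <- data.frame(
        chrom = region$chrom[r], start = region$start[r],
        end = region$end[r], summit = sup$summit[best],
        q = min(sup$q), summit_events = sup$summit_events[best],
        n_events = sum(sup$n_events),
        n_support = length(support),
        replicate_support = paste(sort(reps[support]), collapse = ","),
        stage = stage)
    }
  }
  if (!length(out)) return(empty_peaks())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), ]
  res$name <- sprintf("%s_consensus_%05d",
                      ifelse(is.na(stage), "stage", stage),
                      seq_len(nrow(res)))
  res$score <- round(-10 * log10(pmax(res$q, 1e-300)), 2)
  res$strand <- "."
  rownames(res) <- NULL
  res
}

#' Cross-stage peak catalog
#'
#' The union of per-stage consensus peaks merged at gap 0, with per-stage
#' presence flags.  Catalog peaks are non-overlapping.
#'
#' @param stage_sets named list of per-stage consensus peak data frames.
#' @return catalog data frame with logical `in_<stage>` columns and a
#'   `summit` (from the overlapping stage peak with the most summit events).
#' @export
build_catalog <- function(stage_sets) {
  if (!length(stage_sets)) stop("need at least one stage")
  stages <- names(stage_sets) %||% paste0("stage", seq_along(stage_sets))
  all_pk <- do.call(rbind, lapply(seq_along(stage_sets), function(i) {
    x <- stage_sets[[i]][, c("chrom", "start", "end", "summit",
                             "summit_events")]
    if (nrow(x)) x$stage_idx <- i else x$stage_idx <- integer(0)
    x
  }))
  if (is.null(all_pk) || nrow(all_pk) == 0)
    stop("all stage peak sets are empty")
  cat <- merge_intervals(all_pk, gap = 0)
  hit <- interval_overlap(cat, all_pk)
  for (s in stages) cat[[paste0("in_", s)]] <- FALSE
  cat$summit <- NA_real_
  for (i in seq_len(nrow(cat))) {
    sub <- all_pk[hit$subject[hit$query == i], , drop = FALSE]
    for (j in unique(sub$stage_idx))
      cat[[paste0("in_", stages[j])]][i] <- TRUE
    best <- which.max(sub$summit_events)
    cat$summit[i] <- min(max(sub$summit[best], cat$start[i]),
                         cat$end[i] - 1)
  }
  cat$name <- sprintf("catalog_%05d", seq_len(nrow(cat)))
  cat
}

#' Write peaks in narrowPeak-compatible BED6+ format
#'
#' Columns: chrom, start, end, name, score (`-10 log10 q`), strand, extra:
#' summit offset from start, replicate support, stage.
#'
#' @param peaks peak data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  x <- peaks
  x$summit_offset <- x$summit - x$start
  x$support <- x$replicate_support %||% x$replicate %||% "."
  x$stage_lab <- x$stage %||% "."
  write_bed(x, path, extra = c("summit_offset", "support", "stage_lab"))
}
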