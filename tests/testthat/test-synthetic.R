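test_that("simulation is deterministic given the seed", {
  w1 <- tiny_world(1)
  w2 <- simulate_world(tiny_config(1))
  expect_identical(w1$peaks, w2$peaks)
  expect_identical(w1$genome$sequence, w2$genome$sequence)
  expect_identical(w1$states, w2$states)
  f1 <- simulate_atac_fragments(w1, "EE", "rep1", seed = 5)
  f2 <- simulate_atac_fragments(w2, "EE", "rep1", seed = 5)
  expect_identical(f1, f2)
  s1 <- simulate_chip_summits(w1, "canonical_TF", 50, seed = 3)
  s2 <- simulate_chip_summits(w2, "canonical_TF", 50, seed = 3)
  expect_identical(s1, s2)
})

test_that("world truth is internally consistent", {
  w <- tiny_world(1)
  pk <- w$peaks
  # dynamics classes consistent with levels under the fold threshold
  up <- pk$class_EE_L3 == "increase"
  expect_true(all(pk$level_L3[up] > 2 * pk$level_EE[up]))
  dn <- pk$class_EE_L3 == "decrease"
  expect_true(all(pk$level_EE[dn] > 2 * pk$level_L3[dn]))
  # promoter-flagged peaks are promoter-proximal; distal are >= 1 kb away
  cls <- classify_region(pk, w$annotation)
  expect_true(all(cls$class[pk$promoter] == "promoter_proximal"))
  expect_true(all(abs(cls$distance[!pk$promoter]) >= 1000))
  # accessible peaks sit in active states, by construction
  st <- state_at(w$states$L3, pk$chrom, pk$summit)
  acc <- pk$level_L3 >= 0.5
  expect_true(all(st[acc] %in% c("promoter", "active_enhancer")))
})

test_that("planting probability and dynamic fraction edge cases hold", {
  pl <- default_planting_map()
  pl$prob[pl$motif == "GAGA_dimer" & pl$class == "increase"] <- 1
  w <- simulate_world(tiny_config(2, planting = pl))
  inc <- w$peaks$name[w$peaks$class_EE_L3 == "increase"]
  planted <- unique(w$motif_occurrences$peak[
    w$motif_occurrences$motif == "GAGA_dimer"])
  expect_true(all(inc %in% planted))
  # planted consensus sites are recovered by the scanner
  some <- w$peaks[w$peaks$name %in% inc[1:10], ]
  counts <- motif_count_matrix(some, w$genome,
                               w$config$motifs["GAGA_dimer"])
  expect_true(all(counts[, 1] >= 1))

  w0 <- simulate_world(tiny_config(3, frac_dynamic = c(EE_L3 = 0,
                                                       L3_YA = 0)))
  expect_true(all(w0$peaks$class_EE_L3 == "no-change"))
  expect_true(all(w0$peaks$class_L3_YA == "no-change"))
})

test_that("fragments concentrate in peaks by level; level 0 gives
           uniform midpoints", {
  w <- tiny_world(1)
  fr <- tiny_frags("L3", "rep1")
  cnt <- peak_counts(w$peaks, list(s = fr))[, 1]
  lv <- w$peaks$level_L3
  expect_gt(cor(cnt, lv, method = "spearman"), 0.8)
  # same-stage replicates correlate better than different stages
  fr2 <- tiny_frags("L3", "rep2")
  fr_ee <- tiny_frags("EE", "rep1")
  cnt2 <- peak_counts(w$peaks, list(s = fr2))[, 1]
  cnt_ee <- peak_counts(w$peaks, list(s = fr_ee))[, 1]
  expect_gt(cor(cnt, cnt2, method = "spearman"),
            cor(cnt, cnt_ee, method = "spearman"))
  # flat world: midpoints uniform (KS test against uniform)
  w0 <- simulate_world(tiny_config(4, frac_dynamic = c(EE_L3 = 0,
                                                       L3_YA = 0)))
  w0$peaks$level_EE <- 0
  fr0 <- simulate_atac_fragments(w0, "EE", "rep1", depth = 10000, seed = 9)
  mids <- ((fr0$start + fr0$end) / 2)[fr0$chrom == "chrI"]
  ks <- suppressWarnings(
    stats::ks.test(mids / w0$genome$chrom_lengths[["chrI"]], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("input control is uniform except at hotspots", {
  w <- tiny_world(1)
  inp <- simulate_input_fragments(w, seed = 21)
  expect_true(all(inp$sample_id == "input"))
  hot <- w$hotspots
  mids <- data.frame(chrom = inp$chrom, start = (inp$start + inp$end) %/% 2)
  mids$end <- mids$start + 1
  in_hot <- length(unique(interval_overlap(mids, hot)$query))
  hot_bp <- sum(hot$end - hot$start)
  genome_bp <- sum(w$genome$chrom_lengths)
  fold <- (in_hot / nrow(inp)) / (hot_bp / genome_bp)
  expect_gt(fold, 10)   # strongly elevated over uniform expectation
  # no hotspots -> uniform coverage
  w0 <- simulate_world(tiny_config(5, n_hotspots = 0))
  inp0 <- simulate_input_fragments(w0, depth = 10000, seed = 3)
  m <- ((inp0$start + inp0$end) / 2)[inp0$chrom == "chrI"]
  ks <- suppressWarnings(
    stats::ks.test(m / w0$genome$chrom_lengths[["chrI"]], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ChIP summit placement follows the factor class rules", {
  w <- tiny_world(1)
  acc <- w$peaks[w$peaks$level_L3 >= 0.5, ]
  can <- simulate_chip_summits(w, "canonical_TF", 100, seed = 1)
  frac_in <- length(unique(interval_overlap(can, acc)$query)) / nrow(can)
  expect_gte(frac_in, 0.9)
  het <- simulate_chip_summits(w, "heterochromatin", 100, seed = 1)
  expect_equal(nrow(interval_overlap(het, acc)), 0)
  nuc <- simulate_chip_summits(w, "nucleosome_proximal", 100, seed = 1)
  expect_equal(nrow(interval_overlap(nuc, w$peaks)), 0)
  expect_error(simulate_chip_summits(w, "canonical_TF", 0), "n > 0")
})

test_that("H3 tracks are positive, near baseline, and anti-correlated with
           accessibility", {
  w <- tiny_world(1)
  tr <- simulate_h3_tracks(w, "L3", seed = 2)
  v <- unlist(tr$values)
  expect_true(all(v > 0))
  expect_lt(abs(mean(v) - 1), 0.05)
  pk <- w$peaks
  h3_at_peaks <- track_mean(tr, pk$chrom, pk$start, pk$end)
  expect_lt(cor(h3_at_peaks, pk$level_L3), -0.5)
  hi <- h3_at_peaks[pk$level_L3 >= 0.9]
  lo <- h3_at_peaks[pk$level_L3 <= 0.1]
  expect_lt(mean(hi), mean(lo))
})

test_that("write_world emits a readable copy of the world", {
  w <- tiny_world(1)
  dir <- tempfile("world_")
  paths <- write_world(w, dir)
  expect_true(all(file.exists(paths)))
  g <- read_genome_fasta(paths["genome"])
  expect_equal(g$sequence, w$genome$sequence)
  seg <- read_state_bed(paths[["states_L3"]], "L3", g)
  expect_equal(seg$segments, w$states$L3$segments, ignore_attr = TRUE)
  ann <- read_gff3_lite(paths["annotation"])
  expect_equal(nrow(ann$tss), nrow(w$annotation$tss))
})
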