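empty_peaks_for_test <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), summit = numeric())
}

test_that("cutsite_coverage places two events per fragment", {
  g <- toy_genome()
  fr <- fragments("chrI", 100, 200, "x", "y")
  ev <- cutsite_coverage(fr, g)
  expect_equal(which(ev$chrI > 0), c(101, 200))   # 0-based 100 and 199
  fr2 <- fragments(rep("chrI", 3), c(100, 100, 150), c(200, 200, 250),
                   "x", "y")
  ev2 <- cutsite_coverage(fr2, g)
  expect_equal(sum(unlist(ev2)), 6)
  expect_equal(ev2$chrI[101], 2L)                 # additive overlap
})

test_that("Poisson window tail matches a direct series computation", {
  # p-value of >= 50 events at lambda = 1, by summing the Poisson pmf
  # series directly (independent of ppois)
  lam <- 1
  series_tail <- function(k, lam) {
    terms <- exp(-lam) * lam^(0:200) / factorial(0:200)
    sum(terms[(k + 1):201])
  }
  expect_equal(ppois(49, lam, lower.tail = FALSE), series_tail(50, lam),
               tolerance = 1e-12)
  expect_lt(ppois(49, lam, lower.tail = FALSE), 1e-50)
})

test_that("an isolated dense window is called; empty genomes yield no
           peaks", {
  g <- genome_model(c(chrI = 100000))
  set.seed(11)
  # uniform background + one dense 150 bp site
  bg <- fragments("chrI", st <- sample(99000, 6000),
                  st + sample(50:200, 6000, replace = TRUE), "x", "y")
  ctr <- round(rnorm(400, 50000, 30))
  sig <- fragments("chrI", ctr - 40, ctr + 40, "x", "y")
  ev <- cutsite_coverage(rbind(bg, sig), g)
  pk <- call_peaks_replicate(ev, peak_call_config())
  expect_gte(nrow(pk), 1)
  expect_true(any(pk$start <= 50000 & pk$end >= 50000))
  expect_true(all(pk$summit >= pk$start & pk$summit < pk$end))
  # summit near the planted centre
  best <- pk[which.min(abs(pk$summit - 50000)), ]
  expect_lt(abs(best$summit - 50000), 100)

  empty <- cutsite_coverage(bg[0, ], g)
  cfg0 <- peak_call_config(min_total_events = 0)
  expect_equal(nrow(call_peaks_replicate(empty, cfg0)), 0)
  expect_error(call_peaks_replicate(cutsite_coverage(bg[1:10, ], g)),
               "depth")
})

test_that("uniform events yield (almost) no calls: FDR control", {
  g <- genome_model(c(chrI = 200000))
  called <- 0; windows <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    fr <- fragments("chrI", st <- sample(199000, 10000),
                    st + sample(50:200, 10000, replace = TRUE), "x", "y")
    pk <- call_peaks_replicate(cutsite_coverage(fr, g))
    called <- called + nrow(pk)
    windows <- windows + floor(200000 / 20)
  }
  expect_lte(called / windows, 0.01)
})

test_that("input masking removes peaks in hotspots and nothing else", {
  w <- tiny_world(1)
  fr <- tiny_frags("L3", "rep1")
  ev <- cutsite_coverage(fr, w$genome)
  pk <- call_peaks_replicate(ev, stage = "L3", replicate = "rep1")
  inp <- simulate_input_fragments(w, seed = 77)
  inp_ev <- cutsite_coverage(inp, w$genome)
  masked <- mask_by_input(pk, inp_ev, sample_total = attr(ev, "total"))
  removed <- attr(masked, "removed")
  # every removed peak overlaps a hotspot; no kept peak does
  if (nrow(removed))
    expect_equal(length(unique(interval_overlap(removed,
                                                w$hotspots)$query)),
                 nrow(removed))
  expect_equal(nrow(interval_overlap(masked, w$hotspots)), 0)
  # uniform input removes nothing
  w0 <- simulate_world(tiny_config(5, n_hotspots = 0))
  inp0 <- simulate_input_fragments(w0, seed = 7)
  m0 <- mask_by_input(pk, cutsite_coverage(inp0, w$genome))
  expect_equal(nrow(m0), nrow(pk))
  # empty peak set passes through; missing input warns loudly
  e <- mask_by_input(empty_peaks_for_test(), inp_ev)
  expect_equal(nrow(e), 0)
  expect_warning(mask_by_input(pk, NULL), "NO INPUT")
})

test_that("replicate consensus applies the majority rule", {
  mk <- function(start, end, rep, summit_events = 10) {
    data.frame(chrom = "chrI", start = start, end = end,
               name = "p", score = 1, strand = ".",
               summit = (start + end) %/% 2, q = 1e-6,
               n_events = 20, summit_events = summit_events,
               stage = "L3", replicate = rep)
  }
  r1 <- rbind(mk(100, 300, "rep1"), mk(1000, 1200, "rep1"))
  r2 <- rbind(mk(150, 350, "rep2", 15), mk(5000, 5200, "rep2"))
  r3 <- mk(2000, 2100, "rep3")
  cons <- replicate_consensus(list(r1, r2, r3), "L3")
  # only the 100-350 region is supported by 2 of 3
  expect_equal(nrow(cons), 1)
  expect_equal(c(cons$start, cons$end), c(100, 350))
  expect_equal(cons$n_support, 2)
  expect_equal(cons$summit, 250)   # rep2's summit has more events
  expect_equal(cons$replicate_support, "rep1,rep2")
  # present in all three -> kept
  all3 <- replicate_consensus(list(mk(10, 50, "rep1"), mk(10, 50, "rep2"),
                                   mk(12, 60, "rep3")), "L3")
  expect_equal(nrow(all3), 1)
  expect_error(replicate_consensus(list(r1)), "at least 2")
})

test_that("catalog is the non-overlapping cross-stage union with flags", {
  mk <- function(start, end, stage) {
    data.frame(chrom = "chrI", start = start, end = end, name = "x",
               summit = (start + end) %/% 2, summit_events = 5,
               stage = stage)
  }
  same <- build_catalog(list(EE = mk(0, 100, "EE"), L3 = mk(0, 100, "L3")))
  expect_equal(nrow(same), 1)
  expect_true(same$in_EE & same$in_L3)
  disj <- build_catalog(list(EE = mk(0, 100, "EE"),
                             L3 = mk(500, 600, "L3")))
  expect_equal(nrow(disj), 2)
  part <- build_catalog(list(EE = mk(0, 100, "EE"), L3 = mk(80, 200, "L3"),
                             YA = mk(400, 500, "YA")))
  expect_equal(nrow(part), 2)
  expect_equal(part$end[1], 200)
  expect_true(part$in_EE[1] && part$in_L3[1] && !part$in_YA[1])
  # catalog peaks never overlap
  ov <- interval_overlap(part, part)
  expect_true(all(ov$query == ov$subject))
})

test_that("peak calling is translation invariant", {
  g <- genome_model(c(chrI = 60000))
  set.seed(12)
  st <- sample(20000, 4000)
  sctr <- round(rnorm(300, 10000, 30))
  mk <- function(shift) {
    fr <- fragments("chrI", st + shift,
                    st + shift + rep(c(60, 200), 2000), "x", "y")
    sig <- fragments("chrI", sctr + shift - 40, sctr + shift + 40, "x", "y")
    call_peaks_replicate(cutsite_coverage(rbind(fr, sig), g),
                         peak_call_config(min_total_events = 5000))
  }
  a <- mk(0); b <- mk(20000)   # shift by a multiple of the scan step
  expect_equal(b$start - 20000, a$start)
  expect_equal(b$summit - 20000, a$summit)
})
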