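toy_annotation <- function() {
  gene_annotation(
    tss = intervals("chrI", 10000, 10001, strand = "+", name = "g1"),
    exons = intervals("chrI", c(10000, 10600), c(10400, 10900),
                      strand = "+", name = c("g1", "g1")))
}

pk_at <- function(summit, name = "p") {
  data.frame(chrom = "chrI", start = summit - 100, end = summit + 100,
             summit = summit, name = name)
}

test_that("classify_region applies the distal rule at the summit", {
  ann <- toy_annotation()
  expect_equal(classify_region(pk_at(8500), ann)$class, "distal_noncoding")
  # 400 bp downstream but inside an exon: exonic overrides
  expect_equal(classify_region(pk_at(10400 - 100), ann)$class, "exonic")
  # exactly 1,000 bp upstream: distal ("at least 1 kb" is inclusive)
  expect_equal(classify_region(pk_at(9000), ann)$class, "distal_noncoding")
  expect_equal(classify_region(pk_at(9001), ann)$class,
               "promoter_proximal")
  # exactly 500 bp downstream, outside exons: distal
  expect_equal(classify_region(pk_at(10500), ann)$class,
               "distal_noncoding")
  expect_equal(classify_region(pk_at(10450), ann)$class,
               "promoter_proximal")
})

test_that("classify_region is strand-covariant under genome reflection", {
  w <- tiny_world(1)
  cls <- classify_region(w$peaks, w$annotation)
  L <- w$genome$chrom_lengths
  flip_iv <- function(x) {
    out <- x
    out$start <- L[x$chrom] - x$end
    out$end <- L[x$chrom] - x$start
    if ("strand" %in% names(x))
      out$strand <- c(`+` = "-", `-` = "+", `.` = ".")[x$strand]
    out
  }
  ann_f <- gene_annotation(flip_iv(w$annotation$tss),
                           flip_iv(w$annotation$exons))
  pk_f <- flip_iv(w$peaks)
  pk_f$summit <- L[w$peaks$chrom] - 1 - w$peaks$summit
  cls_f <- classify_region(pk_f, ann_f)
  expect_equal(cls_f$class, cls$class)
})

test_that("enhancer candidates rank by |log2FC| with q and position
           tie-breaks", {
  classes <- data.frame(peak = c("p1", "p2", "p3", "p4"),
                        class = c(rep("distal_noncoding", 3),
                                  "promoter_proximal"))
  res <- data.frame(peak = c("p1", "p2", "p3", "p4"),
                    log2FC = c(-3, 1, 3, 9), q = c(0.2, 0.01, 0.1, 1e-9))
  top <- rank_enhancer_candidates(list(tr = res), classes, k = 2)
  # p4 is promoter-proximal and excluded despite the largest |FC|
  expect_equal(top$peak, c("p3", "p1"))   # tie on |FC|=3 -> smaller q first
  expect_warning(all3 <- rank_enhancer_candidates(list(tr = res), classes,
                                                  k = 10),
                 "only 3")
  expect_equal(nrow(all3), 3)
})

test_that("fisher_one_sided equals the enumeration oracle and base R", {
  # oracle: hypergeometric upper tail from binomial coefficients
  oracle <- function(a, b, c_, d) {
    k <- a + c_; m <- a + b; n <- c_ + d
    if (k == 0 || m + n == 0) return(1)
    x <- max(0, k - n):min(m, k)
    pr <- choose(m, x) * choose(n, k - x) / choose(m + n, k)
    sum(pr[x >= a])
  }
  expect_equal(signif(fisher_one_sided(rbind(c(5, 8), c(0, 10))), 2), 0.038)
  expect_equal(fisher_one_sided(rbind(c(0, 0), c(0, 0))), 1)
  expect_equal(fisher_one_sided(rbind(c(2, 1), c(1, 2))), 0.5)
  set.seed(13)
  for (i in 1:25) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
    expect_equal(fisher_one_sided(tab),
                 oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    if (sum(tab) > 0)
      expect_equal(fisher_one_sided(tab),
                   fisher.test(tab, alternative = "greater")$p.value,
                   tolerance = 1e-9)
  }
  expect_error(fisher_one_sided(rbind(c(-1, 2), c(3, 4))), "negative")
})

test_that("bh_adjust performs the step-up with monotonicity", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # hand step-up on a fixed vector
  p <- c(0.005, 0.009, 0.05, 0.2, 0.9)
  hand <- rev(cummin(rev(p * 5 / seq_len(5))))
  expect_equal(bh_adjust(p), pmin(hand, 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("bootstrap enrichment: planted composition gives the expected
           fold and the p floor", {
  g <- genome_model(c(chrI = 100000))
  seg <- state_segmentation(
    data.frame(chrom = "chrI", start = c(0, 10000),
               end = c(10000, 100000),
               state = c("S", "bg")), "L3", g)
  pk <- data.frame(chrom = "chrI", start = seq(500, 9000, length.out = 100),
                   name = paste0("p", 1:100))
  pk$start <- round(pk$start); pk$end <- pk$start + 50
  pk$summit <- pk$start + 25
  enr <- bootstrap_state_enrichment(pk, seg, g, B = 2000, seed = 1)
  s <- enr[enr$state == "S", ]
  expect_equal(s$observed, 100)
  expect_equal(s$fold, 10, tolerance = 0.15)   # state covers 10% of genome
  expect_true(s$p_is_floor)
  expect_equal(s$p, 1 / 2000)
  bg <- enr[enr$state == "bg", ]
  expect_equal(bg$direction, "depletion")
  expect_error(bootstrap_state_enrichment(pk[0, ], seg, g), "empty")
})

test_that("empirical p is super-uniform for null peak sets", {
  set.seed(21)
  g <- genome_model(c(chrI = 50000))
  seg <- state_segmentation(
    data.frame(chrom = "chrI", start = c(0, 15000), end = c(15000, 50000),
               state = c("S", "bg")), "L3", g)
  hits <- 0
  for (i in 1:100) {
    st <- sample(49000, 30)
    pk <- data.frame(chrom = "chrI", start = st, end = st + 40,
                     summit = st + 20)
    enr <- bootstrap_state_enrichment(pk, seg, g, B = 200, seed = 1000 + i)
    hits <- hits + (enr$p[enr$state == "S"] <= 0.05)
  }
  expect_lte(hits, 8)
})

test_that("transition enrichment finds the planted state movement", {
  w <- tiny_world(1)
  pk <- w$peaks
  dyn <- pk[pk$class_EE_L3 == "increase", ]
  tr <- transition_enrichment(dyn, pk, w$states$EE, w$states$L3)
  top <- tr[1, ]
  expect_equal(paste(top$from, top$to, sep = "->"),
               "heterochromatin->active_enhancer")
  expect_lt(top$q, 0.05)
  # dynamic set == background: all ORs 1, p 1
  same <- transition_enrichment(pk, pk, w$states$EE, w$states$L3)
  expect_true(all(same$p == 1))
  expect_error(transition_enrichment(pk[0, ], pk, w$states$EE,
                                     w$states$L3), "empty")
  alien <- pk[1:3, ]; alien$name <- paste0("zz", 1:3)
  expect_error(transition_enrichment(alien, pk, w$states$EE, w$states$L3),
               "subset")
})

test_that("score enrichment: constant tracks give fold exactly 1; planted
           islands are enriched", {
  g <- genome_model(c(chrI = 50000))
  tr <- score_track(list(chrI = rep(2, 5000)), 10, g)
  pk <- data.frame(chrom = "chrI", start = c(100, 30000),
                   end = c(300, 30200))
  res <- score_enrichment(pk, tr, g, B = 100, seed = 1)
  expect_equal(res$fold, 1)
  expect_gte(res$p, 1 / 101)
  v <- rep(1, 5000); v[1001:1100] <- 10   # island at 10000-11000 bp
  tr2 <- score_track(list(chrI = v), 10, g)
  pk2 <- data.frame(chrom = "chrI", start = seq(10000, 10800, by = 200))
  pk2$end <- pk2$start + 100
  res2 <- score_enrichment(pk2, tr2, g, B = 500, seed = 2)
  expect_gt(res2$fold, 2)
  expect_true(res2$p_is_floor)
  expect_equal(res2$p, 1 / 500)
})

test_that("null-drawn peak sets cover fold = 1 in their bootstrap CI", {
  set.seed(33)
  g <- genome_model(c(chrI = 60000))
  seg <- state_segmentation(
    data.frame(chrom = "chrI", start = c(0, 20000), end = c(20000, 60000),
               state = c("S", "bg")), "L3", g)
  covered <- 0
  for (i in 1:40) {
    st <- sample(59900, 60)
    pk <- data.frame(chrom = "chrI", start = st, end = st + 60,
                     summit = st + 30)
    enr <- bootstrap_state_enrichment(pk, seg, g, B = 400, seed = 500 + i)
    s <- enr[enr$state == "S", ]
    covered <- covered + (s$ci_lo <= 1 && s$ci_hi >= 1)
  }
  expect_gte(covered, 36)   # ~93% nominal coverage
})
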