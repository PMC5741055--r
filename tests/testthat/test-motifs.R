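sharp_pwm <- function(consensus, id = "m", sharp = 0.85, threshold = 0.8) {
  bases <- strsplit(consensus, "")[[1]]
  mat <- vapply(bases, function(b) {
    col <- rep((1 - sharp) / 3, 4)
    col[match(b, c("A", "C", "G", "T"))] <- sharp
    col
  }, numeric(4))
  pwm(id, mat, threshold = threshold)
}

test_that("scan_pwm finds consensus sites on both strands and rejects
           2-mismatch sites (hand log-odds arithmetic)", {
  p <- sharp_pwm("ACGTAC")
  hits <- scan_pwm("TTTACGTACTTT", p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 3)
  expect_equal(hits$strand, "+")
  # hand score: 6 matches at log2(.85/.25) each
  expect_equal(hits$score, 6 * log2(0.85 / 0.25), tolerance = 1e-9)
  # reverse complement of the consensus: minus-strand hit, mirrored offset
  rc <- scan_pwm("TTTGTACGTTTT", p)   # revcomp(ACGTAC) = GTACGT
  expect_equal(rc$strand, "-")
  expect_equal(rc$position, 3)
  # two mismatches: score 4*1.766 - 2*2.322 < 0.8 * max -> no hit
  two_mm <- scan_pwm("TTTACGGGCTTT", p)
  expect_equal(nrow(two_mm), 0)
  hand_score <- 4 * log2(0.85 / 0.25) + 2 * log2(0.05 / 0.25)
  expect_lt(hand_score, 0.8 * 6 * log2(0.85 / 0.25))
  # shorter than the motif: empty
  expect_equal(nrow(scan_pwm("ACG", p)), 0)
  # N scores as background (zero log-odds): 5 matches + N still passes
  withN <- scan_pwm("TTTACGTNCTTT", p)
  expect_equal(withN$score, 5 * log2(0.85 / 0.25), tolerance = 1e-9)
  # ...but a mismatch on top of the N does not
  expect_equal(nrow(scan_pwm("TTTACGGNCTTT", p)), 0)
})

test_that("strand symmetry: reverse-complementing the sequence preserves
           hit counts", {
  set.seed(17)
  p <- sharp_pwm("AGATAAGA")
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
          collapse = ""), "")
  seqs <- paste0(seqs, "AGATAAGA")   # ensure some hits
  rc <- vapply(seqs, function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  n_fwd <- vapply(seqs, function(s)
    length(unique(scan_pwm(s, p)$position)), numeric(1))
  n_rc <- vapply(rc, function(s)
    length(unique(scan_pwm(s, p)$position)), numeric(1))
  expect_equal(unname(n_fwd), unname(n_rc))
})

test_that("motif_count_matrix counts distinct positions; palindromes count
           once", {
  g <- genome_model(c(chrI = 100),
                    sequence = c(chrI = paste0(
                      strrep("T", 20), "TGACGTCA", strrep("T", 20),
                      "AGATAAGA", strrep("T", 44))))
  pk <- data.frame(chrom = "chrI", start = 0, end = 100, name = "p1")
  pal <- sharp_pwm("TGACGTCA", "pal")     # its own reverse complement
  gata <- sharp_pwm("AGATAAGA", "gata")
  counts <- motif_count_matrix(pk, g, list(pal, gata))
  expect_equal(unname(counts["p1", ]), c(1, 1))
  raw_hits <- scan_pwm(g$sequence[["chrI"]], pal)
  expect_equal(nrow(raw_hits), 2)   # + and - at the same window
  expect_equal(length(unique(raw_hits$position)), 1)
  expect_error(motif_count_matrix(pk, genome_model(c(chrI = 100)),
                                  list(pal)), "no sequence")
})

test_that("motif_enrichment flags the planted motif and handles degenerate
           tables", {
  set.seed(19)
  n <- 300
  labels <- rep(c("increase", "decrease", "no-change"), each = 100)
  counts <- cbind(
    planted = rbinom(n, 2, ifelse(labels == "increase", 0.8, 0.05)),
    flat = rbinom(n, 2, 0.3),
    everywhere = rep(1L, n))
  me <- motif_enrichment(counts, labels, "increase", "no-change")
  expect_equal(me$motif[1], "planted")
  expect_lt(me$q[1], 0.01)
  expect_gt(me$q[me$motif == "flat"], 0.2)
  ev <- me[me$motif == "everywhere", ]
  expect_equal(ev$p, 1)
  expect_true(is.finite(ev$odds_ratio))   # Haldane-corrected
  expect_error(motif_enrichment(counts, labels, "increase", "absent"),
               "no peaks")
})

test_that("balanced accuracy is the unweighted mean of per-class recalls", {
  expect_equal(balanced_accuracy(c("a", "b", "c"), c("a", "b", "c")), 1)
  # recalls 1, 0.5, 0 -> 0.5
  pred <- c("a", "a", "b", "b", "c", "b")
  true <- c("a", "a", "b", "c", "c", "b")
  expect_equal(balanced_accuracy(pred, true), mean(c(1, 1, 0.5)))
  truth3 <- rep(c("a", "b", "c"), each = 10)
  expect_equal(balanced_accuracy(rep("a", 30), truth3), 1 / 3)
  expect_error(balanced_accuracy(character(), character()), "non-empty")
})

test_that("boosting separates a single informative feature and is
           deterministic", {
  set.seed(23)
  n <- 300
  labels <- sample(rep(c("increase", "decrease", "no-change"), each = 100))
  x <- cbind(
    signal = ifelse(labels == "increase", 3,
                    ifelse(labels == "decrease", 1, 0)) +
      rbinom(n, 1, 0.05),
    noise1 = rpois(n, 1), noise2 = rpois(n, 1))
  m1 <- fit_boost(x, labels, seed = 3)
  expect_gte(m1$balanced_accuracy, 0.95)
  ri <- relative_influence(m1)
  expect_equal(ri$motif[1], "signal")
  expect_gte(ri$influence[1], 50)
  expect_equal(sum(ri$influence), 100, tolerance = 1e-6)
  m2 <- fit_boost(x, labels, seed = 3)
  expect_identical(predict_boost(m1, x), predict_boost(m2, x))
  expect_equal(m1$balanced_accuracy, m2$balanced_accuracy)
})

test_that("label-permuted data scores at chance level", {
  set.seed(29)
  n <- 300
  labels <- sample(rep(c("increase", "decrease", "no-change"), each = 100))
  x <- matrix(rpois(n * 4, 1), n,
              dimnames = list(NULL, paste0("m", 1:4)))
  m <- fit_boost(x, labels, seed = 5, n_trees = 100)
  expect_lt(abs(m$balanced_accuracy - 1 / 3), 0.1)
})

test_that("boosting with shrinking rate approaches the class-conditional
           majority rule on a binary feature", {
  set.seed(31)
  n <- 600
  x <- cbind(f = rbinom(n, 1, 0.5), g = rbinom(n, 1, 0.5))
  # class depends stochastically on f only
  labels <- ifelse(x[, "f"] == 1,
                   sample(c("increase", "no-change"), n, TRUE, c(0.8, 0.2)),
                   sample(c("decrease", "no-change"), n, TRUE, c(0.7, 0.3)))
  while (length(unique(labels)) < 3)
    labels <- sample(c("increase", "decrease", "no-change"), n, TRUE)
  m <- fit_boost(x, labels, seed = 7, n_trees = 400, learning_rate = 0.02,
                 min_split = 10)
  pred <- predict_boost(m, x)
  # majority rule: f == 1 -> increase, f == 0 -> decrease
  expect_gt(mean(pred[x[, "f"] == 1] == "increase"), 0.9)
  expect_gt(mean(pred[x[, "f"] == 0] == "decrease"), 0.9)
})

test_that("degenerate boosting inputs error cleanly", {
  x <- matrix(rpois(120, 1), 40, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(fit_boost(x, rep(c("i", "d"), 20)), ">= 3 classes")
  x2 <- matrix(rpois(300, 1), 100, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(fit_boost(x2[1:45, ], rep(c("i", "d", "n"), 15)),
               ">= 50 peaks")
})
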