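---
title: "Measuring developmental chromatin accessibility dynamics with atacdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring developmental chromatin accessibility dynamics with atacdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdyn)
```

# The analysis problem

ATAC-seq on a whole organism measures chromatin accessibility summed over
all cell types present at a developmental stage. Comparing tightly
synchronised stages (early embryo, L3 larva, young adult in the nematode
setting this package targets) turns that into a dynamics problem: which
genomic regions gain or lose accessibility between stages, which of the
distal ones behave like enhancers, and which transcription-factor motifs
predict the change. `atacdyn` implements that chain of analyses on fragment
intervals (the Tn5-to-Tn5 insert spans of paired-end ATAC reads), together
with a synthetic-data module that generates every input the chain needs.

All coordinates are 0-based half-open (BED convention); fragments are
strandless, since a Tn5 insert has no meaningful strand for accessibility
counting.

# Peak calling model

Accessibility signal is carried by Tn5 *insertion events*: each fragment
contributes one event at `start` and one at `end - 1`, so a library of n
fragments yields exactly 2n events at single-base resolution
(`cutsite_coverage()`). `call_peaks_replicate()` slides a window of
`window` bp (default 150) at `step` bp (default 20) and tests each window's
event count against a Poisson upper tail with

\[ \lambda = \max(\lambda_{genome},\ \lambda_{1kb},\ \lambda_{5kb},\
\lambda_{10kb}) \cdot w , \]

where the local rates exclude the tested window itself, so a sharp peak
does not inflate its own background. P-values are Benjamini–Hochberg
corrected across all windows genome-wide; windows with q < 0.01 and at
least `min_events` (default 8) events are merged within `merge_gap`
(default 100 bp). The summit is the maximum of 51-bp-smoothed event counts
inside the merged region. Windowed Poisson scanning with a local-maximum
lambda is the standard design of ATAC/ChIP peak callers; re-implementing it
keeps the pipeline self-contained and lets the consensus and masking policy
— the part that matters here — be tested directly.

Two guard rails: calling requires at least `min_total_events` events
genome-wide (default 10,000; lower it deliberately for toy inputs), and
peaks overlapping regions with significant signal in the input control
(Poisson against the input's genome-wide rate, BH q < 0.01) are removed by
`mask_by_input()`, which logs what it removed. A missing input control is a
loud warning, not an error.

**Consensus.** Within a stage, `replicate_consensus()` merges all replicate
peaks and keeps regions supported by more than half of the replicates (2 of
3 in the default design); the consensus interval is the union of its
supporting peaks and its summit the supporting summit with the most
smoothed events. `build_catalog()` merges the per-stage consensus sets at
gap 0 into a non-overlapping catalog with per-stage presence flags. The
"any overlap, majority support" rule is deliberately the weakest
reproducibility criterion that still uses replication; it is configurable
at the call site by passing fewer or more replicate sets.

# Differential accessibility

`peak_counts()` assigns each fragment to the single catalog peak containing
its midpoint. `differential_test()` runs a per-peak Welch t-test on
`log2(CPM + 1)` across replicates (3 vs 3 at default), BH-corrects across
the catalog, and labels classes: `increase` iff q < α and log2FC > 0,
`decrease` iff q < α and log2FC < 0, else `no-change` (α = 0.05). The
reported `log2FC` is `log2((mean CPM_B + 1) / (mean CPM_A + 1))` — a
pseudocount of one CPM keeps it finite at zero counts. With three
replicates per group a negative-binomial GLM with shared dispersion would
buy little and cost interpretability; the t-test on log-CPM is calibrated
on null simulations (observed fraction of q < 0.05 calls ≤ 0.07 over 20
seeded no-change worlds) and is a single pluggable function should a user
want to swap it.

# Enhancer candidates and enrichment statistics

A peak is **distal noncoding** when its *summit* is at least 1,000 bp
upstream or at least 500 bp downstream of every TSS (signed relative to the
TSS strand) and outside every exon; summits inside exons are `exonic`
(overriding), the rest are `promoter_proximal`. Boundaries are inclusive:
a summit exactly 1 kb upstream is distal. Classification at the summit
rather than by base-pair overlap is unambiguous when a peak spans a
boundary; the distance convention is point-based (summit position vs TSS
position). `rank_enhancer_candidates()` orders distal peaks by the largest
|log2FC| over all stage pairs, breaking ties by smaller q, then position.

**Bootstrap enrichment** (`bootstrap_state_enrichment()`): the observed
statistic per chromatin state is the number of peak summits in that state.
Each of B draws (default 10,000) re-places every peak as a length-matched
interval uniformly at random on its own chromosome, keeping the summit
offset, and recounts. Reported are fold = observed / mean(null), the
2.5–97.5 percentile interval of the observed/null fold distribution, and
the empirical p `(1 + #{null ≥ obs}) / (B + 1)` for enrichment (mirrored
for depletion), reported as the floor `1/B` when no draw reaches the
observed count — with B = 10,000 that floor is 1e-4. The null allows
placed intervals to overlap each other and is not GC- or
mappability-matched: it is the simplest defensible "expected by chance"
null, and the placement routine is a single function that can be swapped.
Under a true null the CI covers fold = 1 at its nominal rate (≥ 93/100
seeded trials in the acceptance suite), and the empirical p is
super-uniform.

State transitions of dynamic peaks (`transition_enrichment()`) and motif
presence (`motif_enrichment()`) use the one-sided Fisher exact test
(`fisher_one_sided()`, the hypergeometric upper tail), BH-corrected; odds
ratios carry the Haldane +0.5 correction so degenerate tables stay finite.

# Motif scanning and the boosting model

PWMs are probability matrices over A/C/G/T (columns sum to 1). Scanning
(`scan_pwm()`) computes the log2-odds score of every window on both
strands against a uniform background (probabilities floored at 1e-4; `N`
bases score zero); a window is a hit at ≥ 80% of the maximal achievable
score, the conventional cisBP-style threshold, recorded in output
metadata. Counts are distinct window positions, so a palindromic site
matching both strands counts once — hence reverse-complementing the genome
leaves the count matrix unchanged.

`fit_boost()` is a from-first-principles multinomial gradient-boosting
classifier: per iteration and class it fits a depth-≤3 regression tree
(rpart, no competitor/surrogate splits) to the multinomial-deviance
gradient `y_k − p_k` and applies the standard leaf update
`γ = (K−1)/K · Σr / Σ|r|(1−|r|)` with shrinkage 0.05 over 200 rounds,
after a stratified 70/30 split. Model quality is **balanced accuracy**
(unweighted mean of per-class recalls; chance = 1/3 for three classes),
appropriate because the no-change class dominates. **Relative influence**
is the per-feature sum of squared-error reductions over all splits in all
trees, computed from node deviance differences and normalised to total
100. The implementation is deliberately inspectable: the influence numbers
are a property of this code, not of a wrapped library, and the suite checks
the limiting behaviour (a single informative feature reaches ≥ 0.95
held-out balanced accuracy; label permutation collapses to chance; with
small learning rate and many rounds the model approaches the
class-conditional majority rule).

# Fragment-size profiling at ChIP summits

`summit_fragstats()` takes, per ChIP summit, the fragments overlapping
summit ± 50 bp and reports their median insert length and
fragments-per-million signal; summits with no overlapping fragment are
flagged and excluded from factor-level medians. "Overlapping the window"
(not "midpoint inside it") is the recorded convention. Factor-level
histograms are normalised to percentages and aggregated over factor
classes by the per-bin mean; 147 bp — the DNA content of one nucleosome —
is the exposed constant partitioning sub-nucleosomal from nucleosomal
mass. Pairwise factor comparisons use two-sided Mann–Whitney tests on
per-summit medians with BH correction. Nucleosome-occupancy change
(`occupancy_change()`) is the windowed (± 100 bp) difference of
depth-normalised (mean 1, 5% tolerance enforced) H3 tracks, summarised by
the median with a bootstrap CI — a transparent surrogate for
positioned-nucleosome occupancy callers, and labelled as such.

# The synthetic world

`simulate_world()` generates the study conditions the analyses assume, at
the smallest scale at which every statistical property is well powered in
about a minute on one CPU:

* **Genome**: 2 chromosomes × 1 Mb of uniform random sequence.
* **Genes**: 200, on an even slot grid (guaranteeing intergenic room), each
  with 2–4 exons; TSSs stranded.
* **Truth peaks**: 600 non-overlapping peaks of 150–400 bp; 30% with
  summits 20–300 bp upstream of a TSS (promoter-proximal, non-exonic),
  the rest ≥ 1 kb from every gene.
* **Dynamics**: 40% of peaks change between the first two stages and 5%
  between the last two — mirroring the strong asymmetry between the
  embryo-to-larva and larva-to-adult transitions — with gain/loss split
  evenly; levels move between U(0.02, 0.12) and U(0.6, 1.0), and class
  labels are derived from the levels with a fold-2 threshold, so labels and
  levels cannot disagree.
* **Motifs**: a built-in library of six sharp PWMs; the 16-bp dimeric
  GA-repeat motif is planted (as its consensus, random strand) in 80% of
  gain-class peaks and 5% elsewhere, decoys at background rates; planted
  site coordinates are recorded in the truth object.
* **Fragments** (`simulate_atac_fragments()`): midpoints are drawn from
  peaks (Gaussian around the summit) with probability proportional to the
  stage level, over a uniform background; insert lengths follow the
  sub-nucleosomal + laddered mixture `Exp(scale 40 bp) + 20 bp` and
  Gaussians (sd 20 bp) at 60 + k·147 bp, k = 0, 1, 2. Peak-origin
  fragments are mostly sub-nucleosomal (70/15/10/5% over the four
  components) and background fragments mostly mono/di-nucleosomal
  (15/15/45/25%): open chromatin yields short inserts, nucleosomal DNA the
  ladder. These component weights are free parameters of the model — the
  real-data constraint is only the 147 bp spacing, which is the tested
  property.
* **Input control**: uniform fragments plus 5 artifact hotspots (1 kb,
  50× rate), half placed on truth peaks so that input masking is actually
  exercised end to end.
* **ChIP summits**: canonical-TF summits inside accessible peaks,
  nucleosome-proximal summits near a background nucleosome grid away from
  peaks, heterochromatin summits inside heterochromatin segments.
* **States**: per stage, a painted segmentation over
  {promoter, active_enhancer, repressed_enhancer, transcribed,
  H3K27me3_repressed, heterochromatin}; a peak's label follows its level
  (≥ 0.5 active, 0.15–0.5 repressed enhancer, below that the underlying
  background), so gain peaks realise inactive→active state transitions by
  construction.

Everything is deterministic given the seed; replicates differ only by
their derived sub-seeds (`derive_seed()`), i.e. sampling noise — no batch
effects. What passing tests on this world do **not** show: robustness to
GC/mappability bias, duplicated reads, mitochondrial contamination,
batch-confounded replicates, or chromatin states estimated (rather than
constructed) from histone marks. The world is a correctness instrument,
not a realism benchmark.

# Numerical choices

* **Periodicity estimator.** The insert-size histogram is truncated to the
  informative range (up to the 99.9th percentile length + 50 bp), log1p
  counts are detrended with a **201-bp running median**, and the period is
  the argmax of the residual autocorrelation (nucleosomal range, ≥ 100 bp)
  over lags 100–200. A 51-bp median window — a natural first choice — was
  found to absorb most of each sd-20 ladder bump and bias the recovered
  lag low by 5–13 bp; the wider window recovers planted periods of 120,
  147 and 180 bp within ± 5. Significance is the z-score of the
  max-over-window autocorrelation against 1,000 **value permutations** of
  the residual (the same max statistic, so selection is matched).
  Circularly shifting the whole residual series is not a usable null —
  shifting preserves autocorrelation — and permutation is what destroys
  the lag structure while keeping the marginal distribution. A period is
  reported only at z ≥ 3 with an interior argmax (the boundary guard
  rejects monotone-trend artifacts such as a uniform length cliff); the
  detector is silent (with a warning) below 10,000 fragments. On
  white-noise histograms the detector fired 0 times in 100 seeded trials.
* **Degenerate differential rows.** Zero-variance rows get p = 1 when the
  group means agree and p = 0 when they differ (the Welch limit).
* **Ties.** Peak summits break ties leftmost; enhancer ranking breaks
  |log2FC| ties by q, then genomic position; Mann–Whitney uses the normal
  approximation with mid-ranks (exact = FALSE), appropriate at the ≥ 10
  summits the comparison requires.
* **Bootstrap fold CIs** divide by null counts; draws with a zero null
  count contribute no finite fold and are dropped from the percentile
  (`NA`-removed), which can only widen the interval.
* **Problem sizes in the test suite.** Unit tests run on a scaled world
  (0.6 Mb, 150 peaks, 30,000 fragments per replicate); the acceptance
  suite runs the default study conditions (five seeds of the full
  three-stage pipeline, 20 null calibration draws, 100 CI-coverage
  trials, B = 10,000 for the p-floor check). These sizes were chosen as
  the smallest at which each property is well powered.

# Known limitations

Single-end data, BAM input and blacklist curation are out of scope (a
user-supplied exclusion BED can be applied as an extra masking step);
peak calling on a single replicate is supported only for exploration
(consensus requires ≥ 2); the bootstrap null is not composition-matched;
motif discovery is not included — any externally discovered PWM library in
MEME or TSV form slots into the scanner.
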