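# atacdyn

Chromatin accessibility dynamics from whole-organism ATAC-seq.

`atacdyn` analyses developmental chromatin accessibility from paired-end
ATAC-seq fragment intervals collected at several life stages with biological
replicates — the setting of whole-animal *C. elegans* ATAC-seq across early
embryo (EE), larval stage 3 (L3) and young adult (YA). It is written for
computational biologists who want a self-contained, testable implementation
of the full analysis chain:

* **Library QC** — insert-size histograms with a nucleosome-periodicity
  detector (detrended autocorrelation over lags 100–200 bp), TSS enrichment
  profiles, and Spearman-correlation clustering of replicates.
* **Peak calling** — a replicate-level Poisson scan on Tn5 insertion events
  (each fragment contributes its two cut sites): windows of width *w* are
  tested against `Poisson(λ·w)` with λ the maximum of the genome-wide rate
  and 1/5/10 kb local rates, BH-corrected; significant windows are merged and
  peaks masked against regions with significant signal in an input control.
* **Consensus and catalog** — majority-vote consensus per stage (a region
  must be supported by peaks in more than half of the replicates) and a
  non-overlapping cross-stage union catalog with per-stage presence flags.
* **Differential accessibility** — per-peak Welch t-tests on
  `log2(CPM + 1)` between stages, BH-adjusted, yielding three dynamics
  classes (`increase` / `decrease` / `no-change` at FDR < 0.05).
* **Enhancer candidates** — peaks whose summit is ≥ 1 kb upstream or
  ≥ 0.5 kb downstream of every TSS and outside exons are distal noncoding;
  candidates are ranked by the largest |log2 fold change| over stage pairs.
  The small-sample validation statistic is a one-sided Fisher exact test
  (hypergeometric upper tail).
* **Bootstrap state enrichment** — observed summit-in-state counts against
  B (default 10,000) draws of length-matched intervals placed uniformly on
  the same chromosome; fold = observed / mean(null), 95% percentile CI, and
  empirical p = (1 + #{null ≥ obs}) / (B + 1) reported as the floor `1/B`
  at zero exceedances. Ordered state transitions of dynamic peaks are
  tested with one-sided Fisher tests.
* **Motif machine learning** — log-odds PWM scanning on both strands
  (threshold 0.8 of the maximal score), presence/absence motif enrichment,
  and a from-first-principles multinomial gradient-boosting classifier of
  dynamics classes (depth-≤3 regression trees on multinomial-deviance
  gradients; 70/30 stratified split; balanced accuracy; per-motif relative
  influence normalised to 100).
* **Summit profiling** — median ATAC fragment size and signal at ChIP
  summit midpoints (± 50 bp), per-factor fragment-size histograms with the
  147 bp sub-nucleosomal/nucleosomal partition, Mann–Whitney comparisons
  with BH correction, nucleosome-occupancy change from H3 tracks, and
  pairwise peak-set Jaccard overlap.
* **Synthetic data** — `simulate_world()` generates a complete three-stage
  world (genome with planted motif sites, genes, truth peaks with per-stage
  accessibility levels, chromatin states, nucleosome-laddered fragment
  libraries, an input control with artifact hotspots, ChIP summits and H3
  tracks), so the entire pipeline runs and is tested without any external
  data.

## Worked example

A full pipeline run on the default simulated world (2 chromosomes × 1 Mb,
600 truth peaks, 3 stages × 3 replicates × 120,000 fragments) takes under a
minute:

```r
library(atacdyn)
cfg <- run_config(output_dir = "atac_run", seed = 1)
res <- run_pipeline(cfg, quiet = TRUE)

res$qc$periodicity$period
#> [1] 146
round(res$qc$tss_score, 2)
#> [1] 2.72
nrow(res$catalog)
#> [1] 597
table(res$differential$EE_L3$class)
#>  decrease  increase no-change
#>       111       125       361
head(res$motif_enrichment[, c("motif", "odds_ratio", "q")], 3)
#>                 motif odds_ratio            q
#> GAGA_dimer GAGA_dimer  59.120930 1.994142e-57
#> GATA_1         GATA_1   6.525242 5.634508e-11
#> BZIP_1         BZIP_1   1.358421 6.310720e-01
head(res$relative_influence, 3)
#>        motif influence
#> 1 GAGA_dimer  73.46915
#> 2      TBX_1  15.59484
#> 3     GATA_1   4.29791
round(sapply(res$summit_stats, function(s) s$factor_median_insert))
#>       tf1       tf2 eor1_like  hpl_like
#>        71        71       222       220
```

Reading the output: the insert-size ladder of the simulated library has a
dominant period of 146 bp (the planted nucleosome spacing is 147 bp); ATAC
signal at TSSs is 2.7-fold over the flanking baseline; 597 catalog peaks
are classified into dynamics classes between EE and L3; the dimeric GAGA
motif planted preferentially in gain-of-accessibility peaks is both the top
enrichment hit (q ≈ 2e-57) and the dominant feature of the boosting model
(relative influence 73 of 100); and summits of the nucleosome-proximal
factor (`eor1_like`) sit in regions with much larger ATAC fragments
(median 222 bp, above the 147 bp nucleosomal threshold) than canonical TFs
(71 bp). Replicates cluster by stage in `res$correlation$order`, and
`res$manifest` records every output file with its md5 and the seeds used.

A thin command-line wrapper around the same functions is installed at
`inst/scripts/atacdyn.R` (`simulate` and `run-all` subcommands; `--seed` is
mandatory).

## Limitations

The simulator models fragment intervals, not reads: no sequence errors, GC
or mappability bias, duplicates or mitochondrial contamination. Replicates
are exchangeable (sampling noise only). See the methods vignette
(`vignettes/accessibility-dynamics.Rmd`) for the model, parameter defaults
and the numerical choices behind the periodicity estimator and the
bootstrap null.
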