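Package: atacdyn
Title: Chromatin Accessibility Dynamics from Whole-Organism ATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for analysing developmental chromatin
    accessibility dynamics from paired-end ATAC-seq fragment intervals in a
    whole organism: replicate-level Poisson peak calling with input-control
    masking, majority-vote consensus peaks and a cross-stage catalog,
    differential accessibility with FDR-based dynamics classes, distal
    noncoding enhancer-candidate selection, bootstrap enrichment of peaks in
    chromatin-state segmentations, position-weight-matrix motif counting with
    enrichment tests, a multinomial gradient-boosting classifier of
    accessibility change with per-motif relative influence, and fragment-size
    and nucleosome-occupancy profiling at transcription-factor binding
    summits. A synthetic-data module simulates a complete three-stage worm
    world (genome, genes, truth peaks with planted motifs, chromatin states,
    nucleosome-laddered fragments, input control, ChIP summits, histone
    tracks) so that every stage of the pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rpart,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
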