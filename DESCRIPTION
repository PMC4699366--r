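Package: nucphase
Title: Nucleosome Phasing and Chromatin Accessibility Analysis for ATAC-seq Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fragment-size-stratified analysis of paired-end ATAC-seq data
    around transcription-factor motif sites: Tn5 insertion offset correction,
    nucleosome-free and mononucleosome metaprofiles with background
    normalization, CTCF-anchored cross-condition rescaling, spline smoothing
    and flanking-nucleosome summit localization, V-plot (fragment midpoint
    versus length) matrices, single-base cut-site accessibility profiles,
    union-peak differential accessibility classification, and cross-cell-type
    specificity z-scores. Includes a synthetic Tn5 fragment generator that
    plants phased nucleosomes, condition-specific compaction and jitter, and
    negative-binomial region-by-cell-type count matrices, so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
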