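# nucphase

Fragment-size-stratified ATAC-seq analysis of nucleosome phasing and
chromatin accessibility around transcription-factor motifs.

## The problem

In open chromatin, the binding motif of a lineage factor such as p63 sits
in a nucleosome-free region flanked by phased nucleosomes. When the BAF
(SWI/SNF) remodeling complex or the factor itself is lost, the flanking
nucleosomes encroach on the motif. Paired-end ATAC-seq resolves this
directly from fragment lengths: fragments < 100 bp report nucleosome-free
DNA, fragments of 180–247 bp span one nucleosome, and their midpoints
estimate nucleosome dyads. `nucphase` is for epigenomicists who want that
measurement as tested, reusable functions rather than one-off scripts.

At its core is the compaction statistic. For a condition pair, the
mononucleosome metaprofile *P(x)* (mean midpoint count per 10-bp bin in a
1-kb motif-centered window, background-normalized so the first five bins
average 1, affine-rescaled across conditions via CTCF anchor profiles, and
spline-smoothed) has flanking summits `x_L < 0 < x_R`; compaction is

```
Δ = (x_R − x_L)_control − (x_R − x_L)_perturbed
```

with per-flank shifts reported signed toward the motif. Summits are refined
below bin width by quadratic interpolation. The package also provides Tn5
cut-site correction (+4/−5 around the 9-bp insertion stagger), V-plot
matrices (midpoint offset × fragment length), single-base cut-site
accessibility profiles, union-peak differential accessibility
(fold change ≥ 2, BH FDR < 0.01, exact binomial stand-in test),
hypergeometric set-overlap significance, and cross-cell-type specificity
z-scores (asinh transform, per-region z, KS comparison).

A synthetic fragment generator plants all of this structure — phased dyads,
condition-specific compaction and jitter, the 9-bp Tn5 stagger, NB
region × cell-type count matrices — so every stage is validated by
parameter recovery with no sequencing data.

## Worked example

Simulate control and BAF-loss libraries at 2,000 p63-like sites (with 1,000
CTCF-like anchors for cross-condition rescaling) and recover the planted
compaction:

```r
library(nucphase)

genome <- genome_model("chrS", 2e7)
p63  <- generate_sites(genome, 2000, "p63-like",  min_spacing = 2000, seed = 1)
ctcf <- generate_sites(genome, 1000, "CTCF-like", min_spacing = 2000, seed = 1001)
sites <- rbind(p63, ctcf)
attr(sites, "chrom_length") <- genome$chrom_length

ctrl <- simulate_fragments(sites, condition_profile("CTRL"),
                           frags_per_site = 100, seed = 12)$fragments
bafi <- simulate_fragments(sites, condition_profile("BAFi"),
                           frags_per_site = 100, seed = 13)$fragments

res <- run_compaction_analysis(ctrl, bafi, p63, ctcf)
res$control_summits$inter_summit_distance
#> [1] 369.8961
res$perturbed_summits$inter_summit_distance
#> [1] 329.4474
res$per_flank_shift
#>     left    right
#> 19.54865 20.90010
res$total_compaction
#> [1] 40.44875
```

The control flanking summits sit ~370 bp apart (planted dyads at ±185 bp);
under the BAF-loss profile each flank moves ~20 bp toward the motif, a total
compaction of ~40 bp — the pipeline recovering the planted 2 × 20 bp shift
through binning, normalization, CTCF rescaling, smoothing, and sub-bin
summit refinement. The CTCF negative control
(`run_compaction_analysis(ctrl, bafi, ctcf, ctcf)`) stays within one bin of
zero.

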