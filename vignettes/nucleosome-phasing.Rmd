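---
title: "Measuring nucleosome phasing and compaction from ATAC-seq fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nucleosome phasing and compaction from ATAC-seq fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucphase)
```

## The measurement problem

ATAC-seq tags open chromatin with the Tn5 transposase, which inserts
sequencing adaptors preferentially between nucleosomes. Paired-end fragment
lengths therefore carry positional information: fragments shorter than
100 bp come from nucleosome-free DNA, while fragments of 180–247 bp span a
single nucleosome, so their midpoints estimate nucleosome dyads. Around the
binding motif of a lineage transcription factor such as p63, open chromatin
shows a stereotyped architecture — a nucleosome-free region over the motif
with phased nucleosomes on both flanks. When a chromatin remodeler (the BAF
complex) or the factor itself is depleted, the flanking nucleosomes encroach
on the motif. `nucphase` quantifies that encroachment as *compaction*: the
reduction of the distance between the two flanking mononucleosome summits of
an averaged profile.

Because the deposited sequencing data are not needed to test the geometry of
the measurement, the package ships a synthetic fragment generator that
plants a known architecture and perturbs it the way the biology does; every
analysis stage is then validated by parameter recovery against that planted
truth.

## Tn5 geometry and cut-site correction

The Tn5 dimer inserts two adaptors 9 bp apart, so the 5' ends of the plus-
and minus-strand reads of one insertion event straddle the physical
insertion center. `tn5_correct()` shifts plus-strand read starts by +4 bp
and minus-strand 5' ends by −5 bp, collapsing each event onto a single
corrected cut coordinate. Coordinates are 0-based half-open throughout; a
minus-strand 5' end is stored as `end − 1` of its alignment interval, which
round-trips cleanly through BED tooling.

## The metaprofile pipeline

`fragment_center_profile()` counts fragment midpoints in a 1-kb window
around each anchor, in 100 bins of 10 bp, orienting offsets by site strand
and averaging over sites. Midpoints are `floor((start+end)/2)`; minus-strand
sites negate the offset, with floor binning and a single-coordinate edge
clamp so an offset of zero falls in the same bin on either strand.

Downstream steps, in the order the package applies them:

1. **Background normalization** (`normalize_background()`): every bin is
   divided by the mean of the first five bins, fixing the background at one.
   No pseudocount is applied; a profile with an empty background tail is an
   error asking for more data, not something to paper over.
2. **Cross-condition rescaling** (`fit_reference_transform()`): library
   signal-to-noise differs between conditions, so profiles at CTCF anchors —
   a feature empirically stable under both perturbations — are matched by an
   ordinary least-squares affine fit over all bins, and the fitted transform
   is applied to the profiles of interest. OLS is the simplest transform
   consistent with a "linear transformation", closed-form and testable. The
   fit uses the same size class as the profile being scaled.
3. **Smoothing** (`smooth_profile()`): a cubic smoothing spline
   (`stats::smooth.spline`) evaluated back at the bin centers, `spar` 0.4 by
   default (sensible range 0.3–0.5). Smoothing happens after normalization
   and scaling, before summit calling, so the summit sees a single
   consistent signal; the choice of order is ours, and monotone transforms
   of the y-axis do not move an argmax, so it is inconsequential for
   compaction.
4. **Summit localization** (`locate_summits()`): on each flank, the maximum
   within 60–400 bp of the anchor, restricted to interior local maxima
   (a monotone flank is an error, a boundary maximum a truncation warning),
   refined by a three-point quadratic interpolation through the winning bin
   and its neighbours. 10-bp bins cannot otherwise resolve a 20-bp shift;
   the parabola vertex is clamped to half a bin. Ties break toward the
   position farther from the anchor.
5. **Compaction** (`estimate_compaction()`): control inter-summit distance
   minus perturbed inter-summit distance; per-flank shifts are signed toward
   the anchor. Because an affine rescaling never moves an argmax, the
   estimate is invariant to library depth whenever the reference scaling is
   applied — a property the tests assert exactly.

One textual ambiguity deserves a note: the binning prescription we follow is
100 bins of 10 bp across the 1-kb window. The five background bins then span
the outermost 50 bp of the window tail, which is the only reading compatible
with treating them as background, and matches the 10-bp bins used for the
companion coverage metaplots (`coverage_metaplot()`, counts per million
records).

## The V-plot and base-resolution views

`build_vplot()` bins (midpoint offset, fragment length) pairs into a 2-D
matrix — phased nucleosomes appear as focal spots at mononucleosome lengths
offset from the anchor, and the accessible motif as a short-fragment apex.
Counts are normalized per site and per million library fragments so panels
are comparable across conditions; the y-axis bin of 5 bp and x-axis bin of
10 bp are package defaults, not reported values. Fragments longer than the
y-range are excluded and tallied. The mono-length row marginal of the matrix
equals the fragment-center profile computed on length-filtered fragments,
bin for bin — an internal consistency the tests assert exactly.

`cutsite_base_profile()` counts corrected cut sites at single-base offsets
(±100 bp by default), per million cuts, averaged over sites;
`motif_accessibility_change()` summarizes a condition contrast as the log2
ratio of mean counts in the motif core (center ±10 bp — the aggregation
window is a package choice). Zero core means yield an explicit undefined
flag rather than ±Inf.

## Differential accessibility and specificity scoring

`merge_union_peaks()` merges replicate peak calls by single linkage at a
300 bp gap; `count_read_ends()` counts both fragment endpoints (the right
endpoint at `end − 1`, the last covered base) per merged peak per condition.
`classify_differential()` labels peaks lost/gained/independent at normalized
fold change ≥ 2 and BH FDR < 0.01. The per-peak test is a library-size-
normalized two-sided exact binomial test — a deliberate, documented
stand-in for a negative-binomial count model: with one library per
condition there is no replicate dispersion to estimate, and the binomial
test is closed-form and oracle-testable. Fold changes carry a 0.5
pseudocount on both sides. Set-overlap significance
(`overlap_significance()`) is the hypergeometric upper tail.

`transform_counts()` variance-stabilizes region × cell-type counts with the
inverse hyperbolic sine. A literal arcsine is undefined on unbounded counts;
asinh is the standard variance-stabilizing choice that shares the name
history, and a strict arcsine-of-square-root-proportion variant is kept
behind `method = "arcsin_prop"` for comparison. `region_zscores()` then
z-scores each region across cell types with the sample (n−1) SD; rows with
zero SD score 0 everywhere and carry a `degenerate` flag so joins conserve
regions. `compare_zscore_distributions()` is the two-sample two-sided
Kolmogorov–Smirnov test with the asymptotic p-value.

## What the generator plants, and what it does not

`simulate_fragments()` draws, per site, a mixture of nucleosome-free
fragments (centers Normal(motif, 25 bp), lengths uniform 30–99 bp),
mononucleosome fragments (centers on a planted flanking dyad plus Gaussian
jitter, lengths truncated-normal 210 ± 15 bp in 180–247), and uniform
genome-wide background (lengths from a fixed 0.40/0.45/0.15
NFR/mono/dinucleosome mixture, chosen once as a plausible library
composition). Each fragment emits the four uncorrected read starts of its
two insertion events, with the exact 9-bp stagger.

Condition profiles encode the study conditions as defaults:

| condition | NFR weight | per-flank dyad shift | jitter SD |
|-----------|-----------:|---------------------:|----------:|
| CTRL      | 0.35       | 0 bp                 | 20 bp     |
| BAFi      | 0.14       | 20 bp                | 35 bp     |
| p63i      | 0.14       | 12/13 bp alternating | 35 bp     |

The mononucleosome weight is 0.45 throughout, and flanking dyads sit 185 bp
from the motif center in the control — the distance and the signal-to-noise
at p63-like sites are not reported quantities, so these are plausible fixed
choices, not measurements. The p63i shift alternates 12 and 13 bp across
sites so the planted mean total compaction is exactly 25 bp without
fractional coordinates. Perturbations apply only at p63-like sites;
CTCF-like anchors always receive control weights and geometry, which is the
stability that makes them usable as a scaling reference and as the negative
control. `simulate_dhs_counts()` plants shared-open, lineage-specific, and
closed regions with negative-binomial counts (means 100 vs 5, dispersion
phi = 0.1, variance mu + phi·mu²).

The generator does **not** emulate sequence content, Tn5 sequence bias,
mappability, GC effects, multiple chromosomes (generation is per-chromosome
and composes trivially), or replicate structure. Passing parameter-recovery
tests therefore demonstrates that the measurement pipeline is unbiased for
the geometry it targets, not that real libraries meet its assumptions.

## Problem sizes and numerical choices

Validation simulations use 2,000 p63-like and 1,000 CTCF-like sites on a
20 Mb synthetic chromosome with 100 fragments per site per condition
(~300,000 fragments per library) — the smallest design at which the summit
standard error sits comfortably inside one 10-bp bin, and small enough that
the whole recovery suite runs in seconds. The generator's default 2 Mb
chromosome suits quick examples; dense designs simply use a longer one.
Fixed seeds make every generated dataset byte-reproducible.

Degenerate inputs fail loudly by design: infeasible site packing, a dyad
shift that would cross the motif, constant reference profiles (scale
unidentifiable), overlapping peaks passed to end counting, single-cell-type
z-scores, and empty KS samples are all errors with actionable messages.

## Known limitations

* The binomial stand-in ignores replicate overdispersion; with replicated
  real data a count model with dispersion estimation is the right tool, and
  this package's classification should then be read as the merge/count/
  threshold scaffold around it.
* Summit localization reports a single pair per profile; it does not model
  higher-order phasing (second and third nucleosomes) or call dyads per
  locus.
* Compaction estimates inherit the profile's bin width: recovery is
  validated to within one bin (±10 bp) at study scale, and the per-flank
  quadratic refinement to ±5 bp.
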