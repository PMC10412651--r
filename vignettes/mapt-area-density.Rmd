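---
title: "Per-cell MAPT transcript area density: measurement model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-cell MAPT transcript area density: measurement model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maptquant)
```

## The measurement

`maptquant` quantifies how much *MAPT* (tau) transcript signal a single cell
carries in a multiplex RNAscope fluorescence image, and asks whether cells
bearing phospho-tau (AT8) inclusions — neurofibrillary tangles in neurons,
coiled bodies in oligodendrocytes, tufted astrocytes — express more or less
*MAPT* than their inclusion-free neighbours.

RNAscope renders each transcript as a small fluorescent punctum. In tissue,
puncta occur individually or fuse into small confluent clusters, so
counting spots per cell is unreliable. The package therefore measures an
**area density**: for a cell region of interest $C$ and the binary mask $T$
of transcript-positive pixels,

$$ d = 100 \cdot \frac{|T \cap C|}{|C|} \quad (\%). $$

Being a ratio of pixel counts, $d$ is independent of the physical pixel
size, bounded in $[0, 100]$, and additive over sub-compartments: the
transcript-positive area of the whole cell splits exactly into nuclear and
cytoplasmic parts. A nuclear variant uses the nucleus mask in place of $C$;
with no nucleus mask the nuclear density is *missing*, never zero.

## Per-cell ROIs

Cells are found from the DAPI channel and grown outward:

1. **Nucleus detection** (`detectNuclei`): Otsu threshold, hole filling,
   distance-transform watershed to split touching nuclei, then an area gate
   (default 15–150 µm²) against debris and clumps. The choice is
   deliberately parameter-light; the original analysis used closed
   commercial software, so a standard, testable pipeline stands in its
   place.
2. **ROI extension** (`extendRois`): each nucleus is dilated by a radius
   matched to the size of the cell type under study. Where dilations of
   neighbouring cells overlap, every contested pixel goes to the nearest
   nucleus (region growing from the nucleus seeds; exact ties to the lower
   cell id), so typed cells always partition their joint support. Cells
   whose mask is clipped by the field border are flagged and excluded from
   density statistics by default — a truncated denominator would bias $d$.
3. **Cell typing** (`callCellType`): the assay hybridizes *one* cell-type
   marker per section (*RBFOX3*, *Olig2* or *ALDH1L1*), so typing is binary
   typed/untyped per field. A cell is typed iff its marker-positive area
   (intensity strictly above a threshold) reaches a minimum area
   (inclusive), which suppresses false typing from processes of nearby
   cells. Morphologically distinctive populations can instead be imported
   as hand-drawn polygons (`importManualRois`).

Inclusion status (`classifyInclusion`) uses the same intensity-plus-area
logic on the AT8 channel. Fields without an AT8 channel (control tissue)
classify every cell inclusion-free, with a warning.

Transcript segmentation (`segmentTranscripts`) defaults to per-field Otsu
on the transcript channel; a fixed global threshold is available when
cross-field comparability matters more than per-field adaptation. A
uniform-intensity channel makes Otsu degenerate and is reported as an error
that points at the fixed mode.

## The statistics stage

Tissue densities are strongly right-skewed, so the analysis is
nonparametric throughout (`runDensityStats`):

* a Kolmogorov–Smirnov screen against a fitted normal (0.05 level) records
  the non-normality that motivates rank tests. Estimating the parameters
  from the sample makes this screen anticonservative (the Lilliefors
  effect); it is kept in this form because it only gates the choice of
  tests, and because it mirrors how commercial packages screen;
* Mann–Whitney U compares inclusion-bearing to inclusion-free cells within
  each cell type and region; Kruskal–Wallis compares cell types. The
  working significance level is **0.01**. The Mann–Whitney p-value is exact
  (complete enumeration) when both groups have ≤ 8 observations without
  ties, and otherwise uses the normal approximation with tie correction and
  *without* continuity correction, so that on two groups Kruskal–Wallis
  satisfies $H = z^2$ and the two tests agree exactly. No multiple-testing
  correction is applied — p-values are reported as unadjusted, matching how
  such analyses are conventionally presented;
* because within-type variation dwarfs most group shifts, significance is
  supplemented by an **exceedance criterion** (`exceedance`): the
  proportion of inclusion-bearing cells whose density lies strictly above
  (or below) the 95th percentile of the inclusion-free reference. A
  proportion reaching 50 % is flagged a strong indicator of change. The
  cutoff is the *empirical* percentile with linear interpolation between
  order statistics (R's type-7 quantile); this convention is fixed and
  documented because alternatives shift cutoffs noticeably at small n. A
  parametric standard-score variant, mean $+ z_q \cdot$ SD, is available
  behind `method = "parametric"` for sensitivity analysis — on skewed data
  the two differ, and the empirical form is the default because the
  criterion is defined operationally on the empirical distribution.
  Strictly-greater comparison makes the value-at-cutoff case unambiguous
  (it never exceeds).

Summaries are mean ± SEM (SD/√n, missing at n = 1); count-derived
percentages round half away from zero (`pctFromCounts`). Pooling
(`poolTables`) concatenates records exactly — counts and sums are
conserved — and treats cells from different cases as exchangeable. That
matches the source analyses but is pseudoreplication in the strict sense;
with three cases per group a mixed-effects treatment is not estimable, so
the caveat is documented rather than modelled.

## The expression stage

For single-nucleus RNA-seq tables (`normalizeCp10k`,
`compareMaptByCelltype`): counts are depth-normalized to 10,000 per cell
and transformed as $\log_2(1 + x)$. The pseudocount is forced — zeros
dominate single-nucleus data and a bare $\log_2$ is undefined on them; +1
is the community default and is stated prominently here. Per cell type, a
two-sided Mann–Whitney test compares control and disease groups. Upstream
clustering, embedding and marker-based annotation are out of scope: the
stage consumes cell-type labels.

## What the synthetic generator emulates

`generateField` builds fields with known per-cell truth:

* cells are **disks** (nucleus disk inside cell disk). Real cells are
  irregular, but the measured statistic is an area ratio, which disks
  preserve; shape realism buys nothing for the quantities under test.
* true densities are drawn from a **clipped lognormal** per (cell type,
  inclusion status). Defaults use the pooled tissue means — neurons 7.2 %,
  glia 3.1 %, with inclusion-bearing oligodendrocytes elevated ×1.5 — and
  sdlog 0.8, giving the heavy right tail and strong non-normality seen in
  tissue (every pooled KS screen there rejected at p < 0.001).
* transcript signal is stamped as **puncta** (0.5–1 µm diameter disks),
  which with probability 0.3 seed confluent clusters of 2–5 overlapping
  puncta — the morphology that justifies area- over count-based
  measurement. Stamping continues until the cell's transcript-positive
  pixel fraction first reaches the drawn density; the last punctum is
  trimmed so the realized fraction matches the drawn value to within one
  pixel. The stored whole-cell truth is the drawn density; the nuclear
  truth is the realized fraction inside the nucleus mask.
* imaging model: intensities on a [0, 1] scale with background 0.08,
  signal amplitude 0.8, Gaussian PSF blur of 0.5 px and read noise
  SD 0.03. At the default field composition (≈ 105 cells in a
  384 × 384 µm field at 0.5 µm/px, transcript-positive fraction ≈ 0.7 % of
  pixels) per-field Otsu recovers the positive area accurately; at far
  sparser signal or several-fold higher noise Otsu collapses into the
  background mode, which is exactly when the fixed-threshold mode exists.
* the AT8 channel is bright only inside inclusion-flagged cells (a blob of
  1.2 × the nucleus radius clipped to the cell); one marker channel lights
  the cells of the field's marker type.
* a single RNG stream is seeded from the config; per-cell draws happen in
  deterministic placement order, so identical configs give bit-identical
  fields, truth and tables, without touching the caller's RNG state.

What it does **not** emulate: irregular cell and inclusion shapes, uneven
illumination and autofluorescence, optical crowding of dense neuropil,
section-to-section staining variability, and spatial correlation between
neighbouring cells' expression. Recovery results on synthetic fields
therefore validate the *computational* chain — segmentation, ROI
partitioning, typing, density arithmetic, statistics — not the
photophysics of real slides.

`generateDensityTable` bypasses imaging and draws table rows straight from
the density laws, so the statistics stage can be exercised at arbitrary n
in milliseconds. `generateExprMatrix` emulates the single-nucleus count
structure: lognormal target library sizes (median ≈ 8000 UMIs, as in human
cortex nuclei), negative-binomial counts (size 2), *MAPT* abundance graded
across six cell types (highest in inhibitory neurons, then astrocytes and
OPCs, near-absent in endothelial cells) and a configurable multiplicative
disease-group shift in designated types.

## Numerical choices and degenerate inputs

* Percentile interpolation: type-7 (linear between order statistics);
  101 evenly spaced values 0…100 give exactly 95 at q = 95.
* Boundary conventions: area gates are inclusive (`>=`), intensity
  thresholds strict (`>`), exceedance strict.
* Ties: all-tied groups give Mann–Whitney p = 1 and Kruskal–Wallis H = 0,
  p = 1, rather than NaN from a zero rank variance.
* Empty inputs: a blank nucleus channel is an empty segmentation, not an
  error; an empty cell mask is an error; a zero-count cell is an error
  naming the offending cells.
* Problem sizes in the shipped tests were chosen to keep the full suite in
  the low minutes on one CPU: recovery uses 20 default fields (~2,000
  cells), calibration uses 2,000 null replicates, the expression power
  check uses 50 seeds × 24,000 cells. These sizes give the binomial/SEM
  tolerances quoted in the tests.

## Known limitations

* One marker per field means cells of other types remain untyped; their
  densities are computed but excluded from typed analyses by default
  (`keepUntyped` reverses this).
* The automated nuclear density uses the segmented DAPI mask as a proxy for
  a hand-drawn nuclear ROI; manual polygons can override it where the
  distinction matters.
* Inclusion-calling thresholds have no tissue-derived gold standard (visual
  AT8 assessment in the source workflow); the defaults are calibrated on
  the synthetic fields and are configuration, not constants.
* Cells are pooled across cases in all tests (see above); between-case
  variance is not modelled.
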