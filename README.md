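# maptquant

Cell-resolved quantification of *MAPT* (tau) transcript signal in multiplex
RNAscope fluorescence images, and the inclusion-stratified statistics used
to ask whether tau-inclusion-bearing cells — neurons with neurofibrillary
tangles, oligodendrocytes with coiled bodies, tufted astrocytes — express
more or less *MAPT* than their inclusion-free neighbours in progressive
supranuclear palsy (PSP) tissue.

The package is written for neuropathology and image-analysis groups who
have per-field multichannel TIFFs (DAPI, one cell-type marker among
*RBFOX3*/*Olig2*/*ALDH1L1*, *MAPT* probe, AT8 immunofluorescence) and want
a reproducible, testable version of the capture → extend → annotate →
quantify → test workflow, plus a seeded synthetic-field generator with
exported ground truth to validate every stage.

## The measurement and the analysis

RNAscope puncta occur singly or in small confluent clusters, so per-spot
counting is unreliable; the per-cell statistic is instead the **area
density**

> d = 100 · (transcript-positive area within the cell ROI) / (ROI area) [%],

with a nuclear variant on the nucleus mask. Cell ROIs are DAPI nuclei
(Otsu + watershed) dilated by a cell-type-specific radius, with contested
pixels going to the nearest nucleus; cells are typed by marker intensity
*and* area thresholds (one marker per field). The statistics stage is
nonparametric at α = 0.01 (Mann–Whitney U, Kruskal–Wallis, KS normality
screen at 0.05), reports mean ± SEM, and supplements p-values with an
**exceedance criterion**: the proportion of inclusion-bearing cells whose
density lies strictly above the empirical 95th percentile of inclusion-free
cells, with ≥ 50 % read as a strong indicator of change. A CP10K +
log2(1+x) expression stage compares *MAPT* between control and PSP groups
per cell type in single-nucleus RNA-seq tables. The methods vignette
(`vignettes/mapt-area-density.Rmd`) documents the model, defaults and
design decisions.

## Worked example

Simulate a field under the default study conditions (pooled density means
7.2 % in neurons, 3.1 % in glia, heavy-tailed lognormal spread, 0.5 µm/px),
quantify it, and inspect the result:

```r
library(maptquant)

cfg <- synthFieldConfig(seed = 42, markerType = "oligodendrocyte")
sim <- generateField(cfg)
sim$truth
#> GroundTruth: 105 synthetic cells (15 inclusion-bearing)

dt <- buildDensityTable(list(sim$field))
dt
#> DensityTable: 35 cells (5 with inclusions) from 1 field(s); mean density 2.34%
```

Only the 35 oligodendrocytes are retained: the field's single marker labels
that type, and untyped or border-clipped cells are excluded by default.
Running the statistics stage on a larger synthetic table (1,800 cells,
inclusion-bearing oligodendrocytes elevated ×1.5 by the default law):

```r
cfg <- synthFieldConfig(
  cellsPerType = c(neuron = 600L, oligodendrocyte = 600L, astrocyte = 600L),
  inclusionFraction = c(neuron = 0.15, oligodendrocyte = 0.15, astrocyte = 0.15),
  seed = 7)
tab <- generateDensityTable(cfg, 1800)$table
rep <- runDensityStats(tab, alpha = 0.01, q = 95)

subset(rep$comparisons, region == "pooled", c(cell_type, p_value, significant))
#>         cell_type      p_value significant
#>            neuron 6.251436e-01       FALSE
#>   oligodendrocyte 8.362033e-07        TRUE
#>         astrocyte 4.677403e-01       FALSE

subset(rep$exceedance, region == "pooled" & direction == "above",
       c(cell_type, cutoff, n_exceeding, n_test, proportion_pct))
#>         cell_type    cutoff n_exceeding n_test proportion_pct
#>            neuron 20.521061           3     76       3.947368
#>   oligodendrocyte  8.913268          13     89      14.606742
#>         astrocyte  8.073680           5     99       5.050505
```

The inclusion-vs-no-inclusion comparison is significant only for
oligodendrocytes (p ≈ 8×10⁻⁷ < 0.01), and their exceedance proportion is
elevated (14.6 % vs the ~5 % null rate) while still short of the 50 %
strong-indicator bar — the qualitative pattern reported for coiled bodies
in tissue, where significance coexists with large within-type overlap.
Neurons and astrocytes stay null on both readouts, as generated.

An end-to-end run (simulate → quantify → stats → exprstats, TIFF/CSV/JSON
artifacts plus a manifest) is driven by a YAML config:

```r
runPipeline(readRunConfig(system.file("extdata", "demo_config.yaml",
                                      package = "maptquant")))
```

or from a shell via `inst/scripts/maptquant.R`.

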