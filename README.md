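# lfqatlas

Statistical analysis of developmental label-free quantification (LFQ)
proteomic atlases — protein-by-sample intensity matrices measured over
brain regions and developmental stages, the kind of data produced when
many anatomical regions are profiled by quantitative mass spectrometry at
several fetal and neonatal time points.

It is written for proteomics analysts and computational biologists who
need the full downstream toolchain for such an atlas as composable,
pipe-friendly R functions, each returning a tidy tibble:

* **Differential abundance** — two-sided pooled-variance Student's
  t-tests of log2 LFQ, one region vs the rest at a stage or one stage vs
  the rest, with Bonferroni control within each contrast and DEPs called
  at adjusted p < 0.05.
* **Marker proteins** — one-vs-rest ROC AUC by the Mann–Whitney pair
  construction (`AUC = (#{a > b} + ½·#{a = b}) / (n_in · n_out)`), with
  markers at AUC > 0.7 and linear fold change > 1.
* **Composition trends** — intensity-weighted percentages of subcellular
  localizations and protein families per sample, with adjacent-stage
  t-tests for the solid/dashed trend convention.
* **Regional dynamics** — the inter-regional difference (mean |Δ log2|
  over cross-region sample pairs in a macro-region), cerebellum-to-region
  Euclidean distances, stage–stage Pearson correlations, and
  complete-case PCA.
* **Temporal events** — newly emerging proteins (zero before, detected
  and significantly up after, using a detection-floor t-test), per-day
  rates of change, and gene-set abundance trajectories.
* **Fuzzy c-means trend clustering** of z-scored stage trajectories, with
  the per-iteration objective exposed.
* **Over-representation analysis** — exact hypergeometric tail with BH
  correction, plus adjacent-stage overlap rates and newly enriched sets.
* **Cross-species conservation** — pairwise Pearson correlations of 1:1
  ortholog regional profiles across human/monkey/mouse and interval-rule
  classes (human-specific [−1, −0.5] on both human comparisons;
  conserved [0.75, 1] on monkey–human and monkey–mouse;
  primate-specific residual; else unclassified).
* **RNA/protein concordance** — six-type classification of paired
  prenatal→postnatal fold changes by magnitude (|FC| vs 2) and direction
  agreement.

A first-class synthetic-data generator (`simulate_atlas()`,
`simulate_ortholog_panel()`, `simulate_rna_protein_pairs()`) emulates the
full study design — log-normal intensities, stage/region effects,
intensity-dependent dropout, 5/11/18/18 regions across four stages with
three replicates, technical CB replicates at F90 — and plants exact,
ledgered structure (markers, emergent proteins, trajectory sets,
conservation classes, concordance types) so every statistic can be
validated against known truth. `full_run()` chains everything into a
deterministic TSV bundle with a manifest.

## Worked example

```r
library(lfqatlas)
library(dplyr)

sim <- simulate_atlas(sim_config(seed = 42))
sim$atlas
#> <lfq_atlas> 2000 proteins x 156 samples
#>   detected entries: 82.7%
#>   samples per stage: F50=15, F90=33, F120=54, P3=54

# stage-axis vs region-axis DEP unions (CB excluded)
dep_summary(sim$atlas, grouping = "all_excl_cb") |> select(axis, n_deps)
#>   axis   n_deps
#> 1 stage    1828
#> 2 region     33
#> 3 both       30

# stage markers at AUC > 0.7 and fold change > 1
find_markers(sim$atlas,
             class_partition(sim$atlas, "stage", exclude_regions = "CB")) |>
  filter(marker) |>
  count(class)
#>   class     n
#> 1 F120    557
#> 2 F50     519
#> 3 F90     586
#> 4 P3      576

# inter-regional difference curve in the cortex
interregional_curve(sim$atlas) |> filter(group == "CTX")
#>   stage group value n_pairs
#> 1 F50   CTX   0.695      54
#> 2 F90   CTX   0.637     189
#> 3 F120  CTX   0.609     702
#> 4 P3    CTX   0.675     702

glance(fuzzy_cmeans_trends(sim$atlas, seed = 42))
#>   n_proteins n_clusters iterations objective converged n_dropped
#> 1       1939          4         67     1253.  TRUE            61
```

Reading the numbers: far more proteins separate *stages* than separate
*regions* (1828 vs 33) — temporal variability dominates spatial
variability, which is exactly the regime the generator's defaults encode
(stage-effect SD 1.0 vs region-effect SD 0.35). Each stage has several
hundred upregulated marker proteins, including all 20 planted per stage.
The cortical inter-regional difference traces a shallow V with its
minimum at F120, the planted inflection, and the four-cluster fuzzy fit
converges in 67 iterations on the 1939 proteins with complete, non-flat
stage trajectories. Result objects provide `tidy()`/`glance()` methods
and `autoplot()`/`plot_*()` diagnostics (`autoplot(fit)`,
`plot_interregional()`, `plot_concordance()`, …).

## Documentation

The methods vignette (`vignettes/lfqatlas-methods.Rmd`) describes the
statistical procedures, the generator's model and defaults, the numerical
conventions (zero handling, detection floor, tie-breaks, degenerate
inputs), and the design decisions taken where published rule systems are
ambiguous — notably the six-type concordance partition and the
conservation interval precedence.
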