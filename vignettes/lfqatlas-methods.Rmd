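---
title: "Methods: models, statistics and design choices in lfqatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in lfqatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqatlas)
library(dplyr)
```

## The data model

lfqatlas analyses developmental label-free quantification (LFQ) proteomic
atlases: a proteins-by-samples matrix of LFQ intensities together with
per-sample metadata (developmental stage, brain region, macro-region,
animal, replicate kind). Two conventions run through every function:

* **Zero means undetected.** An LFQ intensity of exactly 0 encodes
  non-detection, not a true zero abundance. Averaged and tested statistics
  treat undetected entries as *missing* — they never enter a mean or a
  t-test as zeros, which would manufacture enormous spurious effects.
  Presence/emergence logic treats them as *absent*. No pseudocount is ever
  added.
* **log2 scale for location statistics.** Intensities are approximately
  log-normal, so t-tests, distances, correlations and trajectories operate
  on `log2(LFQ)` of the detected entries. Fold changes, composition
  percentages and gene-set sums stay on the linear intensity scale.

The default sampling frame mirrors a fetal-to-neonatal primate brain
design: four stages (F50, F90, F120 at 50/90/120 days post-fertilization,
P3 at gestation ≈ 150 days + 3), a region panel that widens from 5 regions
at F50 to 11 at F90 and 18 at F120/P3 as finer structures become
dissectable, three biological replicates per (region, stage), and — as a
deliberate idiosyncrasy of the emulated design — *technical* rather than
biological CB replicates at F90. Region codes map onto macro-regions
(CTX / sCTX / CB) and onto cortical lineages (PFC, TL, PL, V1, …) so that
a territory can be followed across stages even as its subdivisions are
renamed.

## Statistical procedures

**Differential abundance.** Two-sided pooled-variance Student's t-tests on
log2 LFQ compare one region against all other same-stage samples, or one
stage against the rest. A protein is tested only when each side has at
least two detected values; untested proteins are reported as such.
Bonferroni correction is applied within one contrast (the family is the
set of proteins tested in that contrast, not all contrasts pooled), and a
differentially expressed protein (DEP) is called at adjusted p < 0.05.
Degenerate inputs are defined, not errors: identical constant groups give
t = 0, p = 1; constant groups with different means give p = 0. Welch's
test is deliberately not the default (a config option would be trivial,
but the pooled test is the reference procedure here); limma-style
moderated variances are out of scope. The stage-axis and region-axis DEP
unions and their intersection are summarised by `dep_summary()`, with CB
excludable because its profile dominates any pooled contrast.

**Marker detection.** One-vs-rest markers use the Mann–Whitney
construction of the ROC AUC: over all cross pairs, a pair scores 1 when
the in-class value is larger and 0.5 on ties (mid-rank tie handling; the
rank-sum identity makes this O(n log n)). A marker needs AUC > 0.7 *and*
linear fold change > 1 — "fold change" is read as the linear ratio of
group means over detected entries, not log2 units (ratio > 2 would be a
far stricter rule; the threshold pair 0.7/1 only makes sense with the
linear reading, since AUC > 0.7 already implies a consistent direction).
A protein must be detected in at least two class samples to be a
candidate. Ranking is AUC-descending with fold change and then protein ID
as tie-breaks.

**Composition.** The percentage of a sample's proteome in a subcellular
localization or protein family is intensity-weighted:
`100 · Σ LFQ(members) / Σ LFQ(all proteins)`. Multi-label proteins count
fully toward each label (membership, not apportionment), so sums can
exceed 100%; unannotated proteins stay in the denominator. Percentages
are scale-invariant per sample by construction. Adjacent-stage trend
significance (the solid/dashed line convention) uses per-segment
uncorrected two-sided pooled t-tests, mirroring figure-level testing;
`p_adjust` offers a correction across segments when wanted.

**Regional dynamics.** The inter-regional difference at a stage is the
mean absolute difference of log2 intensities over proteins detected in
both samples of a pair, averaged over all cross-region sample pairs
within a macro-region group. Same-region replicate pairs are excluded by
default — the quantity is *inter*-regional — except when a group contains
a single region (CB), where the statistic falls back to all sample pairs
with a warning. This fallback is what reproduces the characteristic dip
of the CB curve at F90: technical replicates are nearly identical, so
replicate pairs depress the average. CB-to-region dissimilarity is the
Euclidean distance between mean log2 profiles on shared detected
proteins; stage-stage similarity is the Pearson correlation of stage-mean
profiles (replicates averaged first) with the correlation-test p-value.
PCA is centered, unscaled `prcomp` on the complete-case log2 matrix:
imputation would distort the geometry, so only proteins detected in every
sample enter the SVD.

**Emergence and rates.** A protein is *new* at a stage within a region
class when it is zero in every class sample at all earlier stages,
detected afterwards, and significantly up (p < 0.05, fold change > 1).
The earlier group is all zeros, so its log2 values are undefined; the
test places that group at the *detection floor* — the smallest positive
intensity in the dataset — which is the package's explicit resolution of
an otherwise undefined comparison (the floor is reported in the output).
Non-significant appearances fold into the `absent` status. Per-day rates
of change divide the log2 stage-mean difference by the day gap
(40/30/33 days for the three transitions under the default day table);
rates telescope exactly across consecutive transitions. Gene-set
trajectories sum member intensities per sample, then average per stage,
with the same adjacent-segment t-test.

**Soft trend clustering.** Stage-mean trajectories are z-scored per
protein and clustered with fuzzy c-means (default 4 clusters, fuzzifier
m = 2, tolerance 1e-6, at most 500 iterations, seeded draw of distinct
initial centroids). The implementation is native so the per-iteration
objective `J = Σ u_ij^m ||x_i − c_j||²` is available — it is non-increasing
by construction and tested as such; `e1071::cmeans` serves as an
independent cross-check in the test suite, never as the implementation.
As m → 1 the memberships harden towards k-means assignments.

**Over-representation.** ORA is the exact hypergeometric upper tail
(via `phyper`) of the query/set overlap within a background universe,
with Benjamini–Hochberg correction across the tested sets (matching the
convention of the usual enrichment tools) and enrichment called at
q < 0.05. The universe defaults to all proteins detected anywhere in the
dataset that carry an annotation. The *overlap rate* of enriched-set
names between adjacent stages has no single canonical denominator, so
both are always computed: `100·|A∩B|/|A∪B|` (symmetric, the default) and
`100·|A∩B|/|B|` (consistent with the newly-enriched framing). Newly
enriched sets are plainly `B \ A`.

**Cross-species conservation.** Each 1:1 ortholog contributes three
Pearson correlations of its 5-region abundance profile (monkey–human,
mouse–human, monkey–mouse). With n = 5 regions these correlations are
intrinsically high-variance; that is faithful to the comparison design
and deliberately not "fixed". Conservation classes use closed-interval
rules in precedence order: *human-specific* when both monkey–human and
mouse–human lie in [−1, −0.5]; else *conserved* when monkey–human and
monkey–mouse both lie in [0.75, 1]; else *primate-specific* when
monkey–human lies in [0.75, 1] but neither mouse–human nor monkey–mouse
does (the subtraction is read as minus the union, which makes the rule
residual after the conserved intersection); everything else, including
undefined correlations, is *unclassified*. The three raw predicates are
provably pairwise disjoint, so every ortholog gets exactly one label.
Distribution summaries use eight fixed bins of width 0.25 over [−1, 1],
cumulative percentages, medians, and the two-sample Kolmogorov–Smirnov
test between comparisons.

**RNA/protein concordance.** For each gene, linear fold changes
postnatal/prenatal (default stages F120 → P3) are computed for the
protein layer (stage means of detected intensities) and joined with the
RNA layer. "Large" means |log2 FC| > 1 (|FC| > 2), direction is
`sign(log2 FC)`. The six printed type definitions overlap as literally
stated and do not tile fold-change space, so the package fixes a
disambiguated partition: Type 6 = same direction, both large; Type 5 =
opposite directions, both large; Type 2 = protein large, RNA small
(either direction); Type 3 = RNA large, protein small; Type 1 = the
small-change centre. Under this reading Type 4 ("consistent direction and
fold change > 2 at RNA *or* protein level") is the residual
consistent-direction set on the |FC| = 2 boundary — its interior is empty,
because any interior one-axis-large point already belongs to Type 2 or 3
and any both-large point to Type 5 or 6. Two considerations force this
resolution: restricting Types 2/3 to discordant directions would roughly
halve them in favour of Type 4, contradicting the observed dominance of
Types 1–3 (> 90% of genes, with Type 2 an order of magnitude larger than
Types 4–6 combined); and letting Type 5 absorb *all* opposite-direction
pairs would swallow about half of the small-change centre, contradicting
a Type 1 share near 80%. An order-free predicate oracle in the test suite
verifies that every finite positive FC pair receives exactly one type. A
gene with either FC exactly 1 has no direction and can never be Type 5
or 6.

## The synthetic-data generator

Every downstream stage is exercised on generated data with planted,
ledgered structure; nothing requires external downloads.

**Intensity model.** `log2 LFQ = baseline + stage effect + scale(stage) ·
region effect + planted shifts + replicate noise`, i.e. intensities are
log-normal. Defaults, chosen once as realistic study conditions and not
revisited: baseline mean 25, SD 1.5 (MaxLFQ-like log2 intensities);
replicate noise SD 0.5; per-(protein, stage) effects with SD 1.0 versus
per-(protein, region) effects with SD 0.35 — stage variability dominates
region variability, the qualitative regime the pipeline is meant to
resolve; a per-stage damping of region effects (1, 0.75, 0.5, 0.85) that
encodes a V-shaped inter-regional difference curve bottoming at F120;
technical-replicate noise SD 0.05 for the F90 CB samples.

**Missingness.** Dropout (entries set to 0) defaults to the
intensity-dependent mode: the dropout probability is logistic in the
standardised log2 mean with slope −1.5, calibrated to a 10% marginal
rate, so low-abundance entries drop out preferentially — as in real LFQ
data — and a complete-case stratum of abundant proteins survives for
PCA. An intensity-independent uniform mode is available. Under uniform
dropout at 10% across 156 samples *no* protein is complete-case
(0.9^156 ≈ 10⁻⁷), which is why the intensity-dependent mechanism is the
default: a generator whose default output cannot be ordinated would be a
poor emulation of the data it imitates.

**Planted structure is exact by construction.** Planted stage markers
(20 per stage) and CB markers (20) receive a +2 log2 shift in their
target class and carry *no* random background stage effects — otherwise a
protein's own effect draw could cancel the plant and the truth ledger
would misstate ground truth, turning recovery tests into tests of the
background distribution. The same holds for the 30 trajectory proteins
(a +1 log2/stage monotone step confined to the PFC lineage). Emergent
proteins (20 per adjacent-stage transition) are forced to zero before
their onset stage and guaranteed detected after it. The ortholog panel
(default 3025 orthologs with class counts 531/591/457) constructs each
triplet of 5-region species vectors from a centered orthonormal basis
mixed by the Cholesky factor of the target correlation matrix, so the
three pairwise sample correlations land *exactly* on their targets (the
third, unconstrained correlation is set to the product of the two drawn
ones, which keeps the matrix positive semidefinite); an optional noise
mode perturbs the vectors. RNA/protein pairs are drawn from each type's
defining region of FC-space (Type 4 on its boundary), with default
fractions mirroring a frontal-lobe composition (78.7/15.6/1.4% for
Types 1–3). All truth ledgers partition the planted proteins; roles never
overlap.

**Determinism.** Every generator takes a seed, uses it through an
RNG-state-restoring wrapper, and is byte-reproducible; `full_run()`
threads one root seed through every stage and writes a manifest with a
configuration hash, so an identical configuration and seed give a
byte-identical output bundle.

**What the generator does not emulate.** Peptide-level structure and
razor-peptide assignment, instrument drift and batch effects, correlated
protein modules (co-regulation), compositional closure of LFQ
normalisation, and annotation errors. Passing recovery tests on this
generator therefore demonstrates that the statistics implement their
definitions and have the expected operating characteristics under a
clean log-normal regime — not that they are robust to every artefact of
real LFQ data.

## Problem sizes used in the checks

The bundled tests and the acceptance script size their simulations so the
whole suite states something meaningful yet runs comfortably on a laptop:
the full design (156 samples) with 2000 proteins for marker/DEP
summaries, 1000-protein datasets × 200 replicates for the null
family-wise error rate, a 3025-ortholog panel, 2000 gene pairs for
concordance, and 200 trajectories for clustering recovery. These sizes
are the package's own choices; the statistics scale to larger atlases
unchanged.

## Known limitations

* The pooled t-test assumes equal variances; with n = 3 per group there
  is little power to detect violations, which matches the reference
  procedure but should be kept in mind.
* The detection-floor convention for emergence p-values is a pragmatic
  resolution of an undefined comparison; calls near the floor should be
  read qualitatively.
* Conservation classes inherit the n = 5 region design; correlation
  estimates at that length are noisy, and the interval rules are sharp
  cutoffs on noisy quantities.
* The Type 4 concordance class is a boundary set under the package's
  disambiguation; on continuous data it is effectively empty, and the
  generator plants it only on the boundary.
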