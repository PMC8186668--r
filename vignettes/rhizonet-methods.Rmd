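---
title: "Methods and design choices in rhizonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in rhizonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

rhizonet analyses sample-by-OTU count tables from monoculture
chronosequence (continuous monocropping) rhizosphere experiments. This
vignette documents the statistical procedures, the parameters that matter
and their defaults, the synthetic-data generator used for validation, and
the design decisions taken where the methodology was genuinely open.

## The data model

An `otu_table` couples an integer count matrix (samples × OTUs) with a
seven-rank taxonomy per OTU and per-sample metadata (cropping-years
`group`, development `stage`, `replicate`, `compartment`). Ingestion
rejects zero-depth samples, non-integer counts and samples without
metadata; count-file orientation is auto-detected against the metadata's
sample ids. Unresolved taxonomy ranks carry an explicit `"unclassified"`
marker rather than being dropped, and are pooled into a single
`"unclassified"` column when aggregating to a rank.

## Normalization and filtering

Counts are converted to relative abundance in per mille: each count is
divided by its sample's total depth and multiplied by 1000, so rows sum to
1000‰ exactly. No rarefying is performed; depth differences are handled by
this normalization alone.

Normalization precedes the prevalence filter, mirroring the order such
pipelines usually apply. Consequently, after dropping rare columns a
sample's row sum can fall below 1000‰; the package asserts and documents
this rather than silently re-closing, and `prevalence_filter(...,
reclose = TRUE)` restores closure when an analysis needs strict
compositions. The filter removes taxa occurring in strictly less than
`min_fraction` (default 5%) of the samples: a taxon present in exactly
`ceiling(0.05 * n)` samples is retained, i.e. ties at the threshold
survive. The filter is global by default; per-subset filtering can be
obtained by subsetting first.

Log2 fold changes between group means use a pseudo-count of 0.001‰ — the
smallest nonzero abundance representable at a depth of one million reads —
so that taxa absent from both groups report exactly 0 rather than NaN. The
pseudo-count is a parameter, not a constant.

## Diversity

Shannon entropy uses log base 2 (bits) by default; richness is a nonzero
count. Rarefaction draws `n_draws = 10` seeded subsamples without
replacement at 10 evenly spaced depths up to the minimum sample depth
(both configurable), and for richness also reports the closed-form
hypergeometric expectation, which the random draws are tested to approach.

Faith's PD follows the rooted convention: the minimal spanning subtree
always includes the path to the root, so a single observed tip contributes
its full root-to-tip length. Weighted UniFrac is computed by postorder
branch accumulation: for branch $b$ with length $l_b$,
$d(A,B) = \sum_b l_b |A_b - B_b|$ where $A_b$ is the fraction of community
$A$ below $b$; the normalized variant divides by
$\sum_b l_b (A_b + B_b)$. Both metrics require every analysed taxon to be
a tip of the supplied rooted tree — the package deliberately takes the
tree as an input rather than estimating one.

PCoA is classical metric scaling of $-D^2/2$. Negative eigenvalues from
non-Euclidean dissimilarities are reported unchanged and excluded from the
proportion-explained denominator; no Cailliez/Lingoes correction is
applied by default. PERMANOVA delegates to vegan's `adonis2` (999
permutations by default, seeded; optional permutation blocks via
`strata`), so $p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})$ and
the permutation floor is $1/(n_{perm}+1)$. RDA Hellinger-transforms the
per-mille response and z-scores the constraints by default; collinear
constraint columns are a hard error naming the dependent column.

## Differential abundance

Only taxa whose median relative abundance exceeds 2‰ (0.2%) enter
testing. The prefilter accepts a taxon if either group's median passes
(default `"any"`), since enrichment on either side is of interest; a
stricter `"both"` mode is available. Per-taxon two-sided Wilcoxon
rank-sum tests use exact enumeration when the combined sample size is at
most 12 and there are no ties, otherwise the normal approximation with tie
and continuity corrections. Benjamini–Hochberg correction is applied
within each pairwise comparison, over the tested taxa only. A taxon
constant across both groups reports p = 1 by convention rather than an
error.

## Random-forest biomarkers

Taxon abundances (typically aggregated to one rank; family is the usual
choice) are regressed against monocropping years with 500 trees;
permutation importance (mean decrease in accuracy / %IncMSE) is the
ranking criterion, with impurity importance also exposed.
Zero-variance taxa are retained but flagged with importance 0.
Classification against the group factor is available as an alternative
task. Out-of-bag variance explained, $1 - MSE_{oob}/\widehat{Var}(y)$, is
the headline fit statistic; note that regressing on a handful of distinct
year values is intentional and the forest's warning about few unique
responses is suppressed.

Feature selection follows the recursive-elimination cross-validation of
`randomForest::rfcv`: features are re-ranked within training folds and CV
error is evaluated along a halving schedule (all, half, …, 1) over 10
folds, averaged over `n_repeats` repetitions (default 5). The selected
feature count is the schedule point with minimum mean error, ties broken
toward the smaller count; a one-standard-error rule is available via
`rule = "one_se"`. The reported biomarker set is the top-ranked features
of the full-data fit at that count.

## Co-occurrence networks and node roles

All unordered taxon pairs are screened on the per-mille table (the same
table every other stage consumes, not raw counts). Spearman's ρ uses
average ranks under ties. P-values are exact by full permutation
enumeration for n ≤ 9 samples — the enumeration conditions on the observed
values, so it remains exact under ties — and use the t-approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ otherwise. The t-approximation tracks
the exact distribution closely in the central range (relative error around
1–2% at the median for n = 9) but can deviate substantially in the extreme
tail; this is an intrinsic property of the approximation and is the reason
the exact route is the small-n default. Edges require |ρ| ≥ 0.6 and
P < 0.01 (raw p by default — an optional BH mode exists but published
screens of this kind use unadjusted p), and carry the correlation sign.
Taxa nonzero in fewer than 3 samples of the subset are excluded before
correlation, because rank correlations on mostly-zero vectors are
unstable; constant taxa are skipped and logged.

Networks are built per cropping-system subset (all stages and replicates
pooled within a group), which is a parameter, not a hard-coded rule.
Isolated taxa never become nodes. Topology reports avgK = 2E/N, the mean
local clustering coefficient with degree-<2 nodes contributing 0, and the
mean geodesic distance over connected pairs only (the graphs are routinely
disconnected), treating edges as unweighted and unsigned.

Module detection maximizes Newman modularity
$Q = \sum_m (e_{mm} - a_m^2)$. The default algorithm is the multilevel
(Louvain) heuristic: in head-to-head testing it dominated fast-greedy
agglomeration both on small graphs (where fast-greedy frequently misses
the exhaustive optimum) and at network scale (where agglomerative merging
under-resolves small dense modules). Fast-greedy remains available, and an
exact integer-programming mode (`algorithm = "optimal"`) solves the
maximization outright for small graphs and is what the test suite
validates against exhaustive partition enumeration. Module counts are
algorithm-dependent and should not be over-interpreted.

Node roles use the within-module degree z-score and participation
coefficient: $Z_i = (k_{is} - \bar{k}_s)/\sigma_s$ (sample SD over the
members of the node's module; a module with zero spread yields $Z_i = 0$
for all members by convention) and $P_i = 1 - \sum_t (k_{it}/k_i)^2$.
Classification at the customary thresholds (2.5, 0.62) distinguishes
peripherals, connectors, module hubs and network hubs; values exactly at a
threshold fall into the lower (non-hub) category, since the published rule
pairs leave equality undefined.

## The synthetic-data generator

`generate_dataset()` emulates the study design the package targets: 60
samples (4 cropping-years groups × 3 stages × 5 replicates), 2000 OTUs in
a nested random taxonomy (26 phyla, ~260 families), and library depths
drawn uniformly from 50,000–160,000. Latent log abundance is

$$\log a_{so} = \mu_o + s_o \cdot \text{years}_s +
  \gamma_{\text{stage}(s),o} + \sigma \epsilon_{so}$$

with baseline $\mu_o \sim N(0, 2)$, dispersion $\sigma = 1$ log-unit, and
counts drawn multinomially from the softmax composition — log-normal plus
multinomial rather than Dirichlet-multinomial, because the planted
correlation structure stays transparent on the latent scale, with
overdispersion available through $\sigma$.

Ground truth has three layers:

* **Informative families** (default 5): whole families of 4–10 members
  whose member OTUs share a per-year slope of ±0.08 on the log scale
  (about five-fold over 20 years, in line with multi-fold shifts of
  responsive taxa along cropping chronosequences); signs alternate between
  families. A family-level biomarker is modelled as a family that shifts
  together — planting the trend in scattered single OTUs would dilute the
  family aggregate and test nothing a family-level model could recover.
* **Planted correlation modules** (default 3 modules of 12): the latent
  noise of module members is equicorrelated at $\rho = 0.9$ through a
  shared Gaussian factor ($\sqrt{\rho} f_s + \sqrt{1-\rho}\,\eta$).
  Modules are placed on abundant, stage-neutral, non-informative taxa so
  the planted structure is identifiable and attributable: realized rank
  correlations on counts are attenuated relative to the latent target (by
  the normal-rank transform and by multinomial noise), and low-abundance
  members would attenuate them below the screen threshold for reasons
  unrelated to the method under test.
* **Stage effects**: 30% of taxa receive stage offsets of SD 0.5
  log-units, giving the stage separation that PERMANOVA and ordination
  should detect, disjoint from the informative and module sets.

A random coalescent tree over the OTUs (decorative but valid for PD and
UniFrac) and a soil-property table with monotone-by-years trends plus
noise complete the dataset. Everything derives from a single seed and is
bit-reproducible.

What the generator does **not** emulate: sequencing error and chimeras,
taxon inventories of real soils, phylogenetic signal in abundances (the
tree is independent of the taxonomy), compositional interactions beyond
closure, and temporal autocorrelation between stages. Passing recovery
tests therefore demonstrates that the pipeline recovers the structure this
model plants at realistic sizes and depths — not that real co-occurrence
edges imply ecological interaction, nor that real data meet these
assumptions.

## Validation strategy and problem sizes

The test suite validates each operation against independent oracles:
exhaustive permutation enumeration for Wilcoxon and Spearman p-values,
hand-enumerated branch sums for UniFrac, hypergeometric closed forms for
rarefaction, an explicit per-node hand count for Zi/Pi on ~1000 random
graphs, exhaustive partition enumeration for modularity on graphs of up to
8 nodes, and published arithmetic identities (avgK = 2E/N on the three
printed network sizes; the core-OTU percentage). Statistical calibration
uses 200 null generator draws (PERMANOVA and Wilcoxon type-I error) and
100 all-null 500-taxon tables (BH false-discovery control). Ground-truth
recovery runs the default 60 × 2000 design over 10 seeds; the
cross-validated biomarker selection inside that loop uses 2 repeats of
10-fold CV with 300 trees, sizes chosen to keep the whole suite
comfortably re-runnable while leaving the generator's study conditions at
their defaults.

## Known limitations

* The Spearman screen computes a dense correlation matrix; beyond ~10,000
  taxa memory becomes the binding constraint.
* Raw P < 0.01 edge screening at thousands of taxa admits a predictable
  background of spurious edges (≈1% of null pairs); the optional BH mode
  trades sensitivity for specificity.
* Compositional effects are not modelled away: normalized abundances are
  closed, and negative correlations induced by closure are not corrected
  (methods like SparCC/SPIEC-EASI are out of scope by design).
* PERMANOVA R² conflates location and dispersion effects, as always.
* The exact modularity mode is exponential-time in principle and intended
  for small graphs only.
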