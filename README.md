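# rhizonet

Downstream analysis of rhizosphere microbiome OTU tables from
continuous-monocropping (monoculture chronosequence) experiments, for
microbial ecologists who have already clustered their amplicon reads into
OTUs and want a tested, reproducible path from the count table to the
published-style results: diversity statistics, differential abundance,
random-forest biomarkers, and signed Spearman co-occurrence networks with
topological node roles.

The typical design the package targets is a sample grid of cropping-years
groups (a never-cropped control `CK` plus, e.g., 5, 10 and 20 years of
continuous monocropping) crossed with plant development stages
(transplanting, growth, harvest) and field replicates.

## What it computes

* **Table handling** — per-mille normalization (each count divided by its
  sample's sequencing depth × 1000), prevalence filtering (OTUs occurring
  in < 5% of samples removed; ties at the threshold retained), taxonomic
  aggregation, core/pan-OTU partitions across groups, and log2 fold
  changes `log2((mean_a + ε)/(mean_b + ε))`.
* **Diversity** — observed OTUs and Shannon entropy (−Σ pᵢ log₂ pᵢ) with
  seeded rarefaction curves and the hypergeometric closed form
  E[S] = Σᵢ (1 − C(N−Nᵢ, d)/C(N, d)); Faith's PD; Bray–Curtis and weighted
  UniFrac (Σ_b l_b |A_b − B_b|, optionally normalized by
  Σ_b l_b (A_b + B_b)); PCoA; PERMANOVA (pseudo-F, R², permutation p);
  RDA on soil properties.
* **Differential abundance** — Wilcoxon rank-sum per taxon on taxa whose
  median relative abundance exceeds 0.2% (2‰) in at least one group,
  Benjamini–Hochberg FDR at 0.05.
* **Biomarkers** — random-forest regression of taxon abundances against
  monocropping years, permutation-importance ranking, and 10-fold
  cross-validated recursive feature elimination to select a minimal
  biomarker set.
* **Co-occurrence networks** — all-pairs Spearman correlations (exact
  permutation p-values for n ≤ 9, t-approximation otherwise); edges
  require |ρ| ≥ 0.6 and P < 0.01 and carry their sign; topology summaries
  (avgK = 2E/N, avgCC, avgGD, modularity); modularity-based module
  detection; within-module degree Zᵢ = (k_is − k̄_s)/σ_s and participation
  coefficient Pᵢ = 1 − Σ_t (k_it/kᵢ)²; role classification at the
  customary thresholds (2.5, 0.62) into peripherals, connectors, module
  hubs and network hubs.
* **Synthetic data** — a seeded generator emulating the full 60-sample
  design with known ground truth (year-informative families, planted
  correlation modules via a Gaussian copula), plus `score_recovery()` to
  benchmark every stage against that truth.

## Worked example

```r
library(rhizonet)

ds  <- generate_dataset(synthetic_config(seed = 42))
ds$otu
#> otu_table: 60 samples x 2000 OTUs
#>   depth range: 52293 - 158667
#>   groups: CK, 5yrCC, 10yrCC, 20yrCC

rel <- prevalence_filter(normalize_per_mille(ds$otu))
rel
#> rel_abund (permille): 60 samples x 1982 taxa at rank 'otu'
#>   steps: normalize_per_mille -> prevalence_filter(0.05)

permanova(bray_curtis(rel), ds$otu$metadata$stage,
          n_permutations = 999, seed = 42)
#> PERMANOVA: pseudo-F = 2.440, R2 = 0.079, p = 0.001 (999 perms)

sel <- rel$metadata$group == "5yrCC"          # one cropping-system subset
sub <- rhizonet:::new_rel_abund(rel$values[sel, ], rel$taxonomy,
                                rel$metadata[sel, ], steps = "subset")
net  <- build_network(spearman_edge_screen(sub), taxonomy = rel$taxonomy)
part <- detect_modules(net, seed = 42)
topology_summary(net, part)
#> network topology: N=1886 E=21464 (+12965/-8499) avgK=22.761 avgCC=0.188
#>   avgGD=2.967 M=0.382 (16 modules)

roles <- classify_roles(zipi(net, part))
table(roles$category)
#>  peripheral   connector  module_hub network_hub
#>         308        1532          45           1

score_recovery(ds$truth, network = net, partition = part)
#> $edge_sensitivity  [1] 1
#> $edge_precision    [1] 1
#> $module_ari        [1] 1
```

Reading this output: the development stage explains ~8% of the
between-sample Bray–Curtis variance (significant at the permutation
floor); the 15-sample 5 yrCC subset yields a signed co-occurrence network
whose detected modules recover all three planted correlation modules
exactly (ARI = 1), with every planted intra-module pair screened in as an
edge.

`run_pipeline()` chains all stages from a YAML/list config with a global
seed, writing TSV/JSON/GraphML artifacts stamped with a config hash.

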