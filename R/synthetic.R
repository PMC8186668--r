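# Synthetic OTU-table generator with known ground truth, emulating a
# 4-group (CK/5/10/20 years of continuous monocropping) x 3-stage x
# 5-replicate rhizosphere design: latent log-normal abundances with group-
# and stage-dependent effects, planted equicorrelated taxon modules, and
# multinomial count sampling at realistic library depths.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the study design the package targets: 60 samples
#' (4 cropping-years groups x 3 development stages x 5 replicates), 2000
#' OTUs across 26 phyla (~260 families), library depths 50,000-160,000.
#' Ground-truth structure: `n_informative_families` families whose member
#' OTUs trend monotonically (on the log scale) with monocropping years, and
#' `n_modules` planted correlation modules imposed through a Gaussian
#' copula on the latent log-abundance noise.
#'
#' @param seed RNG seed driving every draw.
#' @param n_otus number of OTUs.
#' @param years named numeric vector of group -> monocropping years.
#' @param stages development-stage labels.
#' @param n_replicates replicates per group x stage cell.
#' @param depth_range inclusive range of library depths.
#' @param n_phyla,n_classes,n_orders,n_families,n_genera taxonomy breadth.
#' @param n_informative_families families carrying a years trend. Each
#'   informative family is drawn from the families with
#'   `informative_family_size` members, and all of its member OTUs share
#'   the family's slope (a family-level biomarker is a family whose members
#'   shift together).
#' @param informative_family_size inclusive member-count range from which
#'   informative families are drawn.
#' @param informative_slope absolute per-year slope on log abundance
#'   (default 0.08, i.e. about a 5-fold shift over 20 years; signs
#'   alternate between families).
#' @param stage_effect_sd SD of per-taxon stage offsets (log scale).
#' @param stage_responder_fraction fraction of taxa with stage offsets.
#' @param n_modules,module_size planted correlation modules.
#' @param rho_target latent pairwise correlation inside each module
#'   (in (0,1)).
#' @param base_log_mean_sd SD of baseline log abundances across taxa.
#' @param dispersion SD of the per-sample latent log-scale noise.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_otus = 2000,
                             years = c(CK = 0, "5yrCC" = 5, "10yrCC" = 10,
                                       "20yrCC" = 20),
                             stages = c("transplanting", "growth",
                                        "harvest"),
                             n_replicates = 5,
                             depth_range = c(50000, 160000),
                             n_phyla = 26, n_classes = 78, n_orders = 168,
                             n_families = 260, n_genera = 488,
                             n_informative_families = 5,
                             informative_family_size = c(4, 10),
                             informative_slope = 0.08,
                             stage_effect_sd = 0.5,
                             stage_responder_fraction = 0.3,
                             n_modules = 3, module_size = 12,
                             rho_target = 0.9,
                             base_log_mean_sd = 2, dispersion = 1) {
  stopifnot(rho_target > 0, rho_target < 1,
            n_modules * module_size <= n_otus,
            is.finite(informative_slope))
  structure(as.list(environment()), class = "synthetic_config")
}

# nested random taxonomy: phylum > class > order > family > genus, with a
# log-normal skew so a few phyla dominate (as in real 16S inventories)
.synthetic_taxonomy <- function(cfg) {
  lab <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  phyla <- lab("Phylum", cfg$n_phyla)
  class_parent <- sample(cfg$n_phyla, cfg$n_classes, replace = TRUE)
  order_parent <- sample(cfg$n_classes, cfg$n_orders, replace = TRUE)
  family_parent <- sample(cfg$n_orders, cfg$n_families, replace = TRUE)
  genus_parent <- sample(cfg$n_families, cfg$n_genera, replace = TRUE)
  fam_w <- exp(stats::rnorm(cfg$n_families))
  otu_family <- sample(cfg$n_families, cfg$n_otus, replace = TRUE,
                       prob = fam_w)
  otu_genus <- vapply(otu_family, function(f) {
    cand <- which(genus_parent == f)
    if (!length(cand)) NA_integer_ else cand[sample.int(length(cand), 1)]
  }, integer(1))
  genus_lab <- ifelse(is.na(otu_genus), UNCLASSIFIED,
                      lab("Genus", cfg$n_genera)[otu_genus])
  fam_lab <- lab("Family", cfg$n_families)[otu_family]
  ord_lab <- lab("Order", cfg$n_orders)[family_parent[otu_family]]
  cls_lab <- lab("Class", cfg$n_classes)[order_parent[
    family_parent[otu_family]]]
  phy_lab <- phyla[class_parent[order_parent[family_parent[otu_family]]]]
  data.frame(kingdom = "Bacteria", phylum = phy_lab, class = cls_lab,
             order = ord_lab, family = fam_lab, genus = genus_lab,
             species = UNCLASSIFIED, stringsAsFactors = FALSE)
}

#' Generate a synthetic dataset with known ground truth
#'
#' Latent log abundance of taxon o in sample s:
#' `mu_o + slope_o * years_s + stage_effect(stage_s, o) + eps_{s,o}`,
#' where `eps` is standard-normal noise scaled by `dispersion` and, inside
#' each planted module, equicorrelated at `rho_target` through a shared
#' Gaussian factor (`sqrt(rho) * f_s + sqrt(1 - rho) * iid`). Counts are
#' multinomial draws of the softmax composition at a depth sampled
#' uniformly from `depth_range`. Module members are placed on abundant,
#' stage-neutral, non-informative taxa so the planted correlation structure
#' is identifiable and disjoint from the years signal. A random coalescent
#' tree (exponential branch structure) over the OTUs and a soil-property
#' table with monotone-by-years trends plus noise are produced alongside.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset`: `otu` (an [otu_table]),
#'   `tree` (`phylo`), `soil` (data.frame), `truth` (class
#'   `synthetic_truth`: `informative` data.frame, `informative_families`,
#'   `modules` list, `module_map`, `expected_log` matrix, `depths`,
#'   `config`).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  cfg <- config
  withr::local_seed(cfg$seed)
  groups <- names(cfg$years)
  meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      stage = cfg$stages, group = groups,
                      stringsAsFactors = FALSE)[, 3:1]
  sample_ids <- sprintf("S%02d", seq_len(nrow(meta)))
  rownames(meta) <- sample_ids
  meta$compartment <- "rhizosphere"
  n_s <- nrow(meta)
  otu_ids <- sprintf("OTU%04d", seq_len(cfg$n_otus))

  taxonomy <- .synthetic_taxonomy(cfg)
  rownames(taxonomy) <- otu_ids

  mu <- stats::rnorm(cfg$n_otus, 0, cfg$base_log_mean_sd)

  # informative taxa: whole small families trend with years
  fams <- unique(taxonomy$family)
  fam_counts <- table(taxonomy$family)[fams]
  eligible <- fams[fam_counts >= cfg$informative_family_size[1] &
                   fam_counts <= cfg$informative_family_size[2] &
                   fams != UNCLASSIFIED]
  if (length(eligible) < cfg$n_informative_families)
    stop("not enough families in the informative size range")
  inf_fams <- sample(eligible, cfg$n_informative_families)
  slope <- numeric(cfg$n_otus)
  inf_rows <- integer(0)
  for (i in seq_along(inf_fams)) {
    members <- which(taxonomy$family == inf_fams[i])
    slope[members] <- cfg$informative_slope * (-1)^(i - 1)
    inf_rows <- c(inf_rows, members)
  }

  # stage responders (excluding informative taxa, so the two signals are
  # attributable)
  stage_eff <- matrix(0, length(cfg$stages), cfg$n_otus,
                      dimnames = list(cfg$stages, otu_ids))
  responders <- sample(setdiff(seq_len(cfg$n_otus), inf_rows),
                       round(cfg$stage_responder_fraction * cfg$n_otus))
  stage_eff[, responders] <- stats::rnorm(
    length(cfg$stages) * length(responders), 0, cfg$stage_effect_sd)

  # planted correlation modules on abundant, signal-free taxa
  free <- setdiff(seq_len(cfg$n_otus), c(inf_rows, responders))
  free <- free[order(mu[free], decreasing = TRUE)]
  pool <- free[seq_len(min(length(free), 4 * cfg$n_modules *
                             cfg$module_size))]
  picked <- sample(pool, cfg$n_modules * cfg$module_size)
  module_lab <- sprintf("module_%d", seq_len(cfg$n_modules))
  modules <- split(otu_ids[picked],
                   rep(module_lab, each = cfg$module_size))[module_lab]
  module_map <- stats::setNames(rep(module_lab, each = cfg$module_size),
                                otu_ids[picked])
  module_idx <- split(picked, rep(seq_len(cfg$n_modules),
                                  each = cfg$module_size))

  years_s <- cfg$years[meta$group]
  expected_log <- matrix(mu, n_s, cfg$n_otus, byrow = TRUE) +
    outer(years_s, slope) + stage_eff[meta$stage, , drop = FALSE]
  dimnames(expected_log) <- list(sample_ids, otu_ids)

  eps <- matrix(stats::rnorm(n_s * cfg$n_otus), n_s, cfg$n_otus)
  for (m in module_idx) {
    f <- stats::rnorm(n_s)
    eps[, m] <- sqrt(cfg$rho_target) * f +
      sqrt(1 - cfg$rho_target) * eps[, m]
  }
  latent <- expected_log + cfg$dispersion * eps

  depths <- sample(seq(cfg$depth_range[1], cfg$depth_range[2]), n_s,
                   replace = TRUE)
  counts <- t(vapply(seq_len(n_s), function(s) {
    p <- exp(latent[s, ] - max(latent[s, ]))
    as.numeric(stats::rmultinom(1, depths[s], p))
  }, numeric(cfg$n_otus)))
  dimnames(counts) <- list(sample_ids, otu_ids)

  tree <- ape::rcoal(cfg$n_otus, tip.label = otu_ids)

  soil <- .synthetic_soil(meta, years_s)

  truth <- structure(list(
    informative = data.frame(otu = otu_ids[inf_rows],
                             family = taxonomy$family[inf_rows],
                             slope = slope[inf_rows],
                             stringsAsFactors = FALSE),
    informative_families = inf_fams,
    modules = modules, module_map = module_map,
    expected_log = expected_log,
    depths = stats::setNames(depths, sample_ids),
    config = cfg), class = "synthetic_truth")

  structure(list(otu = otu_table(counts, taxonomy, meta), tree = tree,
                 soil = soil, truth = truth),
            class = "synthetic_dataset")
}

# soil-property table with monotone years trends plus noise (pH declines
# under monocropping; organic matter and major nutrients accumulate)
.synthetic_soil <- function(meta, years_s) {
  n <- nrow(meta)
  trend <- function(base, per_year, sd)
    base + per_year * years_s + stats::rnorm(n, 0, sd)
  stage_temp <- c(transplanting = 21, growth = 27, harvest = 18)
  data.frame(
    pH = trend(6.8, -0.05, 0.15),
    OM = trend(18, 0.5, 1.5),          # g/kg
    TN = trend(1.0, 0.03, 0.08),       # g/kg
    NO3N = trend(10, 0.6, 1.2),        # mg/kg
    AP = trend(15, 1.0, 2.0),          # mg/kg
    AK = trend(150, 5.5, 12),          # mg/kg
    temp = stage_temp[meta$stage] + stats::rnorm(n, 0, 1),
    row.names = rownames(meta))
}

#' Score how well the analyses recovered the planted ground truth
#'
#' @param truth a `synthetic_truth`.
#' @param network optional `cooc_network`; scores planted intra-module
#'   pairs: `edge_sensitivity` (fraction recovered as edges) and
#'   `edge_precision` (fraction of network edges between planted members
#'   that are true intra-module pairs).
#' @param partition optional `module_partition` of `network`; scored as the
#'   adjusted Rand index between detected modules and planted modules over
#'   the planted members present in the network.
#' @param biomarkers optional `rf_cv` (or character vector of selected
#'   taxa) at family level; scored as the fraction of informative families
#'   selected.
#' @param diffabund optional `diff_abund` at OTU level; scored as true/false
#'   positive rates against the informative-OTU list.
#' @return list of class `recovery_report` with the applicable scores.
#' @export
score_recovery <- function(truth, network = NULL, partition = NULL,
                           biomarkers = NULL, diffabund = NULL) {
  out <- list()
  if (!is.null(network)) {
    planted <- unlist(lapply(truth$modules, function(m) {
      pairs <- utils::combn(sort(m), 2)
      paste(pairs[1, ], pairs[2, ])
    }), use.names = FALSE)
    found <- paste(pmin(network$edges$otu_a, network$edges$otu_b),
                   pmax(network$edges$otu_a, network$edges$otu_b))
    members <- names(truth$module_map)
    both_in <- network$edges$otu_a %in% members &
      network$edges$otu_b %in% members
    out$edge_sensitivity <- mean(planted %in% found)
    out$edge_precision <- if (any(both_in))
      mean(found[both_in] %in% planted) else NA_real_
  }
  if (!is.null(partition)) {
    if (is.null(network))
      stop("scoring a partition requires the network it was computed on")
    nodes <- intersect(names(partition$membership),
                       names(truth$module_map))
    out$module_ari <- if (length(nodes) > 1)
      mclust::adjustedRandIndex(partition$membership[nodes],
                                truth$module_map[nodes])
    else NA_real_
    out$module_members_in_network <- length(nodes)
  }
  if (!is.null(biomarkers)) {
    selected <- if (is.character(biomarkers)) biomarkers else
      biomarkers$selected_taxa
    out$biomarker_recovery <- mean(truth$informative_families %in% selected)
    out$n_selected <- length(selected)
  }
  if (!is.null(diffabund)) {
    inf <- truth$informative$otu
    called <- diffabund$taxon[diffabund$significant]
    tested <- diffabund$taxon
    out$da_tpr <- if (any(tested %in% inf))
      mean(intersect(tested, inf) %in% called) else NA_real_
    null_tested <- setdiff(tested, inf)
    out$da_fpr <- if (length(null_tested))
      mean(null_tested %in% called) else NA_real_
  }
  structure(out, class = "recovery_report")
}
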