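# Config-driven orchestration: ingest -> normalize -> filter -> analysis
# stages, with deterministic seeded outputs and a provenance hash carried
# into every artifact.

default_pipeline_config <- function() {
  list(
    seed = 1,
    outdir = "rhizonet_out",
    synthetic = NULL,              # synthetic_config() args, or NULL
    counts = NULL, taxonomy = NULL, metadata = NULL, tree = NULL,
    soil = NULL,
    prevalence_min_fraction = 0.05,
    stages = list(diversity = TRUE, diffabund = TRUE, biomarkers = TRUE,
                  network = TRUE),
    diversity = list(n_permutations = 999),
    diffabund = list(median_threshold_permille = 2, alpha = 0.05),
    biomarkers = list(rank = "family", n_folds = 10, n_repeats = 5,
                      n_trees = 500),
    network = list(subsets = NULL,   # default: non-control groups
                   rho_min = 0.6, p_max = 0.01, min_occurrence = 3,
                   algorithm = "louvain"))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: ingest (from TSV paths or the synthetic
#' generator) -> per-mille normalization -> prevalence filter -> the
#' enabled analysis stages (alpha/beta diversity with PERMANOVA,
#' differential abundance per cropping group vs control, random-forest
#' biomarkers, and one co-occurrence network per cropping-system subset).
#' Every artifact is written under `outdir` and stamped with an MD5 hash of
#' the resolved configuration; a run log records parameters, seed and
#' per-stage wall time. Identical config + seed give byte-identical
#' outputs.
#'
#' @param config a named list overriding the defaults (see
#'   `rhizonet:::default_pipeline_config()`), or the path to a YAML file of
#'   the same shape. Set `config$synthetic` to a list of
#'   [synthetic_config()] arguments to run on generated data.
#' @return (invisibly) a list with the in-memory results of each stage and
#'   `outdir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config)
  # the hash identifies the analysis, not the run: output location excluded
  hash <- config_hash(cfg[setdiff(names(cfg), "outdir")])
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$outdir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  t0 <- Sys.time()
  logf <- function(...) {
    msg <- sprintf(...)
    writeLines(sprintf("[%7.2fs] %s",
                       as.numeric(Sys.time() - t0, units = "secs"), msg),
               log_con)
    message(msg)
  }
  logf("rhizonet %s | seed=%d | config hash %s",
       as.character(utils::packageVersion("rhizonet")), cfg$seed, hash)
  results <- list(config = cfg, hash = hash, outdir = cfg$outdir)

  # ingest
  if (!is.null(cfg$synthetic)) {
    sc_args <- cfg$synthetic
    if (is.null(sc_args$seed)) sc_args$seed <- cfg$seed
    ds <- generate_dataset(do.call(synthetic_config, sc_args))
    table <- ds$otu
    tree <- ds$tree
    soil <- ds$soil
    results$truth <- ds$truth
    logf("ingest: synthetic dataset, %d samples x %d OTUs",
         nrow(table$counts), ncol(table$counts))
  } else {
    table <- read_otu_table(cfg$counts, cfg$taxonomy, cfg$metadata)
    tree <- if (!is.null(cfg$tree)) ape::read.tree(cfg$tree) else NULL
    soil <- if (!is.null(cfg$soil))
      utils::read.delim(cfg$soil, row.names = 1) else NULL
    logf("ingest: %s, %d samples x %d OTUs", cfg$counts,
         nrow(table$counts), ncol(table$counts))
  }

  rel <- normalize_per_mille(table)
  rel <- prevalence_filter(rel, cfg$prevalence_min_fraction)
  table_f <- prevalence_filter(table, cfg$prevalence_min_fraction)
  logf("normalize + prevalence filter (>=%g): %d taxa retained",
       cfg$prevalence_min_fraction, ncol(rel$values))
  write_rel_abund(rel, file.path(cfg$outdir, "rel_abund_permille.tsv"))
  results$table <- table_f
  results$rel <- rel

  groups <- unique(table$metadata$group)
  ok <- TRUE

  run_stage <- function(name, fun) {
    if (!isTRUE(cfg$stages[[name]])) return(NULL)
    ts <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      ok <<- FALSE
      NULL
    })
    if (!is.null(res))
      logf("stage %s done in %.2fs", name,
           as.numeric(Sys.time() - ts, units = "secs"))
    res
  }

  results$diversity <- run_stage("diversity", function() {
    alpha <- data.frame(
      sample = rownames(table_f$counts),
      observed_otus = alpha_diversity(table_f$counts, "observed_otus"),
      shannon = alpha_diversity(table_f$counts, "shannon"))
    if (!is.null(tree))
      alpha$faith_pd <- faith_pd(table_f$counts, tree)
    utils::write.table(alpha, file.path(cfg$outdir, "alpha_diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dm <- bray_curtis(rel)
    ord <- pcoa(dm)
    coords <- cbind(sample = rownames(ord$coordinates),
                    as.data.frame(ord$coordinates[, 1:min(2,
                      ncol(ord$coordinates)), drop = FALSE]))
    utils::write.table(coords, file.path(cfg$outdir, "pcoa_braycurtis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    perm_group <- permanova(dm, table$metadata$group,
                            cfg$diversity$n_permutations, seed = cfg$seed)
    perm_stage <- permanova(dm, table$metadata$stage,
                            cfg$diversity$n_permutations, seed = cfg$seed)
    write_json_artifact(list(
      group = unclass(perm_group), stage = unclass(perm_stage)),
      file.path(cfg$outdir, "permanova.json"), hash)
    out <- list(alpha = alpha, bray = dm, pcoa = ord,
                permanova_group = perm_group, permanova_stage = perm_stage)
    if (!is.null(soil)) {
      out$rda <- rda_constrained(rel, soil)
      write_json_artifact(list(
        constrained_proportion = out$rda$constrained_proportion),
        file.path(cfg$outdir, "rda.json"), hash)
    }
    out
  })

  results$diffabund <- run_stage("diffabund", function() {
    ctrl <- if ("CK" %in% groups) "CK" else groups[1]
    comps <- lapply(setdiff(groups, ctrl), function(g) {
      da <- diff_abund_screen(rel, g, ctrl,
        median_threshold_permille = cfg$diffabund$median_threshold_permille,
        alpha = cfg$diffabund$alpha)
      write_diff_abund(da, file.path(cfg$outdir,
        sprintf("diffabund_%s_vs_%s.tsv", g, ctrl)))
      da
    })
    names(comps) <- setdiff(groups, ctrl)
    comps
  })

  results$biomarkers <- run_stage("biomarkers", function() {
    rel_rank <- aggregate_by_rank(rel, cfg$biomarkers$rank)
    yrs <- years_from_groups(table$metadata$group)
    cv <- cv_feature_selection(rel_rank, yrs,
                               n_folds = cfg$biomarkers$n_folds,
                               n_repeats = cfg$biomarkers$n_repeats,
                               n_trees = cfg$biomarkers$n_trees,
                               seed = cfg$seed)
    utils::write.table(cv$cv_curve,
                       file.path(cfg$outdir, "biomarker_cv_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep <- biomarker_report(cv, top_k = min(17, length(cv$fit$importance)))
    utils::write.table(rep, file.path(cfg$outdir, "biomarker_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_json_artifact(list(
      task = cv$fit$task, n_trees = cv$fit$n_trees,
      variance_explained = cv$fit$variance_explained,
      selected_n = cv$selected_n, selected_taxa = cv$selected_taxa),
      file.path(cfg$outdir, "biomarker_summary.json"), hash)
    cv
  })

  results$networks <- run_stage("network", function() {
    subsets <- cfg$network$subsets
    if (is.null(subsets))
      subsets <- setdiff(groups, "CK")
    nets <- lapply(subsets, function(g) {
      sel <- rel$metadata$group == g
      sub <- new_rel_abund(rel$values[sel, , drop = FALSE], rel$taxonomy,
                           rel$metadata[sel, , drop = FALSE],
                           steps = c(rel$provenance$steps,
                                     sprintf("subset(%s)", g)))
      edges <- spearman_edge_screen(sub, rho_min = cfg$network$rho_min,
                                    p_max = cfg$network$p_max,
                                    min_occurrence =
                                      cfg$network$min_occurrence)
      net <- build_network(edges, taxonomy = rel$taxonomy)
      if (igraph::vcount(net$graph) == 0) {
        logf("network %s: no edges survived the screen", g)
        return(list(network = net))
      }
      part <- detect_modules(net, algorithm = cfg$network$algorithm,
                             seed = cfg$seed)
      topo <- topology_summary(net, part)
      roles <- classify_roles(zipi(net, part))
      write_network(net, roles,
        edges_path = file.path(cfg$outdir,
                               sprintf("network_%s_edges.tsv", g)),
        roles_path = file.path(cfg$outdir,
                               sprintf("network_%s_roles.tsv", g)),
        graphml_path = file.path(cfg$outdir,
                                 sprintf("network_%s.graphml", g)))
      write_json_artifact(
        unclass(topo), file.path(cfg$outdir,
                                 sprintf("network_%s_topology.json", g)),
        hash)
      list(network = net, partition = part, topology = topo,
           roles = roles)
    })
    names(nets) <- subsets
    nets
  })

  logf("pipeline %s", if (ok) "completed" else "finished with failures")
  if (!ok) stop("one or more pipeline stages failed; see ", log_path)
  invisible(results)
}

# parse monocropping years out of group labels ("CK" -> 0, "5yrCC" -> 5)
years_from_groups <- function(groups) {
  y <- suppressWarnings(as.numeric(sub("[^0-9].*$", "", groups)))
  y[is.na(y)] <- 0
  y
}

write_json_artifact <- function(x, path, hash) {
  x$config_hash <- hash
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
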