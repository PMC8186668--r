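TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
UNCLASSIFIED <- "unclassified"

#' Construct a sample-by-OTU count table
#'
#' The central container of the package: an integer count matrix with samples
#' as rows and OTUs as columns, a 7-rank taxonomy per OTU, and per-sample
#' metadata describing the cropping-years group, development stage and
#' replicate.
#'
#' @param counts non-negative integer matrix, samples x OTUs, with complete
#'   dimnames.
#' @param taxonomy data.frame with one row per OTU (rownames = OTU ids) and
#'   the seven columns `kingdom` .. `species`; unresolved ranks must carry the
#'   literal marker `"unclassified"`.
#' @param metadata data.frame with one row per sample (rownames = sample ids)
#'   containing at least `group`, `stage` and `replicate`; a `compartment`
#'   column defaults to `"rhizosphere"`.
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `taxonomy`, `metadata`.
#' @export
otu_table <- function(counts, taxonomy, metadata) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample rownames and OTU colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in counts")
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative and complete")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  storage.mode(counts) <- "double"   # integer-valued; double avoids overflow

  taxonomy <- as.data.frame(taxonomy, stringsAsFactors = FALSE)
  if (!all(TAX_RANKS %in% colnames(taxonomy)))
    stop("taxonomy must have columns: ", paste(TAX_RANKS, collapse = ", "))
  taxonomy <- taxonomy[, TAX_RANKS, drop = FALSE]
  missing_tax <- setdiff(colnames(counts), rownames(taxonomy))
  if (length(missing_tax))
    stop("OTUs without taxonomy: ", paste(utils::head(missing_tax, 5),
                                          collapse = ", "))
  extra_tax <- setdiff(rownames(taxonomy), colnames(counts))
  if (length(extra_tax))
    stop("taxonomy rows with no OTU column: ",
         paste(utils::head(extra_tax, 5), collapse = ", "))
  taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
  if (any(!nzchar(as.matrix(taxonomy))) || any(is.na(taxonomy)))
    stop("taxonomy ranks must be non-empty; use the 'unclassified' marker")

  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  missing_md <- setdiff(rownames(counts), rownames(metadata))
  if (length(missing_md))
    stop("samples without metadata: ", paste(missing_md, collapse = ", "))
  metadata <- metadata[rownames(counts), , drop = FALSE]
  for (col in c("group", "stage", "replicate"))
    if (!col %in% colnames(metadata))
      stop("metadata must contain a '", col, "' column")
  if (!"compartment" %in% colnames(metadata))
    metadata$compartment <- "rhizosphere"

  depths <- rowSums(counts)
  if (any(depths <= 0))
    stop("zero-depth sample(s): ",
         paste(rownames(counts)[depths <= 0], collapse = ", "))

  structure(list(counts = counts, taxonomy = taxonomy, metadata = metadata),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  depth range: %d - %d\n",
              min(rowSums(x$counts)), max(rowSums(x$counts))))
  cat(sprintf("  groups: %s\n",
              paste(unique(x$metadata$group), collapse = ", ")))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Number of reads per sample
#' @param table an `otu_table`.
#' @return named numeric vector of per-sample read totals.
#' @export
sample_depths <- function(table) rowSums(table$counts)

#' Parse a semicolon-joined taxonomy lineage
#'
#' Accepts plain `"Bacteria;Proteobacteria;..."` strings as well as
#' QIIME-style `"k__Bacteria; p__Proteobacteria; ..."`. Empty or missing
#' ranks are replaced with the `"unclassified"` marker and the lineage is
#' padded (or truncated) to the seven canonical ranks.
#'
#' @param lineages character vector of lineage strings.
#' @return data.frame with the seven rank columns, one row per input.
#' @export
parse_lineage <- function(lineages) {
  parts <- strsplit(as.character(lineages), ";", fixed = TRUE)
  rows <- lapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("^[dkpcofgs]__", "", p)
    p <- trimws(p)
    p[!nzchar(p) | is.na(p)] <- UNCLASSIFIED
    length(p) <- 7L                      # pad with NA / truncate
    p[is.na(p)] <- UNCLASSIFIED
    p
  })
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(out) <- TAX_RANKS
  out
}

#' Read an OTU table from tab-separated files
#'
#' @param counts_path TSV of counts. Orientation (samples as rows vs OTUs as
#'   rows) is auto-detected by matching row/column names against the sample
#'   ids in the metadata file.
#' @param taxonomy_path TSV with OTU id in the first column and a
#'   semicolon-joined lineage in the second.
#' @param metadata_path TSV with sample id in the first column and columns
#'   `group`, `stage`, `replicate` (optionally `compartment`).
#' @return an [otu_table].
#' @export
read_otu_table <- function(counts_path, taxonomy_path, metadata_path) {
  metadata <- utils::read.delim(metadata_path, row.names = 1,
                                check.names = FALSE,
                                stringsAsFactors = FALSE)
  raw <- utils::read.delim(counts_path, row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  samples <- rownames(metadata)
  row_hits <- mean(rownames(m) %in% samples)
  col_hits <- mean(colnames(m) %in% samples)
  if (col_hits > row_hits) m <- t(m)        # OTUs were rows
  if (!all(rownames(m) %in% samples))
    stop("samples without metadata: ",
         paste(setdiff(rownames(m), samples), collapse = ", "))
  bad <- which(m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer count at sample '%s', OTU '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  tax_raw <- utils::read.delim(taxonomy_path, header = TRUE,
                               stringsAsFactors = FALSE)
  taxonomy <- parse_lineage(tax_raw[[2]])
  rownames(taxonomy) <- tax_raw[[1]]
  otu_table(m, taxonomy, metadata)
}

#' Write an OTU table to tab-separated files
#'
#' @param table an [otu_table].
#' @param counts_path,taxonomy_path,metadata_path output TSV paths.
#' @export
write_otu_table <- function(table, counts_path, taxonomy_path,
                            metadata_path) {
  write_tsv_matrix(table$counts, counts_path, id_col = "sample_id")
  tax <- data.frame(
    otu_id = rownames(table$taxonomy),
    lineage = apply(table$taxonomy, 1, paste, collapse = ";"))
  utils::write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  md <- cbind(sample_id = rownames(table$metadata), table$metadata)
  utils::write.table(md, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}

#' Per-mille relative-abundance normalization
#'
#' Each count is divided by its sample's total sequencing depth and
#' multiplied by 1000, so every row of the result sums to 1000 permille.
#'
#' @param table an [otu_table].
#' @return an object of class `rel_abund`: list with `values` (samples x
#'   taxa, permille), `taxonomy`, `metadata` and a `provenance` record of
#'   applied steps.
#' @export
normalize_per_mille <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  depths <- rowSums(table$counts)
  if (any(depths <= 0))
    stop("zero-depth sample(s): ",
         paste(rownames(table$counts)[depths <= 0], collapse = ", "))
  values <- table$counts / depths * 1000
  new_rel_abund(values, table$taxonomy, table$metadata,
                steps = "normalize_per_mille")
}

new_rel_abund <- function(values, taxonomy, metadata, steps,
                          rank = "otu") {
  structure(list(values = values, taxonomy = taxonomy, metadata = metadata,
                 provenance = list(steps = steps, rank = rank)),
            class = "rel_abund")
}

#' @export
print.rel_abund <- function(x, ...) {
  cat(sprintf("rel_abund (permille): %d samples x %d taxa at rank '%s'\n",
              nrow(x$values), ncol(x$values), x$provenance$rank))
  cat("  steps:", paste(x$provenance$steps, collapse = " -> "), "\n")
  invisible(x)
}

#' Prevalence filter
#'
#' Removes taxa occurring (count or abundance > 0) in strictly less than
#' `min_fraction` of the samples; taxa present in at least
#' `ceiling(min_fraction * n_samples)` samples are retained, so ties at
#' exactly the threshold survive. Column order is preserved. After filtering
#' a `rel_abund`, row sums may fall below 1000 permille; set `reclose = TRUE`
#' to re-normalize.
#'
#' @param table an [otu_table] or `rel_abund`.
#' @param min_fraction minimum fraction of samples (default 0.05).
#' @param reclose for `rel_abund` input, re-normalize rows to 1000 after
#'   dropping columns (default `FALSE`).
#' @return object of the same class as `table`.
#' @export
prevalence_filter <- function(table, min_fraction = 0.05, reclose = FALSE) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  m <- if (inherits(table, "otu_table")) table$counts else table$values
  need <- ceiling(min_fraction * nrow(m))
  keep <- colSums(m > 0) >= need
  if (!any(keep)) stop("prevalence filter removed every taxon")
  if (inherits(table, "otu_table")) {
    otu_table(table$counts[, keep, drop = FALSE],
              table$taxonomy[keep, , drop = FALSE], table$metadata)
  } else {
    values <- table$values[, keep, drop = FALSE]
    if (reclose) values <- values / rowSums(values) * 1000
    tax <- if (is.null(table$taxonomy)) NULL else
      table$taxonomy[keep, , drop = FALSE]
    new_rel_abund(values, tax, table$metadata,
                  steps = c(table$provenance$steps,
                            sprintf("prevalence_filter(%g)", min_fraction)),
                  rank = table$provenance$rank)
  }
}

#' Aggregate taxa to a higher taxonomic rank
#'
#' Columns sharing the same label at `rank` are summed; OTUs unclassified at
#' that rank are pooled into a single `"unclassified"` column. Row totals are
#' conserved exactly.
#'
#' @param table an [otu_table] or `rel_abund` at OTU level.
#' @param rank one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`.
#' @return object of the same class, columns indexed by rank labels.
#' @export
aggregate_by_rank <- function(table, rank) {
  if (!rank %in% TAX_RANKS[-1])
    stop("unknown rank '", rank, "'")
  tax <- table$taxonomy
  if (is.null(tax)) stop("table has no OTU-level taxonomy to aggregate")
  labels <- tax[[rank]]
  labels[labels == UNCLASSIFIED] <- UNCLASSIFIED
  m <- if (inherits(table, "otu_table")) table$counts else table$values
  agg <- t(rowsum(t(m), group = labels))  # samples x rank labels
  agg <- agg[, unique(labels), drop = FALSE]  # first-appearance order
  if (inherits(table, "otu_table")) {
    out <- table
    out$counts <- agg
    out$taxonomy <- NULL
    attr(out, "rank") <- rank
    out
  } else {
    new_rel_abund(agg, NULL, table$metadata,
                  steps = c(table$provenance$steps,
                            sprintf("aggregate_by_rank(%s)", rank)),
                  rank = rank)
  }
}

#' Core/pan OTU partition across groups
#'
#' An OTU is "present in a group" when it has a nonzero count in at least one
#' sample of that group. The core set is shared by all groups; every OTU is
#' also assigned to the exact subset of groups in which it occurs, so the
#' sizes of the disjoint presence patterns sum to the pan total.
#'
#' @param table an [otu_table].
#' @param grouping name of a metadata column (default `"group"`) or a named
#'   vector mapping sample id to a label.
#' @return list with `presence` (groups x OTUs logical), `core` (character),
#'   `patterns` (named list of OTU sets keyed by `"g1+g2"` patterns),
#'   `exclusive` (per-group private OTU sets), `n_core`, `n_pan` and
#'   `pct_core` (= 100 * n_core / n_pan, rounded to 2 decimals).
#' @export
core_pan_partition <- function(table, grouping = "group") {
  if (length(grouping) == 1 && is.character(grouping)) {
    labels <- table$metadata[[grouping]]
    if (is.null(labels)) stop("no metadata column '", grouping, "'")
    names(labels) <- rownames(table$metadata)
  } else {
    labels <- grouping[rownames(table$counts)]
  }
  groups <- sort(unique(labels))   # canonical order: sample-order invariant
  if (length(groups) < 2) stop("core/pan partition needs at least 2 groups")
  presence <- t(vapply(groups, function(g) {
    colSums(table$counts[labels == g, , drop = FALSE] > 0) > 0
  }, logical(ncol(table$counts))))
  rownames(presence) <- groups
  observed <- colSums(presence) > 0
  pattern <- apply(presence, 2, function(p) paste(groups[p], collapse = "+"))
  pattern <- pattern[observed]
  patterns <- split(names(pattern), pattern)
  core <- colnames(presence)[colSums(presence) == length(groups)]
  exclusive <- lapply(groups, function(g) {
    sel <- presence[g, ] & colSums(presence) == 1
    colnames(presence)[sel]
  })
  names(exclusive) <- groups
  n_pan <- sum(observed)
  list(presence = presence, core = core, patterns = patterns,
       exclusive = exclusive, n_core = length(core), n_pan = n_pan,
       pct_core = round(100 * length(core) / n_pan, 2))
}

#' Log2 fold change of group mean relative abundances
#'
#' `log2((mean_a + pseudo) / (mean_b + pseudo))` per taxon, the means taken
#' over the per-mille values of the samples in each group.
#'
#' @param rel a `rel_abund`.
#' @param group_a,group_b group labels (values of `metadata$group`).
#' @param pseudo pseudo-count in permille added to both means; default
#'   0.001 permille, the smallest nonzero abundance representable at a depth
#'   of one million reads.
#' @return named numeric vector, one value per taxon.
#' @export
log2_fold_change <- function(rel, group_a, group_b, pseudo = 0.001) {
  stopifnot(pseudo > 0)
  g <- rel$metadata$group
  a <- rel$values[g == group_a, , drop = FALSE]
  b <- rel$values[g == group_b, , drop = FALSE]
  if (nrow(a) == 0) stop("empty group '", group_a, "'")
  if (nrow(b) == 0) stop("empty group '", group_b, "'")
  log2((colMeans(a) + pseudo) / (colMeans(b) + pseudo))
}

#' Write a relative-abundance table as TSV with a provenance header
#'
#' @param rel a `rel_abund`.
#' @param path output path; the first line is a `#`-prefixed provenance
#'   comment.
#' @export
write_rel_abund <- function(rel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rhizonet rel_abund permille | rank=%s | steps=%s",
                     rel$provenance$rank,
                     paste(rel$provenance$steps, collapse = ";")), con)
  m <- cbind(sample_id = rownames(rel$values),
             as.data.frame(rel$values, check.names = FALSE))
  utils::write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rel)
}

write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- cbind(stats::setNames(data.frame(rownames(m)), id_col),
              as.data.frame(m, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
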