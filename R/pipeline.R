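#' Pipeline run configuration
#'
#' Bundles every threshold and mode of the end-to-end analysis. All
#' thresholds must be positive and `alpha` must lie in `(0, 1)`.
#'
#' @param ssp_threshold SSP length threshold (default 300).
#' @param identity Clustering identity threshold (default 0.70).
#' @param min_species Minimum species per kept cluster (default 3).
#' @param evalue Hit/similarity e-value cutoff (default `1e-5`).
#' @param alpha Significance level (default 0.01).
#' @param min_group_size Minimum species per lifestyle for group
#'   comparisons (default 5).
#' @param kdel_mode Retention-motif mode (see [scan_cterm_retention()]).
#' @param protease_mapping MEROPS endo/exo mapping.
#' @param grouping Lifestyle-to-group mapping for the four-set comparison.
#' @return A validated config list.
#' @export
pipeline_config <- function(ssp_threshold = 300L, identity = 0.70,
                            min_species = 3L, evalue = 1e-5, alpha = 0.01,
                            min_group_size = 5L, kdel_mode = "ps00014",
                            protease_mapping = default_protease_mapping(),
                            grouping = default_lifestyle_grouping()) {
  if (ssp_threshold < 1 || identity <= 0 || identity > 1 ||
      min_species < 1 || evalue <= 0 || min_group_size < 1) {
    stop("all pipeline thresholds must be positive (identity in (0, 1])")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  list(ssp_threshold = as.integer(ssp_threshold), identity = identity,
       min_species = as.integer(min_species), evalue = evalue,
       alpha = alpha, min_group_size = as.integer(min_group_size),
       kdel_mode = kdel_mode, protease_mapping = protease_mapping,
       grouping = grouping)
}

#' Per-species secretome summary
#'
#' @param decisions Decision table from [decide_secreted()] (with `ssp`).
#' @param annotations Annotation table from [annotate_secretome()].
#' @param proteins Full protein table (all species, secreted or not).
#' @param specific_ids Optional character vector of species-specific SSP
#'   ids (from [species_specific_ssps()]).
#' @return One row per species: `species`, `proteome_size`,
#'   `secretome_size`, `secretome_pct`, `ssp_count`, `specific_ssp_count`,
#'   and one count column per functional category.
#' @export
summarize_secretomes <- function(decisions, annotations, proteins,
                                 specific_ids = NULL) {
  sp <- sort(unique(proteins$species))
  if (anyNA(sp) || any(!nzchar(sp))) {
    stop("every protein must carry a species name")
  }
  dec_species <- proteins$species[match(decisions$protein_id,
                                        proteins$protein_id)]
  cats <- c("CAZyme", "Protease", "Lipase", "SSP", "Other")
  rows <- lapply(sp, function(s) {
    n <- sum(proteins$species == s)
    if (n == 0L) stop("species with zero proteins: ", s)
    d <- decisions[which(dec_species == s), , drop = FALSE]
    a <- annotations[annotations$species == s, , drop = FALSE]
    sec <- sum(d$secreted)
    cat_counts <- vapply(cats, function(cg) sum(a$category == cg), integer(1))
    names(cat_counts) <- paste0("n_", tolower(cats))
    cbind(data.frame(species = s, proteome_size = n, secretome_size = sec,
                     secretome_pct = 100 * sec / n,
                     ssp_count = sum(d$ssp),
                     specific_ssp_count = if (is.null(specific_ids))
                       NA_integer_ else
                       sum(d$protein_id[d$ssp] %in% specific_ids),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(cat_counts)))
  })
  .rbind_df(rows)
}

#' Run the full secretome comparison pipeline
#'
#' Executes predict -> annotate -> cluster -> compare: applies the
#' combined secretion decision rule, annotates the predicted secretome,
#' detects species-specific SSPs, clusters SSPs by identity, keeps
#' clusters spanning enough species, partitions them by lifestyle,
#' computes Venn-region counts, per-group PFAM enrichment, per-species
#' summaries, SSP-proportion comparisons and size correlations. The run is
#' fully deterministic for fixed inputs.
#'
#' @param proteins Protein table (all species).
#' @param evidence Evidence table matching the proteins.
#' @param registry Species registry covering every species in `proteins`.
#' @param hits Optional reference hit table.
#' @param config Settings from [pipeline_config()].
#' @return An object of class `secretome_run`: a list with `decisions`,
#'   `annotations`, `summary`, `specific_ssps`, `clustering`,
#'   `filtered_clusters`, `profiles`, `venn`, `enrichment` (per group),
#'   `proportion_stats` (or `NULL` when too few qualifying lifestyles),
#'   `size_correlation` and the `config` used.
#' @export
run_secretome_pipeline <- function(proteins, evidence, registry,
                                   hits = NULL,
                                   config = pipeline_config()) {
  unknown <- setdiff(unique(proteins$species), registry$name)
  if (length(unknown)) {
    stop("prediction stage: species absent from registry: ",
         paste(unknown, collapse = ", "))
  }
  decisions <- decide_secreted(
    evidence, proteins,
    secretion_config(kdel_mode = config$kdel_mode,
                     ssp_threshold = config$ssp_threshold))
  annotations <- annotate_secretome(
    decisions, proteins, hits, evalue_cutoff = config$evalue,
    protease_mapping = config$protease_mapping)
  ssp_ids <- decisions$protein_id[decisions$ssp]
  ssps <- proteins[match(ssp_ids, proteins$protein_id), , drop = FALSE]
  specific <- if (nrow(ssps) && length(unique(ssps$species)) >= 2) {
    species_specific_ssps(ssps, evalue_cutoff = config$evalue)
  } else {
    ssps$protein_id
  }
  clustering <- greedy_cluster(ssps, threshold = config$identity)
  filtered <- filter_clusters(clustering, min_species = config$min_species)
  profiles <- lifestyle_profiles(filtered, registry, config$grouping)
  venn <- if (is.null(profiles)) {
    data.frame(region = character(), n_clusters = integer(),
               stringsAsFactors = FALSE)
  } else {
    venn_partition(profiles)
  }
  summary <- summarize_secretomes(decisions, annotations, proteins,
                                  specific_ids = specific)
  groups <- setdiff(unique(unname(
    config$grouping[registry$lifestyle[match(summary$species,
                                             registry$name)]])), NA)
  focal_groups <- setdiff(groups, "other")
  enrichment <- lapply(focal_groups, function(g) {
    tryCatch(pfam_enrichment(annotations, registry, g,
                             grouping = config$grouping,
                             alpha = config$alpha),
             error = function(e) NULL)
  })
  names(enrichment) <- focal_groups
  proportion_stats <- tryCatch(
    ssp_proportion_stats(summary, registry,
                         min_group_size = config$min_group_size,
                         alpha = config$alpha),
    error = function(e) NULL)
  structure(list(decisions = decisions, annotations = annotations,
                 summary = summary, specific_ssps = specific,
                 clustering = clustering, filtered_clusters = filtered,
                 profiles = profiles, venn = venn, enrichment = enrichment,
                 proportion_stats = proportion_stats,
                 size_correlation = size_correlation(summary, registry),
                 config = config),
            class = "secretome_run")
}

#' @export
print.secretome_run <- function(x, ...) {
  cat("Secretome pipeline run\n")
  cat("  species:          ", nrow(x$summary), "\n")
  cat("  proteins:         ", sum(x$summary$proteome_size), "\n")
  cat("  secreted:         ", sum(x$summary$secretome_size), "\n")
  cat("  SSPs:             ", sum(x$summary$ssp_count), "\n")
  cat("  SSP clusters:     ", nrow(x$clustering$clusters),
      sprintf("(%d spanning >= %d species)\n",
              nrow(x$filtered_clusters$clusters), x$config$min_species))
  invisible(x)
}

#' Write a result table as TSV with a metadata header
#'
#' Every output table declares the thresholds it was produced under as
#' `#`-prefixed header lines, so a table re-read with [read_output_tsv()]
#' recovers the numbers exactly and carries its provenance.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param params Named list of settings to record in the header.
#' @return `path`, invisibly.
#' @export
write_output_tsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(params)) {
    writeLines(sprintf("# %s: %s", k, paste(params[[k]], collapse = ",")),
               con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_output_tsv()]
#'
#' @param path Path to the table.
#' @return The data.frame (header metadata lines are skipped).
#' @export
read_output_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
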