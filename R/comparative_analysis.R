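#' Default lifestyle-to-group mapping for the four-group comparison
#'
#' Maps registry lifestyles onto the four comparison groups: `ECM`
#' (ectomycorrhizal), `white_rot`, `brown_rot` and `litter_decayer`
#' (soil/litter decayers). All remaining lifestyles (orchid and ericoid
#' symbionts, endophytes, pathogens, mycoparasites, yeasts) map to
#' `other` and are outside the four-set comparison.
#'
#' @return Named character vector: lifestyle -> group.
#' @export
default_lifestyle_grouping <- function() {
  g <- setNames(rep("other", length(lifestyle_labels())), lifestyle_labels())
  g["Ectomycorrhizal"] <- "ECM"
  g["White rot"] <- "white_rot"
  g["Brown rot"] <- "brown_rot"
  g["Litter decayers"] <- "litter_decayer"
  g
}

#' Saprotrophic comparison groups
#'
#' @return The group labels counted as saprotrophic (white rot, brown rot,
#'   litter decayers).
#' @export
saprotroph_groups <- function() c("white_rot", "brown_rot", "litter_decayer")

#' Lifestyle profile of one SSP cluster
#'
#' Maps a cluster's member species to lifestyle groups and derives the
#' cluster's specificity: `ECM_only` when every member is ectomycorrhizal;
#' `saprotroph_only` when all members fall in saprotrophic groups;
#' `shared_ECM_saprotroph` when ECM members co-occur exclusively with
#' saprotrophic members; `other` in every remaining case (including any
#' member outside the declared groups).
#'
#' @param member_species Character vector of member species names.
#' @param registry Species registry.
#' @param grouping Named vector lifestyle -> group (default
#'   [default_lifestyle_grouping()]).
#' @return A list with `lifestyles` (sorted group set, including `other`
#'   when present), `region` (sorted group set restricted to the declared
#'   non-`other` groups) and `specificity`.
#' @export
lifestyle_profile <- function(member_species, registry,
                              grouping = default_lifestyle_grouping()) {
  idx <- match(member_species, registry$name)
  if (anyNA(idx)) {
    stop("cluster member species absent from registry: ",
         paste(member_species[is.na(idx)], collapse = ", "))
  }
  groups <- unname(grouping[registry$lifestyle[idx]])
  groups[is.na(groups)] <- "other"
  ls <- sort(unique(groups))
  region <- setdiff(ls, "other")
  sap <- saprotroph_groups()
  specificity <- if (identical(ls, "ECM")) {
    "ECM_only"
  } else if (length(ls) && all(ls %in% sap)) {
    "saprotroph_only"
  } else if ("ECM" %in% ls && length(setdiff(ls, "ECM")) &&
             all(setdiff(ls, "ECM") %in% sap)) {
    "shared_ECM_saprotroph"
  } else {
    "other"
  }
  list(lifestyles = ls, region = region, specificity = specificity)
}

#' Lifestyle profiles for a set of clusters
#'
#' @param clusters Either an `ssp_clusters` object ([greedy_cluster()]) or
#'   a data.frame with `cluster_id` and a list-column `members` of species
#'   names (the packaged fixture layout, [load_cluster_fixture()]).
#' @param registry Species registry.
#' @param grouping Named vector lifestyle -> group.
#' @return data.frame: `cluster_id`, `lifestyles` (joined with `+`),
#'   `region` (joined with `+`), `specificity`.
#' @export
lifestyle_profiles <- function(clusters, registry,
                               grouping = default_lifestyle_grouping()) {
  if (inherits(clusters, "ssp_clusters")) {
    ids <- clusters$clusters$cluster_id
    member_sets <- lapply(ids, function(cid) {
      clusters$members$species[clusters$members$cluster_id == cid]
    })
  } else {
    ids <- clusters$cluster_id
    member_sets <- clusters$members
  }
  rows <- lapply(seq_along(ids), function(i) {
    p <- lifestyle_profile(member_sets[[i]], registry, grouping)
    data.frame(cluster_id = ids[i],
               lifestyles = paste(p$lifestyles, collapse = "+"),
               region = paste(p$region, collapse = "+"),
               specificity = p$specificity, stringsAsFactors = FALSE)
  })
  .rbind_df(rows)
}

#' Venn-region counts of cluster lifestyle profiles
#'
#' Counts each profile in exactly one region, keyed by the sorted set of
#' declared groups with at least one member species. Profiles with no
#' member in any declared group (empty region) are excluded from the
#' counts.
#'
#' @param profiles Profile table from [lifestyle_profiles()].
#' @return data.frame with `region` and `n_clusters`, sorted by
#'   decreasing count.
#' @export
venn_partition <- function(profiles) {
  r <- profiles$region[nzchar(profiles$region)]
  tab <- sort(table(r), decreasing = TRUE)
  data.frame(region = names(tab), n_clusters = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' One-sided enrichment p-value for a 2x2 table
#'
#' Upper-tail probability (one-sided Fisher exact test) that the
#' in-lifestyle domain count is at least `a`, for the table
#' `(a, b; c, d)` = (in-lifestyle with/without domain; elsewhere
#' with/without domain), computed as a hypergeometric tail. Degenerate
#' tables with a zero margin return 1.
#'
#' @param a,b,c,d Non-negative integer cell counts (vectorized).
#' @return Numeric vector of p-values.
#' @export
enrichment_pvalue <- function(a, b, c, d) {
  n1 <- a + b
  k <- a + c
  n <- a + b + c + d
  p <- phyper(a - 1, k, n - k, n1, lower.tail = FALSE)
  p[n1 == 0 | k == 0 | n1 == n | k == n] <- 1
  pmin(pmax(p, 0), 1)
}

#' PFAM domain enrichment in one lifestyle's secretomes
#'
#' For every PFAM accession, tests over-representation among secreted
#' proteins of the focal lifestyle group against secreted proteins of all
#' other groups (one-sided Fisher exact test on the 2x2 presence table),
#' with step-down (Holm) multiple-testing adjustment. The counting unit is
#' the secreted protein.
#'
#' @param annotations Annotation table from [annotate_secretome()]
#'   (columns `species` and `pfam_domains`).
#' @param registry Species registry.
#' @param lifestyle Focal group label (under `grouping`).
#' @param grouping Named vector lifestyle -> group.
#' @param alpha Significance level on adjusted p-values (default 0.01).
#' @param min_count Minimum number of proteins carrying the domain overall
#'   for it to be tested (default 2).
#' @param adjust Multiple-testing method (default `"holm"`).
#' @return data.frame with one row per tested accession: `lifestyle`,
#'   `pfam`, counts `a`, `b`, `c`, `d`, `p_value`, `adjusted_p`,
#'   `enriched`; sorted by adjusted then raw p-value.
#' @export
pfam_enrichment <- function(annotations, registry, lifestyle,
                            grouping = default_lifestyle_grouping(),
                            alpha = 0.01, min_count = 2L, adjust = "holm") {
  grp <- unname(grouping[registry$lifestyle[
    match(annotations$species, registry$name)]])
  if (!any(grp == lifestyle, na.rm = TRUE)) {
    stop("no secreted proteins belong to lifestyle group '", lifestyle, "'")
  }
  in_ls <- !is.na(grp) & grp == lifestyle
  doms <- strsplit(annotations$pfam_domains, ";", fixed = TRUE)
  doms <- lapply(doms, function(d) unique(d[nzchar(d)]))
  all_doms <- sort(unique(unlist(doms)))
  if (!length(all_doms)) {
    return(data.frame(lifestyle = character(), pfam = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), p_value = numeric(),
                      adjusted_p = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  n_in <- sum(in_ls)
  n_out <- sum(!in_ls)
  rows <- lapply(all_doms, function(dm) {
    has <- vapply(doms, function(d) dm %in% d, logical(1))
    if (sum(has) < min_count) return(NULL)
    a <- sum(has & in_ls)
    c <- sum(has & !in_ls)
    data.frame(lifestyle = lifestyle, pfam = dm, a = a, b = n_in - a,
               c = c, d = n_out - c,
               p_value = enrichment_pvalue(a, n_in - a, c, n_out - c),
               stringsAsFactors = FALSE)
  })
  out <- .rbind_df(rows)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(lifestyle = character(), pfam = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), p_value = numeric(),
                      adjusted_p = numeric(), enriched = logical(),
                      stringsAsFactors = FALSE))
  }
  out$adjusted_p <- p.adjust(out$p_value, method = adjust)
  out$enriched <- out$adjusted_p < alpha
  out[order(out$adjusted_p, out$p_value, out$pfam), , drop = FALSE]
}

## Compact letter display: groups sharing a letter are not significantly
## different. Letters are the maximal cliques of the "not different" graph.
.significance_letters <- function(pmat, groups, alpha) {
  k <- length(groups)
  adj <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    p <- NA
    if (groups[i] %in% rownames(pmat) && groups[j] %in% colnames(pmat)) {
      p <- pmat[groups[i], groups[j]]
    }
    if (is.na(p) && groups[j] %in% rownames(pmat) &&
        groups[i] %in% colnames(pmat)) {
      p <- pmat[groups[j], groups[i]]
    }
    if (!is.na(p) && p < alpha) adj[i, j] <- FALSE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  ## stable order: by smallest member index
  cliques <- cliques[order(vapply(cliques, min, numeric(1)))]
  letters_out <- setNames(rep("", k), groups)
  for (ci in seq_along(cliques)) {
    for (v in cliques[[ci]]) {
      letters_out[v] <- paste0(letters_out[v], letters[ci])
    }
  }
  letters_out
}

#' Compare SSP proportions across lifestyles
#'
#' Computes, per species, the percentage of SSPs in the secretome and the
#' percentage of species-specific SSPs, then compares lifestyles that
#' contain at least `min_group_size` species with pairwise two-sample
#' t-tests and pairwise Wilcoxon rank-sum tests, both with Holm
#' correction, and assigns compact significance letters at `alpha`
#' (from the t-tests; groups sharing a letter do not differ).
#'
#' @param summaries Per-species summary table from
#'   [summarize_secretomes()] (columns `species`, `secretome_size`,
#'   `ssp_count`, `specific_ssp_count`).
#' @param registry Species registry.
#' @param metric Which percentage to compare: `"ssp_pct"` (SSPs as % of
#'   secretome, default) or `"specific_ssp_pct"`.
#' @param min_group_size Minimum species per lifestyle (default 5).
#' @param alpha Significance level (default 0.01).
#' @return A list with `values` (per-species percentages and lifestyle),
#'   `t_pvalues` and `wilcox_pvalues` (Holm-adjusted lower-triangular
#'   matrices), and `letters`.
#' @export
ssp_proportion_stats <- function(summaries, registry, metric = "ssp_pct",
                                 min_group_size = 5L, alpha = 0.01) {
  v <- summaries
  v$lifestyle <- registry$lifestyle[match(v$species, registry$name)]
  v$ssp_pct <- 100 * v$ssp_count / v$secretome_size
  if (!is.null(v$specific_ssp_count)) {
    v$specific_ssp_pct <- 100 * v$specific_ssp_count / v$secretome_size
  }
  sizes <- table(v$lifestyle)
  qualifying <- names(sizes)[sizes >= min_group_size]
  if (length(qualifying) < 2L) {
    stop("fewer than two lifestyles contain at least ", min_group_size,
         " species")
  }
  vq <- v[v$lifestyle %in% qualifying, , drop = FALSE]
  x <- vq[[metric]]
  g <- factor(vq$lifestyle, levels = qualifying)
  tt <- suppressWarnings(pairwise.t.test(x, g, p.adjust.method = "holm",
                                         pool.sd = FALSE))
  wt <- suppressWarnings(pairwise.wilcox.test(x, g,
                                              p.adjust.method = "holm",
                                              exact = FALSE))
  list(values = vq[, c("species", "lifestyle", metric)],
       t_pvalues = tt$p.value, wilcox_pvalues = wt$p.value,
       letters = .significance_letters(tt$p.value, qualifying, alpha),
       metric = metric, alpha = alpha)
}

#' Secretome-size versus proteome-size correlation per lifestyle
#'
#' Pearson correlation of secretome size against proteome size within each
#' lifestyle having at least `min_species` species. Zero-variance groups
#' yield `NA`.
#'
#' @param summaries Per-species summary table (columns `species`,
#'   `proteome_size`, `secretome_size`).
#' @param registry Species registry.
#' @param min_species Minimum species per lifestyle (default 3).
#' @return data.frame: `lifestyle`, `n`, `r`, `r_squared`.
#' @export
size_correlation <- function(summaries, registry, min_species = 3L) {
  ls <- registry$lifestyle[match(summaries$species, registry$name)]
  rows <- lapply(sort(unique(ls)), function(l) {
    s <- summaries[which(ls == l), , drop = FALSE]
    if (nrow(s) < min_species) return(NULL)
    r <- if (stats::sd(s$proteome_size) == 0 ||
             stats::sd(s$secretome_size) == 0) NA_real_ else {
      cor(s$proteome_size, s$secretome_size)
    }
    data.frame(lifestyle = l, n = nrow(s), r = r, r_squared = r^2,
               stringsAsFactors = FALSE)
  })
  out <- .rbind_df(rows)
  if (is.null(out)) {
    out <- data.frame(lifestyle = character(), n = integer(), r = numeric(),
                      r_squared = numeric(), stringsAsFactors = FALSE)
  }
  out
}
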