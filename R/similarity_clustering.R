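#' Scoring settings for pairwise identity
#'
#' Global alignment under a substitution matrix with affine gaps
#' (defaults: BLOSUM62, gap open 10, gap extend 1). Identity is the number
#' of identical aligned residue pairs divided by the chosen denominator:
#' the length of the shorter sequence (the incremental-clustering tool
#' convention, default) or the alignment length. The ambiguity residue X
#' never counts as a match.
#'
#' @param matrix Substitution matrix name (a matrix shipped with
#'   Biostrings) or an actual matrix.
#' @param gap_open,gap_extend Affine gap penalties (non-negative).
#' @param denominator `"shorter"` (default) or `"alignment"`.
#' @return A named list of settings.
#' @export
identity_scoring <- function(matrix = "BLOSUM62", gap_open = 10,
                             gap_extend = 1,
                             denominator = c("shorter", "alignment")) {
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
       denominator = match.arg(denominator))
}

## Substitution matrices fetched by name are cached after the first lookup.
.submat_cache <- new.env(parent = emptyenv())

.get_submat <- function(m) {
  if (is.matrix(m)) return(m)
  if (!exists(m, envir = .submat_cache)) {
    e <- new.env()
    utils::data(list = m, package = "Biostrings", envir = e)
    assign(m, get(m, envir = e), envir = .submat_cache)
  }
  get(m, envir = .submat_cache)
}

## Aligns many patterns against one subject, returns identity fractions.
## nmatch() counts identical aligned pairs; aligned X:X pairs (which must
## not count as identities) are subtracted via the slower aligned-string
## path only for the rare pairs where both sequences contain X.
.identity_to_one <- function(seqs, subject, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(seqs),
    subject = Biostrings::AAString(subject),
    substitutionMatrix = .get_submat(scoring$matrix),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global")
  matches <- Biostrings::nmatch(aln)
  bothx <- which(grepl("X", seqs, fixed = TRUE) &
                   grepl("X", subject, fixed = TRUE))
  if (length(bothx)) {
    p <- as.character(Biostrings::alignedPattern(aln[bothx]))
    s <- as.character(Biostrings::alignedSubject(aln[bothx]))
    xx <- mapply(function(a, b) {
      ac <- strsplit(a, "")[[1]]
      bc <- strsplit(b, "")[[1]]
      sum(ac == "X" & bc == "X")
    }, p, s, USE.NAMES = FALSE)
    matches[bothx] <- matches[bothx] - xx
  }
  denom <- switch(scoring$denominator,
                  shorter = pmin(nchar(seqs), nchar(subject)),
                  alignment = nchar(aln))
  list(matches = as.integer(matches), denominator = as.integer(denom),
       identity = matches / denom)
}

#' Global pairwise sequence identity
#'
#' @param a,b Amino-acid sequences (non-empty).
#' @param scoring Settings from [identity_scoring()].
#' @return A list with `identity` (in `[0, 1]`), `aligned_matches` and
#'   `denominator`.
#' @export
global_identity <- function(a, b, scoring = identity_scoring()) {
  if (!nzchar(a) || !nzchar(b)) {
    stop("global_identity requires non-empty sequences")
  }
  r <- .identity_to_one(a, b, scoring)
  list(identity = r$identity[1], aligned_matches = r$matches[1],
       denominator = r$denominator[1])
}

#' Greedy incremental clustering of SSPs by sequence identity
#'
#' Sequences are sorted by decreasing length (ties broken by protein
#' identifier) and processed in order: each sequence joins the
#' earliest-created cluster whose representative it matches at identity at
#' or above the threshold, otherwise it founds a new cluster with itself
#' as representative. Because of the sort, every representative is a
#' longest member of its cluster. Cluster ids number the clusters in
#' creation order starting from 0. The documented sort and tie-breaks make
#' the result invariant to the input order.
#'
#' @param proteins Protein table with `protein_id`, `species`, `sequence`,
#'   `length`.
#' @param threshold Identity threshold in `(0, 1]` (default 0.70; a
#'   sequence joins on identity `>= threshold`).
#' @param scoring Settings from [identity_scoring()].
#' @return An object of class `ssp_clusters`: a list with `members` (one
#'   row per input protein: `cluster_id`, `protein_id`, `species`,
#'   `length`, `identity_to_representative`) and `clusters` (one row per
#'   cluster: `cluster_id`, `representative`, `n_members`, `n_species`,
#'   `length_min`, `length_max`), plus the threshold used.
#' @export
greedy_cluster <- function(proteins, threshold = 0.70,
                           scoring = identity_scoring()) {
  stopifnot(threshold > 0, threshold <= 1)
  p <- proteins[order(-proteins$length, proteins$protein_id), , drop = FALSE]
  n <- nrow(p)
  rep_seq <- character(0)
  rep_id <- character(0)
  assign <- integer(n)
  ident <- numeric(n)
  for (i in seq_len(n)) {
    hit <- 0L
    if (length(rep_seq)) {
      r <- .identity_to_one(rep_seq, p$sequence[i], scoring)
      ok <- which(r$identity >= threshold)
      if (length(ok)) {
        hit <- ok[1]
        ident[i] <- r$identity[hit]
      }
    }
    if (hit == 0L) {
      rep_seq <- c(rep_seq, p$sequence[i])
      rep_id <- c(rep_id, p$protein_id[i])
      hit <- length(rep_seq)
      ident[i] <- 1
    }
    assign[i] <- hit - 1L
  }
  members <- data.frame(cluster_id = assign,
                        protein_id = p$protein_id,
                        species = p$species,
                        length = p$length,
                        identity_to_representative = ident,
                        stringsAsFactors = FALSE)
  clusters <- do.call(rbind, lapply(sort(unique(assign)), function(cid) {
    m <- members[members$cluster_id == cid, , drop = FALSE]
    data.frame(cluster_id = cid, representative = rep_id[cid + 1L],
               n_members = nrow(m),
               n_species = length(unique(m$species)),
               length_min = min(m$length), length_max = max(m$length),
               stringsAsFactors = FALSE)
  }))
  if (is.null(clusters)) {
    clusters <- data.frame(cluster_id = integer(), representative = character(),
                           n_members = integer(), n_species = integer(),
                           length_min = integer(), length_max = integer(),
                           stringsAsFactors = FALSE)
  }
  structure(list(members = members, clusters = clusters,
                 threshold = threshold),
            class = "ssp_clusters")
}

#' @export
print.ssp_clusters <- function(x, ...) {
  cat("SSP clustering:", nrow(x$members), "proteins in",
      nrow(x$clusters), "clusters (identity threshold",
      x$threshold, ")\n")
  invisible(x)
}

#' Keep clusters spanning a minimum number of species
#'
#' @param clustering An `ssp_clusters` object from [greedy_cluster()], or a
#'   cluster summary data.frame with an `n_species` column.
#' @param min_species Minimum number of distinct member species
#'   (default 3).
#' @return The same type as the input, restricted to qualifying clusters;
#'   cluster ids are preserved.
#' @export
filter_clusters <- function(clustering, min_species = 3L) {
  if (inherits(clustering, "ssp_clusters")) {
    keep <- clustering$clusters$cluster_id[
      clustering$clusters$n_species >= min_species]
    clustering$clusters <- clustering$clusters[
      clustering$clusters$cluster_id %in% keep, , drop = FALSE]
    clustering$members <- clustering$members[
      clustering$members$cluster_id %in% keep, , drop = FALSE]
    return(clustering)
  }
  clustering[clustering$n_species >= min_species, , drop = FALSE]
}

## Karlin-Altschul parameters for gapped BLOSUM62 scoring, used to turn a
## raw local-alignment score into bits and an e-value bound.
.ka_lambda <- 0.267
.ka_K <- 0.041

#' Detect species-specific SSPs
#'
#' An SSP is species-specific when it has no sufficiently strong local
#' alignment to any SSP of a different species. Strength is judged by a
#' Karlin-Altschul bit score: a raw Smith-Waterman score `S` under BLOSUM62
#' converts to `bits = (lambda * S - ln K) / ln 2`, and a pair is a hit
#' when its e-value `m * n * 2^-bits` is at or below the cutoff, where `m`
#' is the query length and `n` the total residue count of the
#' other-species SSPs. This plays the role a heuristic similarity search
#' would in a database-scale analysis; intra-species hits are ignored.
#'
#' @param proteins SSP protein table (`protein_id`, `species`, `sequence`,
#'   `length`).
#' @param evalue_cutoff E-value cutoff (default `1e-5`).
#' @param scoring Settings from [identity_scoring()] (matrix and gap
#'   penalties; the denominator is not used).
#' @return Character vector of species-specific protein ids.
#' @export
species_specific_ssps <- function(proteins, evalue_cutoff = 1e-5,
                                  scoring = identity_scoring()) {
  if (length(unique(proteins$species)) < 2L) {
    warning("single-species input: every SSP is trivially species-specific")
    return(proteins$protein_id)
  }
  specific <- logical(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    others <- proteins[proteins$species != proteins$species[i], , drop = FALSE]
    scores <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(others$sequence),
      subject = Biostrings::AAString(proteins$sequence[i]),
      substitutionMatrix = .get_submat(scoring$matrix),
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
      type = "local", scoreOnly = TRUE)
    bits <- (.ka_lambda * scores - log(.ka_K)) / log(2)
    evalues <- proteins$length[i] * sum(others$length) * 2^(-bits)
    specific[i] <- all(evalues > evalue_cutoff)
  }
  proteins$protein_id[specific]
}
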