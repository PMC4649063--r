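#' @importFrom stats cor fisher.test p.adjust pairwise.t.test pairwise.wilcox.test phyper setNames
#' @importFrom utils read.delim write.table head
NULL

## rbind a list of one-row data.frames, tolerating an all-empty list
## (plain do.call(rbind, ...) would degenerate there).
.rbind_df <- function(rows, empty = NULL) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Recognised fungal lifestyle labels
#'
#' The closed set of lifestyle labels a species registry may use.
#'
#' @return Character vector of the ten allowed lifestyle labels.
#' @export
lifestyle_labels <- function() {
  c("Ectomycorrhizal", "White rot", "Brown rot", "Litter decayers",
    "Pathogen", "Orchid symbiont", "Ericoid symbiont", "Endophyte",
    "Mycoparasitic", "Yeast")
}

#' Read a protein FASTA file
#'
#' Reads amino-acid sequences into a protein table. The header token before
#' the first whitespace becomes the protein identifier; sequences are
#' upper-cased and trailing '*' stop characters are stripped. Draft-genome
#' ambiguity characters (X) are accepted.
#'
#' @param path Path to a FASTA file.
#' @param species Optional species name attached to every record.
#' @return A data.frame with columns `protein_id`, `species`, `sequence`,
#'   `length`.
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    return(data.frame(protein_id = character(), species = character(),
                      sequence = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("malformed FASTA: sequence before first header at line ",
         nonblank[1], " of ", path)
  }
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*+$", "", seqs)
  data.frame(protein_id = unname(ids),
             species = rep(species, length(ids)),
             sequence = unname(seqs),
             length = unname(nchar(seqs)),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a protein table to FASTA
#'
#' @param proteins Protein table as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aas <- Biostrings::AAStringSet(setNames(proteins$sequence,
                                          proteins$protein_id))
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Load and validate a species registry
#'
#' The registry maps each species to its lifestyle, phylum and family.
#' Lifestyles must come from the closed label set of [lifestyle_labels()]
#' and species names must be unique.
#'
#' @param path Path to a tab-separated file with columns `name`,
#'   `lifestyle`, `phylum`, `family`.
#' @return A validated data.frame of species records.
#' @export
load_species_registry <- function(path) {
  reg <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("name", "lifestyle", "phylum", "family")
  missing <- setdiff(needed, names(reg))
  if (length(missing)) {
    stop("species registry is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- reg$name[duplicated(reg$name)]
  if (length(dup)) {
    stop("duplicate species name(s) in registry: ",
         paste(unique(dup), collapse = ", "))
  }
  bad <- setdiff(unique(reg$lifestyle), lifestyle_labels())
  if (length(bad)) {
    stop("unknown lifestyle label(s): ", paste(bad, collapse = ", "),
         "; allowed labels are: ", paste(lifestyle_labels(), collapse = ", "))
  }
  reg[, needed]
}

#' Packaged registry of the 49 surveyed fungal species
#'
#' @return The packaged species registry (name, lifestyle, phylum, family).
#' @export
species_registry <- function() {
  load_species_registry(system.file("extdata", "species_registry.tsv",
                                    package = "secretominer", mustWork = TRUE))
}

## ---- helix interval serialization ------------------------------------------
## TM helices travel through tables as "start-end;start-end" strings.

#' Parse a serialized transmembrane-helix string
#'
#' @param x Character vector of `"start-end;start-end"` strings ("" = none).
#' @return A list of two-column integer matrices (start, end).
#' @export
parse_helices <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(matrix(integer(), ncol = 2,
                    dimnames = list(NULL, c("start", "end"))))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    m <- do.call(rbind, lapply(parts, function(p) as.integer(p)))
    colnames(m) <- c("start", "end")
    if (any(is.na(m)) || any(m[, 1] > m[, 2]) || any(m < 1L)) {
      stop("invalid helix interval string: ", s)
    }
    m
  })
}

#' Serialize transmembrane-helix intervals
#'
#' @param helices A two-column matrix of (start, end) intervals, or a list
#'   of such matrices.
#' @return Character vector of `"start-end;start-end"` strings.
#' @export
format_helices <- function(helices) {
  if (is.matrix(helices)) helices <- list(helices)
  vapply(helices, function(m) {
    if (is.null(m) || nrow(m) == 0L) return("")
    paste(paste(m[, 1], m[, 2], sep = "-"), collapse = ";")
  }, character(1))
}

## ---- predictor output dialects ---------------------------------------------

.read_data_lines <- function(path, drop_pattern = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  if (!is.null(drop_pattern)) keep <- keep & !grepl(drop_pattern, lines)
  data.frame(line_no = which(keep), text = lines[keep],
             stringsAsFactors = FALSE)
}

#' Parse SignalP 4.1 short-format output
#'
#' Expects the tool's whitespace-delimited short output: name, Cmax, pos,
#' Ymax, pos, Smax, pos, Smean, D, ?, Dmaxcut, networks. The Ymax position
#' is the first residue of the mature protein; the stored cleavage position
#' is the last residue of the signal peptide (Ymax position minus one).
#'
#' @param path Path to a SignalP 4.1 short-output file.
#' @return data.frame with `protein_id`, `sp_present`, `sp_cleavage_pos`,
#'   `sp_dscore`.
#' @export
parse_signalp <- function(path) {
  dl <- .read_data_lines(path)
  rows <- lapply(seq_len(nrow(dl)), function(i) {
    f <- strsplit(trimws(dl$text[i]), "\\s+")[[1]]
    if (length(f) < 12 || is.na(suppressWarnings(as.numeric(f[9]))) ||
        !f[10] %in% c("Y", "N")) {
      stop("unparseable SignalP line ", dl$line_no[i], " in ", path)
    }
    sp <- f[10] == "Y"
    data.frame(protein_id = f[1], sp_present = sp,
               sp_cleavage_pos = if (sp) as.integer(f[5]) - 1L else 0L,
               sp_dscore = as.numeric(f[9]), stringsAsFactors = FALSE)
  })
  .rbind_df(rows)
}

#' Parse TMHMM 2.0 short-format output
#'
#' Expects one line per protein with `len=`, `ExpAA=`, `First60=`,
#' `PredHel=` and `Topology=` fields; helix coordinates are taken from the
#' topology string (e.g. `i7-29o44-66i` gives helices 7-29 and 44-66).
#'
#' @param path Path to a TMHMM short-output file.
#' @return data.frame with `protein_id`, `tm_n_helices`, `tm_helices`
#'   (serialized intervals).
#' @export
parse_tmhmm <- function(path) {
  dl <- .read_data_lines(path)
  rows <- lapply(seq_len(nrow(dl)), function(i) {
    f <- strsplit(trimws(dl$text[i]), "\\s+")[[1]]
    pred <- grep("^PredHel=", f, value = TRUE)
    topo <- grep("^Topology=", f, value = TRUE)
    if (length(f) < 2 || length(pred) != 1 || length(topo) != 1) {
      stop("unparseable TMHMM line ", dl$line_no[i], " in ", path)
    }
    n <- as.integer(sub("^PredHel=", "", pred))
    topo <- sub("^Topology=", "", topo)
    m <- regmatches(topo, gregexpr("\\d+-\\d+", topo))[[1]]
    if (length(m) != n) {
      stop("TMHMM topology disagrees with PredHel on line ", dl$line_no[i],
           " in ", path)
    }
    ints <- do.call(rbind, lapply(strsplit(m, "-"), as.integer))
    if (is.null(ints)) {
      ints <- matrix(integer(), ncol = 2)
    }
    colnames(ints) <- c("start", "end")
    data.frame(protein_id = f[1], tm_n_helices = n,
               tm_helices = format_helices(ints), stringsAsFactors = FALSE)
  })
  .rbind_df(rows)
}

#' Parse TargetP 1.1 tabular output
#'
#' Expects the non-plant table: Name, Len, mTP, SP, other, Loc, RC. Loc `S`
#' is the secretory pathway, `M` mitochondrial; anything else (including
#' `_`) is stored as `O` (other).
#'
#' @param path Path to a TargetP 1.1 output file.
#' @return data.frame with `protein_id`, `targetp_loc`.
#' @export
parse_targetp <- function(path) {
  dl <- .read_data_lines(path, drop_pattern = "^\\s*-{2,}|^\\s*Name\\s|^\\s*cutoff")
  rows <- lapply(seq_len(nrow(dl)), function(i) {
    f <- strsplit(trimws(dl$text[i]), "\\s+")[[1]]
    if (length(f) < 6 || is.na(suppressWarnings(as.numeric(f[2])))) {
      stop("unparseable TargetP line ", dl$line_no[i], " in ", path)
    }
    loc <- f[6]
    if (!loc %in% c("S", "M")) loc <- "O"
    data.frame(protein_id = f[1], targetp_loc = loc, stringsAsFactors = FALSE)
  })
  .rbind_df(rows)
}

#' Parse WoLF PSORT one-line output
#'
#' Expects `id comp1 score1, comp2 score2, ...` with compartments ranked by
#' decreasing score. The full ranked string is kept so that downstream rules
#' can resolve ties at rank one.
#'
#' @param path Path to a WoLF PSORT output file.
#' @return data.frame with `protein_id`, `wolfpsort_top` (the ranked
#'   compartment string, e.g. `"extr 21, mito 4"`).
#' @export
parse_wolfpsort <- function(path) {
  dl <- .read_data_lines(path, drop_pattern = "^\\s*k used")
  rows <- lapply(seq_len(nrow(dl)), function(i) {
    s <- trimws(dl$text[i])
    sp <- regexpr("\\s", s)
    if (sp < 0) stop("unparseable WoLF PSORT line ", dl$line_no[i], " in ", path)
    id <- substr(s, 1, sp - 1)
    rest <- trimws(substr(s, sp + 1, nchar(s)))
    if (!grepl("^[A-Za-z_.]+\\s+[0-9.]+", rest)) {
      stop("unparseable WoLF PSORT line ", dl$line_no[i], " in ", path)
    }
    data.frame(protein_id = id, wolfpsort_top = rest, stringsAsFactors = FALSE)
  })
  .rbind_df(rows)
}

#' Compartment label(s) tied at rank one of a WoLF PSORT prediction
#'
#' @param x Character vector of ranked compartment strings as stored by
#'   [parse_wolfpsort()].
#' @return A list of character vectors: the compartment labels sharing the
#'   top score of each prediction.
#' @export
wolfpsort_top_labels <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    pairs <- strsplit(trimws(strsplit(s, ",", fixed = TRUE)[[1]]), "\\s+")
    labs <- vapply(pairs, `[`, character(1), 1)
    scores <- suppressWarnings(as.numeric(vapply(pairs, `[`, character(1), 2)))
    if (any(is.na(scores))) return(labs[1])
    labs[scores == max(scores)]
  })
}

#' Merge the four predictor outputs into one evidence table
#'
#' Produces one evidence row per protein present in all four inputs;
#' proteins missing from any input are reported in a warning and excluded.
#' If protein sequences are supplied, the C-terminal ER-retention scan is
#' run and stored in `kdel_cterm`.
#'
#' @param signalp_path,tmhmm_path,targetp_path,wolfpsort_path Paths to the
#'   respective predictor output files.
#' @param proteins Optional protein table used for the ER-retention scan.
#' @param kdel_mode Retention-motif mode, see [scan_cterm_retention()].
#' @return An evidence data.frame with columns `protein_id`, `sp_present`,
#'   `sp_cleavage_pos`, `sp_dscore`, `tm_n_helices`, `tm_helices`,
#'   `targetp_loc`, `wolfpsort_top`, `kdel_cterm`.
#' @export
parse_predictor_outputs <- function(signalp_path, tmhmm_path, targetp_path,
                                    wolfpsort_path, proteins = NULL,
                                    kdel_mode = "ps00014") {
  sp <- parse_signalp(signalp_path)
  tm <- parse_tmhmm(tmhmm_path)
  tp <- parse_targetp(targetp_path)
  wp <- parse_wolfpsort(wolfpsort_path)
  ids <- Reduce(intersect, list(sp$protein_id, tm$protein_id,
                                tp$protein_id, wp$protein_id))
  if (length(ids) == 0L) {
    stop("no protein identifiers are shared by all four predictor outputs")
  }
  all_ids <- unique(c(sp$protein_id, tm$protein_id, tp$protein_id,
                      wp$protein_id))
  dropped <- setdiff(all_ids, ids)
  if (length(dropped)) {
    warning(length(dropped), " protein(s) missing from at least one ",
            "predictor output were excluded: ",
            paste(head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) ", ..." else "")
  }
  ev <- merge(merge(sp, tm, by = "protein_id"),
              merge(tp, wp, by = "protein_id"), by = "protein_id")
  ev <- ev[match(ids, ev$protein_id), , drop = FALSE]
  if (!is.null(proteins)) {
    idx <- match(ev$protein_id, proteins$protein_id)
    ev$kdel_cterm <- ifelse(is.na(idx), NA,
                            scan_cterm_retention(proteins$sequence[idx],
                                                 mode = kdel_mode))
  } else {
    ev$kdel_cterm <- NA
  }
  rownames(ev) <- NULL
  ev
}

## ---- cluster fixture -------------------------------------------------------

#' Load the packaged table of lifestyle-shared SSP clusters
#'
#' The fixture transcribes the published table of small-secreted-protein
#' clusters shared among lifestyles. Member species are printed as
#' abbreviated binomials; they are expanded to full registry names through
#' the packaged abbreviation map (one-letter genus initials collide between
#' e.g. Paxillus, Pisolithus, Piloderma and Pleurotus, so an explicit map is
#' used rather than prefix matching).
#'
#' @param registry Species registry used to validate expanded names.
#' @return A data.frame with one row per cluster: `cluster_id`, `n_species`,
#'   `length_min`, `length_max`, `pfam`, `section`, and a list-column
#'   `members` of full species names.
#' @export
load_cluster_fixture <- function(registry = species_registry()) {
  path <- system.file("extdata", "ssp_clusters.tsv",
                      package = "secretominer", mustWork = TRUE)
  abbr_path <- system.file("extdata", "species_abbreviations.tsv",
                           package = "secretominer", mustWork = TRUE)
  cl <- read.delim(path, stringsAsFactors = FALSE)
  abbr <- read.delim(abbr_path, stringsAsFactors = FALSE)
  amap <- setNames(abbr$name, abbr$abbreviation)
  cl$members <- lapply(strsplit(cl$members, ";"), function(m) {
    m <- trimws(m)
    full <- ifelse(m %in% registry$name, m, unname(amap[m]))
    if (anyNA(full)) {
      stop("unresolvable species abbreviation(s) in cluster fixture: ",
           paste(m[is.na(full)], collapse = ", "))
    }
    unknown <- setdiff(full, registry$name)
    if (length(unknown)) {
      stop("cluster fixture species not present in registry: ",
           paste(unknown, collapse = ", "))
    }
    full
  })
  got <- lengths(cl$members)
  if (any(got != cl$n_species)) {
    stop("cluster fixture species counts disagree with member lists for ",
         "cluster(s): ",
         paste(cl$cluster_id[got != cl$n_species], collapse = ", "))
  }
  cl
}
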