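#' Best reference hit per database
#'
#' For each database, keeps the hit with the smallest e-value among hits at
#' or below the cutoff (inclusive). Ties are broken by larger bitscore,
#' then lexicographically smaller subject label, so the result does not
#' depend on the order of the input hits.
#'
#' @param hits Hit table with columns `protein_id`, `database`,
#'   `subject_label`, `evalue`, `bitscore` (one protein, many hits).
#' @param evalue_cutoff Inclusive e-value cutoff (default `1e-5`).
#' @return A data.frame with at most one row per database.
#' @export
best_hits <- function(hits, evalue_cutoff = 1e-5) {
  h <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(h) == 0L) return(h)
  o <- order(h$database, h$evalue, -h$bitscore, h$subject_label)
  h <- h[o, , drop = FALSE]
  h <- h[!duplicated(h$database), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Default MEROPS endo/exoprotease mapping
#'
#' The endo/exo split of the ecologically relevant peptidase families:
#' endoproteases A01 (pepsin), M36 (fungalysin), S53 (sedolisin) and S28
#' (lysosomal Pro-Xaa carboxypeptidase); exoproteases S08 (subtilisin),
#' S09 (carboxypeptidase) and M28 (aminopeptidase). The mapping is an
#' argument everywhere it is used, so an alternative assignment (e.g.
#' moving S08/S09 to endo and S28 to exo) is one edit away.
#'
#' @return Named character vector: MEROPS family -> `"endo"` or `"exo"`.
#' @export
default_protease_mapping <- function() {
  c(A01 = "endo", M36 = "endo", S53 = "endo", S28 = "endo",
    S08 = "exo", S09 = "exo", M28 = "exo")
}

#' Classify a MEROPS family as endo- or exoprotease
#'
#' @param merops_family Character vector of MEROPS family labels.
#' @param mapping Named vector family -> type; families outside the
#'   mapping return `"unassigned"`.
#' @return Character vector in `{"endo", "exo", "unassigned"}`.
#' @export
protease_type <- function(merops_family, mapping = default_protease_mapping()) {
  out <- unname(mapping[merops_family])
  out[is.na(out) & !is.na(merops_family)] <- "unassigned"
  out
}

#' Parse a lipase-database label into class and subfamily
#'
#' Labels encode the oxyanion-hole class and a subfamily, e.g.
#' `"GGGX.carboxylesterase"` or `"GX.thioesterase"`. Labels without a
#' recognized GX/GGGX class prefix are returned unclassified with a
#' warning.
#'
#' @param led_label Character vector of lipase labels.
#' @return data.frame with columns `lipase_class` (`"GX"`, `"GGGX"` or
#'   `NA`) and `lipase_subfamily`.
#' @export
lipase_classify <- function(led_label) {
  cls <- sub("\\..*$", "", led_label)
  sub <- ifelse(grepl(".", led_label, fixed = TRUE),
                sub("^[^.]*\\.", "", led_label), NA_character_)
  bad <- !is.na(led_label) & !cls %in% c("GX", "GGGX")
  if (any(bad)) {
    warning("unrecognized lipase class label(s): ",
            paste(unique(led_label[bad]), collapse = ", "))
    cls[bad] <- NA_character_
    sub[bad] <- NA_character_
  }
  cls[is.na(led_label)] <- NA_character_
  data.frame(lipase_class = cls, lipase_subfamily = sub,
             stringsAsFactors = FALSE)
}

#' Percentage of cysteine residues
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Numeric vector, 100 x (number of C residues) / length.
#' @export
cys_percent <- function(sequence) {
  if (any(!nzchar(sequence))) stop("cys_percent requires non-empty sequences")
  100 * (nchar(sequence) - nchar(gsub("C", "", sequence, fixed = TRUE))) /
    nchar(sequence)
}

#' Locate lysine/arginine-rich regions
#'
#' Slides a window along the sequence and merges all windows whose K+R
#' fraction reaches `min_fraction` into maximal intervals. The window and
#' fraction defaults are pragmatic settings for flagging charged stretches;
#' both are exposed.
#'
#' @param sequence A single amino-acid sequence.
#' @param window Window length (default 20).
#' @param min_fraction Minimum K+R fraction within a window (default 0.4).
#' @return A two-column (start, end) integer matrix of merged intervals;
#'   zero rows when the sequence is shorter than the window or no window
#'   qualifies.
#' @export
kr_rich_regions <- function(sequence, window = 20L, min_fraction = 0.4) {
  if (window < 1) stop("window must be >= 1")
  empty <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end")))
  n <- nchar(sequence)
  if (n < window) return(empty)
  kr <- as.integer(strsplit(sequence, "")[[1]] %in% c("K", "R"))
  cs <- cumsum(c(0L, kr))
  starts <- 1:(n - window + 1L)
  frac <- (cs[starts + window] - cs[starts]) / window
  hit <- starts[frac >= min_fraction]
  if (!length(hit)) return(empty)
  ivs <- cbind(hit, hit + window - 1L)
  merged <- list(ivs[1, ])
  if (nrow(ivs) > 1) {
    for (i in 2:nrow(ivs)) {
      last <- merged[[length(merged)]]
      if (ivs[i, 1] <= last[2] + 1L) {
        merged[[length(merged)]] <- c(last[1], max(last[2], ivs[i, 2]))
      } else {
        merged[[length(merged) + 1L]] <- ivs[i, ]
      }
    }
  }
  m <- do.call(rbind, merged)
  colnames(m) <- c("start", "end")
  m
}

#' Assign the functional category of one secreted protein
#'
#' The category follows the database of the overall smallest-e-value best
#' hit: CAZy -> CAZyme, MEROPS -> Protease, LED -> Lipase. Proteins without
#' any database hit are categorized SSP when small, otherwise Other. The
#' SSP flag is kept independently of the category, so a small lipase is
#' both a Lipase (category) and an SSP (flag).
#'
#' @param best Best-hit table from [best_hits()] (may be empty).
#' @param ssp_flag Logical, is the protein a small secreted protein?
#' @return Character scalar category.
#' @export
assign_category <- function(best, ssp_flag) {
  cat_map <- c(CAZy = "CAZyme", MEROPS = "Protease", LED = "Lipase")
  b <- best[best$database %in% names(cat_map), , drop = FALSE]
  if (nrow(b) == 0L) return(if (isTRUE(ssp_flag)) "SSP" else "Other")
  b <- b[order(b$evalue, -b$bitscore, b$subject_label), , drop = FALSE]
  unname(cat_map[b$database[1]])
}

#' Simple basic-residue nuclear-localization-signal scan
#'
#' A surrogate motif scan (not the external NLS predictor): flags a
#' monopartite stretch of five or more consecutive K/R residues.
#' Disabled by default in [annotate_secretome()].
#'
#' @param sequence Character vector of sequences.
#' @return Logical vector.
#' @export
nls_basic_scan <- function(sequence) {
  grepl("[KR]{5,}", sequence)
}

#' Annotate a predicted secretome
#'
#' Joins the secretion decisions with the reference hit table and computes,
#' for every secreted protein: functional category, CAZy family, MEROPS
#' family and endo/exo type, lipase class and subfamily, PFAM domain list,
#' cysteine percentage and K/R-rich regions.
#'
#' @param decisions Decision table from [decide_secreted()] (must carry
#'   `length` and `ssp`, i.e. be computed with sequences available).
#' @param proteins Protein table covering the secreted proteins.
#' @param hits Reference hit table (columns `protein_id`, `database`,
#'   `subject_label`, `evalue`, `bitscore`); may be empty.
#' @param evalue_cutoff Inclusive best-hit e-value cutoff.
#' @param protease_mapping MEROPS endo/exo mapping.
#' @param nls_scan Run the surrogate NLS scan (default `FALSE`)?
#' @return One row per secreted protein: identifiers, `category`, `ssp`,
#'   sub-family fields, `pfam_domains` (semicolon-joined accessions),
#'   `cys_percent`, `kr_rich_regions` (serialized intervals),
#'   `nls_predicted`.
#' @export
annotate_secretome <- function(decisions, proteins, hits = NULL,
                               evalue_cutoff = 1e-5,
                               protease_mapping = default_protease_mapping(),
                               nls_scan = FALSE) {
  sec <- decisions[decisions$secreted, , drop = FALSE]
  if (is.null(hits)) {
    hits <- data.frame(protein_id = character(), database = character(),
                       subject_label = character(), evalue = numeric(),
                       bitscore = numeric(), stringsAsFactors = FALSE)
  }
  hit_split <- split(hits, hits$protein_id)
  idx <- match(sec$protein_id, proteins$protein_id)
  if (anyNA(idx)) {
    stop("secreted protein(s) missing from the protein table: ",
         paste(head(sec$protein_id[is.na(idx)], 5), collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(sec)), function(i) {
    pid <- sec$protein_id[i]
    seq <- proteins$sequence[idx[i]]
    ph <- hit_split[[pid]]
    best <- if (is.null(ph)) hits[0, , drop = FALSE] else {
      best_hits(ph, evalue_cutoff)
    }
    pick <- function(db) {
      r <- best[best$database == db, , drop = FALSE]
      if (nrow(r)) r$subject_label[1] else NA_character_
    }
    cazy <- pick("CAZy")
    merops <- pick("MEROPS")
    led <- pick("LED")
    pf <- if (is.null(ph)) character() else {
      sort(unique(ph$subject_label[ph$database == "PFAM" &
                                     ph$evalue <= evalue_cutoff]))
    }
    lip <- lipase_classify(led)
    data.frame(protein_id = pid,
               species = proteins$species[idx[i]],
               length = proteins$length[idx[i]],
               category = assign_category(best, sec$ssp[i]),
               ssp = sec$ssp[i],
               cazy_family = cazy,
               merops_family = merops,
               protease_type = if (is.na(merops)) "unassigned" else {
                 protease_type(merops, protease_mapping)
               },
               lipase_class = lip$lipase_class,
               lipase_subfamily = lip$lipase_subfamily,
               pfam_domains = paste(pf, collapse = ";"),
               cys_percent = cys_percent(seq),
               kr_rich_regions = format_helices(kr_rich_regions(seq)),
               nls_predicted = if (nls_scan) nls_basic_scan(seq) else NA,
               stringsAsFactors = FALSE)
  })
  out <- .rbind_df(rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), species = character(),
                      length = integer(), category = character(),
                      ssp = logical(), cazy_family = character(),
                      merops_family = character(), protease_type = character(),
                      lipase_class = character(),
                      lipase_subfamily = character(),
                      pfam_domains = character(), cys_percent = numeric(),
                      kr_rich_regions = character(), nls_predicted = logical(),
                      stringsAsFactors = FALSE)
  }
  out
}
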