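#' Scan a sequence for a C-terminal ER-retention motif
#'
#' Proteins carrying an ER-retention tetrapeptide at their extreme C
#' terminus permanently reside in the endoplasmic reticulum and are
#' excluded from the predicted secretome. Two motif definitions are
#' supported: `strict_kdel` matches the literal K-D-E-L, while `ps00014`
#' matches the PROSITE ER_TARGET pattern \code{[KRHQSA]-[DENQ]-E-L}.
#' `ps00014` is the default because it subsumes the literal motif while
#' covering the common HDEL/RDEL variants.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param mode `"ps00014"` (default) or `"strict_kdel"`.
#' @return Logical vector: does the sequence end in the motif? Sequences
#'   shorter than four residues cannot carry it and return `FALSE`.
#' @export
scan_cterm_retention <- function(sequence, mode = c("ps00014", "strict_kdel")) {
  mode <- match.arg(mode)
  if (any(!nzchar(sequence) | is.na(sequence))) {
    stop("scan_cterm_retention requires non-empty sequences")
  }
  n <- nchar(sequence)
  last4 <- substr(sequence, n - 3L, n)
  out <- rep(FALSE, length(sequence))
  ok <- n >= 4L
  if (mode == "strict_kdel") {
    out[ok] <- last4[ok] == "KDEL"
  } else {
    out[ok] <- grepl("^[KRHQSA][DENQ]EL$", last4[ok])
  }
  out
}

#' Is a transmembrane topology compatible with secretion?
#'
#' A protein passes the membrane-topology rule when it has no predicted
#' transmembrane helix, or exactly one helix that overlaps the signal
#' peptide (helix start at or before the predicted cleavage position) --
#' such a "helix" is the signal peptide's own hydrophobic core, not a
#' membrane anchor.
#'
#' @param tm_helices A two-column (start, end) interval matrix, a
#'   serialized `"start-end;..."` string, or a list of either.
#' @param sp_present Logical, signal peptide predicted?
#' @param sp_cleavage_pos Integer, last residue of the signal peptide
#'   (0 when no signal peptide).
#' @return Logical vector.
#' @export
tm_compatible <- function(tm_helices, sp_present, sp_cleavage_pos) {
  if (is.character(tm_helices)) tm_helices <- parse_helices(tm_helices)
  if (is.matrix(tm_helices) || is.null(tm_helices)) {
    tm_helices <- list(tm_helices)
  }
  n <- length(tm_helices)
  sp_present <- rep_len(sp_present, n)
  sp_cleavage_pos <- rep_len(as.integer(sp_cleavage_pos), n)
  if (any(!sp_present & sp_cleavage_pos != 0L)) {
    stop("sp_cleavage_pos must be 0 when no signal peptide is present")
  }
  vapply(seq_len(n), function(i) {
    h <- tm_helices[[i]]
    k <- if (is.null(h)) 0L else nrow(h)
    if (k == 0L) return(TRUE)
    if (k > 1L) return(FALSE)
    sp_present[i] && h[1, 1] <= sp_cleavage_pos[i]
  }, logical(1))
}

#' Secretion-rule configuration
#'
#' @param kdel_mode Retention-motif mode, see [scan_cterm_retention()].
#' @param ssp_threshold Length below which a secreted protein counts as a
#'   small secreted protein (strict `<`, full precursor length).
#' @param extracellular_label WoLF PSORT compartment label meaning
#'   "extracellular".
#' @return A named list of settings.
#' @export
secretion_config <- function(kdel_mode = "ps00014", ssp_threshold = 300L,
                             extracellular_label = "extr") {
  if (ssp_threshold < 1) stop("ssp_threshold must be a positive length")
  list(kdel_mode = match.arg(kdel_mode, c("ps00014", "strict_kdel")),
       ssp_threshold = as.integer(ssp_threshold),
       extracellular_label = extracellular_label)
}

#' Flag small secreted proteins
#'
#' A small secreted protein (SSP) is a predicted secreted protein whose
#' full precursor (signal peptide included) is shorter than the threshold.
#'
#' @param secreted Logical vector of secretion calls.
#' @param length Integer vector of precursor lengths.
#' @param threshold SSP length threshold (default 300; strict `<`).
#' @return Logical vector.
#' @export
flag_ssp <- function(secreted, length, threshold = 300L) {
  if (threshold < 1) stop("SSP threshold must be a positive length")
  secreted & length < threshold
}

#' Apply the combined secretion decision rule
#'
#' A protein is predicted secreted when all five sub-criteria hold:
#' a signal peptide is present (`sp_present`), its transmembrane topology
#' is compatible with secretion (`tm_ok`, see [tm_compatible()]), the
#' targeting predictor assigns the secretory pathway (`targetp_ok`, Loc
#' `S`), the sorting predictor ranks the extracellular compartment first
#' (`wolfpsort_ok`, ties at rank one count as a pass when the
#' extracellular label is among them), and no C-terminal ER-retention
#' motif is found (`kdel_ok`). All five sub-decisions are recorded even
#' when an earlier one already fails.
#'
#' @param evidence Evidence table (one row per protein) as produced by
#'   [parse_predictor_outputs()], [surrogate_predict()] or
#'   [generate_proteome()].
#' @param proteins Optional protein table; when given, the ER-retention
#'   scan is (re)computed from the sequences, and SSPs are flagged.
#' @param config Settings from [secretion_config()].
#' @return A data.frame with one row per evidence row: `protein_id`, the
#'   five rule outcomes, `secreted`, and (when sequences are available)
#'   `length` and `ssp`.
#' @export
decide_secreted <- function(evidence, proteins = NULL,
                            config = secretion_config()) {
  ev <- evidence
  sp_ok <- as.logical(ev$sp_present)
  tm_ok <- tm_compatible(ev$tm_helices, ev$sp_present, ev$sp_cleavage_pos)
  tp_ok <- ev$targetp_loc == "S"
  wp_ok <- vapply(wolfpsort_top_labels(ev$wolfpsort_top),
                  function(l) config$extracellular_label %in% l, logical(1))
  len <- rep(NA_integer_, nrow(ev))
  if (!is.null(proteins)) {
    idx <- match(ev$protein_id, proteins$protein_id)
    if (anyNA(idx)) {
      stop("evidence refers to protein(s) absent from the protein table: ",
           paste(head(ev$protein_id[is.na(idx)], 5), collapse = ", "))
    }
    kdel <- scan_cterm_retention(proteins$sequence[idx],
                                 mode = config$kdel_mode)
    len <- proteins$length[idx]
  } else {
    if (is.null(ev$kdel_cterm) || anyNA(ev$kdel_cterm)) {
      stop("either protein sequences or a complete kdel_cterm evidence ",
           "column is required for the ER-retention rule")
    }
    kdel <- as.logical(ev$kdel_cterm)
  }
  kdel_ok <- !kdel
  secreted <- sp_ok & tm_ok & tp_ok & wp_ok & kdel_ok
  out <- data.frame(protein_id = ev$protein_id,
                    sp_present = sp_ok, tm_ok = tm_ok, targetp_ok = tp_ok,
                    wolfpsort_ok = wp_ok, kdel_ok = kdel_ok,
                    secreted = secreted, stringsAsFactors = FALSE)
  if (!is.null(proteins)) {
    out$length <- len
    out$ssp <- flag_ssp(secreted, len, config$ssp_threshold)
  }
  out
}

## ---- surrogate predictor ---------------------------------------------------

## Kyte-Doolittle hydropathy scale; X is treated as neutral (0).
.kd_scale <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2, X = 0)

.hydrophobic_set <- c("A", "I", "L", "M", "F", "V", "W")

#' Surrogate localization predictor configuration
#'
#' @param tm_window Window length for the hydropathy scan (residues).
#' @param tm_cutoff Mean Kyte-Doolittle hydropathy above which a window is
#'   called membrane-spanning.
#' @param kdel_mode Retention-motif mode for the C-terminal scan.
#' @return A named list of settings.
#' @export
surrogate_config <- function(tm_window = 19L, tm_cutoff = 1.6,
                             kdel_mode = "ps00014") {
  list(tm_window = as.integer(tm_window), tm_cutoff = tm_cutoff,
       kdel_mode = match.arg(kdel_mode, c("ps00014", "strict_kdel")))
}

.surrogate_signal <- function(seq) {
  ## charged n-region: >=1 K/R within residues 1-5
  head5 <- substr(seq, 1, 5)
  if (!grepl("[KR]", head5)) return(0L)
  chars <- strsplit(substr(seq, 1, min(30L, nchar(seq))), "")[[1]]
  hyd <- chars %in% .hydrophobic_set
  r <- rle(hyd)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= 8L)
  if (!length(good)) return(0L)
  h_end <- ends[good[1]]
  ## small-residue cleavage context: A-x-A ending at some position shortly
  ## after the hydrophobic core; cleavage after the final A
  lim <- min(nchar(seq) - 1L, h_end + 8L)
  p <- h_end + 2L
  while (p <= lim) {
    if (substr(seq, p, p) == "A" && substr(seq, p - 2L, p - 2L) == "A") {
      return(p)
    }
    p <- p + 1L
  }
  0L
}

.surrogate_tm <- function(seq, from, window, cutoff) {
  n <- nchar(seq)
  if (n - from + 1L < window) {
    return(matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  h <- .kd_scale[strsplit(seq, "")[[1]]]
  h[is.na(h)] <- 0
  cs <- cumsum(c(0, h))
  starts <- from:(n - window + 1L)
  means <- (cs[starts + window] - cs[starts]) / window
  hit <- starts[means > cutoff]
  if (!length(hit)) {
    return(matrix(integer(), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  ## merge overlapping qualifying windows into maximal helices
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

#' Heuristic surrogate for the external localization predictors
#'
#' A deterministic, self-contained stand-in used for demos and tests.
#' It is NOT equivalent to the trained tools whose outputs the pipeline
#' normally ingests. Signal peptides are called from sequence anatomy
#' (charged n-region within the first five residues, a hydrophobic core of
#' at least eight consecutive residues within the first thirty, then an
#' A-x-A cleavage context); transmembrane helices from 19-residue
#' Kyte-Doolittle hydropathy windows outside the called signal; the
#' targeting and sorting fields echo the signal-peptide call; the
#' ER-retention flag comes from [scan_cterm_retention()].
#'
#' @param proteins Protein table (see [read_fasta()]).
#' @param config Settings from [surrogate_config()].
#' @return An evidence data.frame in the layout of
#'   [parse_predictor_outputs()].
#' @export
surrogate_predict <- function(proteins, config = surrogate_config()) {
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    seq <- proteins$sequence[i]
    cleave <- .surrogate_signal(seq)
    sp <- cleave > 0L
    tm <- .surrogate_tm(seq, from = if (sp) cleave + 1L else 1L,
                        window = config$tm_window, cutoff = config$tm_cutoff)
    kdel <- scan_cterm_retention(seq, mode = config$kdel_mode)
    data.frame(protein_id = proteins$protein_id[i],
               sp_present = sp,
               sp_cleavage_pos = cleave,
               sp_dscore = if (sp) 0.9 else 0.1,
               tm_n_helices = nrow(tm),
               tm_helices = format_helices(tm),
               targetp_loc = if (sp) "S" else "O",
               wolfpsort_top = if (sp) "extr 20, cyto 7" else "cyto 20, extr 7",
               kdel_cterm = kdel,
               stringsAsFactors = FALSE)
  })
  .rbind_df(rows)
}
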