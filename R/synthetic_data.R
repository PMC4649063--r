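## Robinson-Robinson style amino-acid background frequencies.
.rr_freqs <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
               Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
               L = 0.091, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
               S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.064)

.aa20 <- names(.rr_freqs)

#' Configuration of the synthetic proteome generator
#'
#' The defaults emulate the statistical shape of the surveyed genomes:
#' forty-nine species whose lifestyles follow the packaged registry,
#' proteomes of ten thousand proteins, 6.5% of each proteome carrying a
#' signal peptide (the survey reports 3-10%), just over half of the
#' secreted proteins below the SSP length threshold, 15% membrane
#' proteins, and 2% of signal-peptide proteins retained in the ER by a
#' C-terminal KDEL. Tests and demos pass smaller explicit sizes.
#'
#' @param seed Integer seed; all randomness flows from it through
#'   per-species substreams so partial regeneration is stable.
#' @param n_species Number of synthetic species.
#' @param lifestyles Lifestyle label per species; defaults to the packaged
#'   registry's lifestyles, recycled.
#' @param proteome_size Proteins per species (recycled).
#' @param secreted_fraction Fraction of each proteome carrying a signal
#'   peptide.
#' @param ssp_fraction_of_secreted Fraction of true secreted proteins
#'   shorter than the SSP threshold.
#' @param tm_protein_fraction Fraction of each proteome that are
#'   polytopic/bitopic membrane proteins (no signal peptide).
#' @param kdel_fraction_of_secreted Fraction of signal-peptide proteins
#'   carrying a C-terminal ER-retention motif (these are NOT secreted in
#'   the ground truth).
#' @param n_planted_families Number of cross-species SSP families planted.
#' @param family_identity Target expected pairwise identity within a
#'   planted family, in `(0, 1]`.
#' @param family_lifestyle_patterns Optional list (length
#'   `n_planted_families`) of lifestyle-label vectors; each family plants
#'   one member in one species of each listed lifestyle. `NULL` draws a
#'   random pattern of 3-5 distinct lifestyles per family.
#' @param background Residue background: `"uniform"` over the 20 standard
#'   residues (default; identity statistics under the null are easiest to
#'   reason about) or `"robinson"` frequencies.
#' @return A validated config list.
#' @export
simulation_config <- function(seed = 1L, n_species = 49L, lifestyles = NULL,
                              proteome_size = 10000L,
                              secreted_fraction = 0.065,
                              ssp_fraction_of_secreted = 0.55,
                              tm_protein_fraction = 0.15,
                              kdel_fraction_of_secreted = 0.02,
                              n_planted_families = 0L,
                              family_identity = 0.85,
                              family_lifestyle_patterns = NULL,
                              background = c("uniform", "robinson")) {
  fracs <- c(secreted_fraction, ssp_fraction_of_secreted,
             tm_protein_fraction, kdel_fraction_of_secreted)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions must lie in [0, 1]")
  }
  if (secreted_fraction + tm_protein_fraction > 1) {
    stop("secreted_fraction + tm_protein_fraction must not exceed 1")
  }
  if (family_identity <= 0 || family_identity > 1) {
    stop("family_identity must lie in (0, 1]")
  }
  if (is.null(lifestyles)) {
    lifestyles <- rep_len(species_registry()$lifestyle, n_species)
  } else {
    lifestyles <- rep_len(lifestyles, n_species)
  }
  list(seed = as.integer(seed), n_species = as.integer(n_species),
       lifestyles = lifestyles,
       proteome_size = rep_len(as.integer(proteome_size), n_species),
       secreted_fraction = secreted_fraction,
       ssp_fraction_of_secreted = ssp_fraction_of_secreted,
       tm_protein_fraction = tm_protein_fraction,
       kdel_fraction_of_secreted = kdel_fraction_of_secreted,
       n_planted_families = as.integer(n_planted_families),
       family_identity = family_identity,
       family_lifestyle_patterns = family_lifestyle_patterns,
       background = match.arg(background))
}

.rand_seq <- function(n, background = "uniform") {
  prob <- if (background == "robinson") .rr_freqs else NULL
  paste(sample(.aa20, n, replace = TRUE, prob = prob), collapse = "")
}

## Signal peptide: M, a charged n-region, an 8-12 residue hydrophobic
## h-region, and an A-x-A c-region; cleavage after the final A.
.make_signal_peptide <- function() {
  n_len <- sample(1:3, 1)
  n_region <- paste(c(sample(c("K", "R"), 1),
                      if (n_len > 1) sample(.aa20, n_len - 1, TRUE)),
                    collapse = "")
  h_region <- paste(sample(c("A", "I", "L", "M", "F", "V", "W"),
                           sample(8:12, 1), TRUE), collapse = "")
  c_mid <- sample(c("S", "T", "G", "N", "Q", "P", "D", "E"), 1)
  sp <- paste0("M", n_region, h_region, "A", c_mid, "A")
  list(seq = sp, cleavage = nchar(sp))
}

## Replace a C-terminal ER-retention motif that arose by chance.
.scrub_kdel <- function(seq) {
  hit <- scan_cterm_retention(seq, mode = "ps00014")
  if (any(hit)) {
    n <- nchar(seq[hit])
    substr(seq[hit], n, n) <- "G"
  }
  seq
}

## Per-member retention t solving t^2 + (1-t)^2/19 = target, so that the
## EXPECTED PAIRWISE identity between independently mutated members equals
## the requested family identity.
.family_retention <- function(target) {
  (2 + sqrt(4 - 80 * (1 - 19 * target))) / 40
}

#' Plant one SSP family by mutating a common ancestor
#'
#' Each member is an independent copy of the ancestor with a per-site
#' substitution probability calibrated so the expected pairwise identity
#' between members equals `target_identity` (substitutions are uniform
#' over the 19 alternative residues, so two members agree at a site with
#' probability `t^2 + (1 - t)^2 / 19` where `t` is the per-member
#' retention; `t` is solved from that equation). No indels are introduced.
#'
#' @param ancestor_length Ancestor length in residues (must be below the
#'   SSP threshold when used to plant SSPs); ignored when `ancestor` is
#'   supplied.
#' @param n_members Number of members; at most one per species.
#' @param species_set Species names to draw members from.
#' @param target_identity Expected pairwise identity in `(0, 1]`.
#' @param seed Optional integer seed.
#' @param ancestor Optional explicit ancestor sequence.
#' @return A list with `ancestor`, `members` (data.frame `protein_id`,
#'   `species`, `sequence`) and `realized_identity` (pairwise identity
#'   matrix, exact site-wise agreement).
#' @export
plant_ssp_family <- function(ancestor_length, n_members, species_set,
                             target_identity, seed = NULL, ancestor = NULL) {
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must lie in (0, 1]")
  }
  if (n_members > length(species_set)) {
    stop("n_members exceeds the number of available species ",
         "(one member per species)")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ancestor)) ancestor <- .rand_seq(ancestor_length)
  anc <- strsplit(ancestor, "")[[1]]
  t_keep <- .family_retention(target_identity)
  species <- species_set[seq_len(n_members)]
  members <- vapply(seq_len(n_members), function(i) {
    m <- anc
    mut <- which(stats::runif(length(m)) < 1 - t_keep)
    if (length(mut)) {
      m[mut] <- vapply(m[mut], function(orig) {
        sample(setdiff(.aa20, orig), 1)
      }, character(1))
    }
    paste(m, collapse = "")
  }, character(1))
  k <- n_members
  ident <- matrix(1, k, k)
  if (k > 1) {
    chars <- lapply(members, function(s) strsplit(s, "")[[1]])
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ident[i, j] <- ident[j, i] <- mean(chars[[i]] == chars[[j]])
    }
  }
  list(ancestor = ancestor,
       members = data.frame(protein_id = sprintf("fam_m%02d", seq_len(k)),
                            species = species, sequence = unname(members),
                            stringsAsFactors = FALSE),
       realized_identity = ident)
}

#' Generate a multi-species synthetic proteome with planted ground truth
#'
#' Builds, per species, an exact (rounded, not sampled) number of secreted
#' proteins, ER-retained (KDEL) signal-peptide proteins, membrane proteins
#' and background proteins, plus cross-species SSP families mutated from
#' common ancestors. Secreted proteins receive a generated signal peptide
#' (charged n-region, hydrophobic h-region, A-x-A cleavage context);
#' membrane proteins receive 1-7 hydrophobic helices at recorded
#' coordinates. The emitted evidence table reflects the planted truth
#' exactly, so the decision rule recovers the planted secretome without
#' error; chance C-terminal retention motifs in non-retained proteins are
#' scrubbed to keep the ground truth consistent.
#'
#' @param config A config from [simulation_config()].
#' @return A list with `proteins` (all species), `evidence`, `truth`
#'   (per-protein `secreted`, `ssp`, `class`, `family_id`), `registry`
#'   (synthetic species registry), and `families` (per-family target and
#'   realized identities, member lists).
#' @export
generate_proteome <- function(config = simulation_config()) {
  set.seed(config$seed)
  species <- sprintf("sp%02d", seq_len(config$n_species))
  sp_seeds <- sample.int(.Machine$integer.max - 1L, config$n_species)
  fam_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  registry <- data.frame(name = species, lifestyle = config$lifestyles,
                         phylum = "Synthetica", family = "Simulatae",
                         stringsAsFactors = FALSE)

  ## choose family patterns and member species up front
  families <- NULL
  fam_members <- list()
  if (config$n_planted_families > 0) {
    set.seed(fam_seed)
    patterns <- config$family_lifestyle_patterns
    if (is.null(patterns)) {
      avail <- unique(config$lifestyles)
      patterns <- lapply(seq_len(config$n_planted_families), function(f) {
        sample(avail, min(length(avail), sample(3:5, 1)))
      })
    }
    if (length(patterns) != config$n_planted_families) {
      stop("family_lifestyle_patterns must have one entry per family")
    }
    fam_rows <- list()
    for (f in seq_len(config$n_planted_families)) {
      pat <- patterns[[f]]
      missing <- setdiff(pat, config$lifestyles)
      if (length(missing)) {
        stop("family lifestyle pattern names absent lifestyle(s): ",
             paste(missing, collapse = ", "))
      }
      ## one member per pattern slot, distinct species throughout (repeated
      ## lifestyle labels draw distinct species of that lifestyle)
      fam_species <- character(0)
      for (l in unique(pat)) {
        k <- sum(pat == l)
        cand <- species[config$lifestyles == l]
        if (k > length(cand)) {
          stop("family pattern asks for ", k, " species of lifestyle '", l,
               "' but only ", length(cand), " exist")
        }
        fam_species <- c(fam_species,
                         if (length(cand) == 1) cand else sample(cand, k))
      }
      sp_part <- .make_signal_peptide()
      body_len <- sample(80:250, 1)
      total_len <- nchar(sp_part$seq) + body_len
      if (total_len >= 300L) body_len <- 299L - nchar(sp_part$seq)
      ancestor <- paste0(sp_part$seq, .rand_seq(body_len, config$background))
      fam <- plant_ssp_family(n_members = length(fam_species),
                              species_set = fam_species,
                              target_identity = config$family_identity,
                              ancestor = ancestor)
      fam$members$sequence <- .scrub_kdel(fam$members$sequence)
      fam$members$protein_id <- sprintf("%s_fam%03d", fam_species, f)
      fam$cleavage <- sp_part$cleavage
      fam$family_id <- f
      fam$pattern <- pat
      fam_rows[[f]] <- fam
      for (s in fam_species) {
        fam_members[[s]] <- rbind(
          fam_members[[s]],
          data.frame(protein_id = sprintf("%s_fam%03d", s, f),
                     sequence = fam$members$sequence[fam$members$species == s],
                     cleavage = sp_part$cleavage, family_id = f,
                     stringsAsFactors = FALSE))
      }
    }
    families <- fam_rows
  }

  per_species <- lapply(seq_len(config$n_species), function(i) {
    set.seed(sp_seeds[i])
    sp_name <- species[i]
    n <- config$proteome_size[i]
    n_sp_all <- round(config$secreted_fraction * n)
    n_kdel <- round(config$kdel_fraction_of_secreted * n_sp_all)
    n_sec <- n_sp_all - n_kdel
    n_ssp <- round(config$ssp_fraction_of_secreted * n_sec)
    n_tm <- round(config$tm_protein_fraction * n)
    fams <- fam_members[[sp_name]]
    n_fam <- if (is.null(fams)) 0L else nrow(fams)
    if (n_fam > n_ssp) {
      stop("species ", sp_name, " has fewer SSP slots (", n_ssp,
           ") than planted family members (", n_fam, ")")
    }
    n_bg <- n - n_sp_all - n_tm
    pid <- function(j) sprintf("%s_p%04d", sp_name, j)
    rows <- vector("list", n)
    j <- 0L
    add <- function(sequence, class, secreted, cleavage, helices,
                    family_id = NA_integer_, id = NULL) {
      j <<- j + 1L
      rows[[j]] <<- data.frame(
        protein_id = if (is.null(id)) pid(j) else id,
        sequence = sequence, class = class, secreted = secreted,
        cleavage = cleavage, tm_helices = helices, family_id = family_id,
        stringsAsFactors = FALSE)
    }
    ## planted family members (fill SSP slots first)
    if (n_fam > 0) {
      for (k in seq_len(n_fam)) {
        add(fams$sequence[k], "secreted", TRUE, fams$cleavage[k], "",
            fams$family_id[k], id = fams$protein_id[k])
      }
    }
    ## remaining small secreted proteins
    for (k in seq_len(n_ssp - n_fam)) {
      sp_part <- .make_signal_peptide()
      body <- .rand_seq(sample(60:(299 - nchar(sp_part$seq) - 1), 1),
                        config$background)
      add(.scrub_kdel(paste0(sp_part$seq, body)), "secreted", TRUE,
          sp_part$cleavage, "")
    }
    ## large secreted proteins
    for (k in seq_len(n_sec - n_ssp)) {
      sp_part <- .make_signal_peptide()
      body <- .rand_seq(sample(300:700, 1), config$background)
      add(.scrub_kdel(paste0(sp_part$seq, body)), "secreted", TRUE,
          sp_part$cleavage, "")
    }
    ## ER-retained signal-peptide proteins
    for (k in seq_len(n_kdel)) {
      sp_part <- .make_signal_peptide()
      body <- .rand_seq(sample(100:400, 1), config$background)
      add(paste0(sp_part$seq, body, "KDEL"), "er_retained", FALSE,
          sp_part$cleavage, "")
    }
    ## membrane proteins
    for (k in seq_len(n_tm)) {
      n_hel <- sample(1:7, 1)
      segs <- character(2 * n_hel + 1)
      helix <- matrix(0L, n_hel, 2)
      pos <- 0L
      segs[1] <- .rand_seq(sample(20:60, 1), config$background)
      pos <- nchar(segs[1])
      for (h in seq_len(n_hel)) {
        hl <- sample(19:21, 1)
        helix[h, ] <- c(pos + 1L, pos + hl)
        segs[2 * h] <- paste(sample(c("I", "L", "V", "F"), hl, TRUE),
                             collapse = "")
        segs[2 * h + 1] <- .rand_seq(sample(15:50, 1), config$background)
        pos <- pos + hl + nchar(segs[2 * h + 1])
      }
      colnames(helix) <- c("start", "end")
      add(.scrub_kdel(paste(segs, collapse = "")), "membrane", FALSE, 0L,
          format_helices(helix))
    }
    ## background proteins
    for (k in seq_len(n_bg)) {
      add(.scrub_kdel(.rand_seq(sample(120:800, 1), config$background)),
          "background", FALSE, 0L, "")
    }
    out <- .rbind_df(rows[seq_len(j)])
    out$species <- sp_name
    out
  })
  all <- do.call(rbind, per_species)
  proteins <- data.frame(protein_id = all$protein_id, species = all$species,
                         sequence = all$sequence,
                         length = nchar(all$sequence),
                         stringsAsFactors = FALSE)
  has_sp <- all$class %in% c("secreted", "er_retained")
  evidence <- data.frame(
    protein_id = all$protein_id,
    sp_present = has_sp,
    sp_cleavage_pos = ifelse(has_sp, all$cleavage, 0L),
    sp_dscore = ifelse(has_sp, 0.85, 0.1),
    tm_n_helices = lengths(regmatches(all$tm_helices,
                                      gregexpr("-", all$tm_helices))),
    tm_helices = all$tm_helices,
    targetp_loc = ifelse(has_sp, "S", ifelse(all$class == "membrane",
                                             "M", "O")),
    wolfpsort_top = ifelse(has_sp, "extr 21, mito 4",
                           ifelse(all$class == "membrane",
                                  "plas 19, cyto 8", "cyto 22, nucl 5")),
    kdel_cterm = scan_cterm_retention(all$sequence, mode = "ps00014"),
    stringsAsFactors = FALSE)
  truth <- data.frame(protein_id = all$protein_id, species = all$species,
                      class = all$class, secreted = all$secreted,
                      ssp = all$secreted & nchar(all$sequence) < 300L,
                      family_id = all$family_id, stringsAsFactors = FALSE)
  list(proteins = proteins, evidence = evidence, truth = truth,
       registry = registry, families = families, config = config)
}

#' Generate synthetic reference hit tables
#'
#' Assigns, per species, an exact (rounded) number of the true secreted
#' proteins to each enzymatic category and emits a matching best hit below
#' the e-value cutoff; PFAM accessions from a pool are then scattered over
#' secreted proteins at a background rate, multiplied per
#' (lifestyle, accession) by the requested enrichment factors.
#'
#' @param sim Result of [generate_proteome()].
#' @param category_rates Named fractions of true secreted proteins planted
#'   per category (`CAZyme`, `Protease`, `Lipase`); must sum to at most 1.
#' @param pfam_pool Accession pool for the background scatter.
#' @param background_pfam_rate Per-accession presence probability.
#' @param domain_enrichment Optional data.frame (`lifestyle`, `pfam`,
#'   `multiplier`) of per-lifestyle rate multipliers; lifestyle refers to
#'   the registry label of the synthetic species.
#' @param seed Integer seed.
#' @return A hit table (`protein_id`, `database`, `subject_label`,
#'   `evalue`, `bitscore`) and, as attribute `"planted"`, the per-protein
#'   planted category.
#' @export
generate_hit_tables <- function(sim,
                                category_rates = c(CAZyme = 0.15,
                                                   Protease = 0.07,
                                                   Lipase = 0.03),
                                pfam_pool = sprintf("PF%05d", 1:20),
                                background_pfam_rate = 0.05,
                                domain_enrichment = NULL, seed = 1L) {
  if (sum(category_rates) > 1) stop("category_rates must sum to at most 1")
  set.seed(seed)
  labels <- list(
    CAZyme = list(db = "CAZy",
                  subj = c("GH5", "GH16", "GH18", "GH25", "GH61", "GH3")),
    Protease = list(db = "MEROPS",
                    subj = c("A01", "M36", "S53", "S28", "S08", "S09", "M28")),
    Lipase = list(db = "LED",
                  subj = c("GGGX.carboxylesterase",
                           "GGGX.Candida-rugosa-lipase-like",
                           "GX.thioesterase", "GX.lysophospholipase",
                           "GX.filamentous-fungal-lipase")))
  sec <- sim$truth[sim$truth$secreted, , drop = FALSE]
  hit_rows <- list()
  planted <- setNames(rep("none", nrow(sec)), sec$protein_id)
  for (sp in unique(sec$species)) {
    ids <- sec$protein_id[sec$species == sp]
    n <- length(ids)
    offset <- 0L
    for (catg in names(category_rates)) {
      k <- round(category_rates[[catg]] * n)
      if (k == 0) next
      take <- ids[(offset + 1):(offset + k)]
      offset <- offset + k
      info <- labels[[catg]]
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        protein_id = take, database = info$db,
        subject_label = sample(info$subj, k, TRUE),
        evalue = 10^-stats::runif(k, 6, 40),
        bitscore = round(stats::runif(k, 60, 400), 1),
        stringsAsFactors = FALSE)
      planted[take] <- catg
    }
  }
  ## PFAM scatter with per-lifestyle enrichment multipliers
  lifestyles <- sim$registry$lifestyle[match(sec$species, sim$registry$name)]
  for (dm in pfam_pool) {
    rate <- rep(background_pfam_rate, nrow(sec))
    if (!is.null(domain_enrichment)) {
      de <- domain_enrichment[domain_enrichment$pfam == dm, , drop = FALSE]
      for (r in seq_len(nrow(de))) {
        rate[lifestyles == de$lifestyle[r]] <-
          background_pfam_rate * de$multiplier[r]
      }
    }
    has <- stats::runif(nrow(sec)) < rate
    if (!any(has)) next
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      protein_id = sec$protein_id[has], database = "PFAM",
      subject_label = dm, evalue = 10^-stats::runif(sum(has), 6, 40),
      bitscore = round(stats::runif(sum(has), 30, 200), 1),
      stringsAsFactors = FALSE)
  }
  hits <- .rbind_df(hit_rows)
  if (is.null(hits)) {
    hits <- data.frame(protein_id = character(), database = character(),
                       subject_label = character(), evalue = numeric(),
                       bitscore = numeric(), stringsAsFactors = FALSE)
  }
  attr(hits, "planted") <- planted
  hits
}
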