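# Small builders for in-code fixtures.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(aa20, n, replace = TRUE), collapse = "")

make_protein <- function(protein_id, sequence, species = "spA") {
  data.frame(protein_id = protein_id, species = species,
             sequence = sequence, length = nchar(sequence),
             stringsAsFactors = FALSE)
}

# One evidence row with all-pass defaults; individual criteria are broken
# through the arguments.
make_evidence <- function(protein_id, sp_present = TRUE,
                          sp_cleavage_pos = if (sp_present) 18L else 0L,
                          tm_helices = "", targetp_loc = "S",
                          wolfpsort_top = "extr 20, cyto 5",
                          kdel_cterm = FALSE) {
  data.frame(protein_id = protein_id, sp_present = sp_present,
             sp_cleavage_pos = sp_cleavage_pos, sp_dscore = 0.7,
             tm_n_helices = lengths(regmatches(tm_helices,
                                               gregexpr("-", tm_helices))),
             tm_helices = tm_helices, targetp_loc = targetp_loc,
             wolfpsort_top = wolfpsort_top, kdel_cterm = kdel_cterm,
             stringsAsFactors = FALSE)
}

make_hits <- function(protein_id, database, subject_label, evalue,
                      bitscore = 100) {
  data.frame(protein_id = protein_id, database = database,
             subject_label = subject_label, evalue = evalue,
             bitscore = rep(bitscore, length.out = length(protein_id)),
             stringsAsFactors = FALSE)
}
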