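test_that("FASTA reading strips stops, uppercases and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1 some description", "MKKL*", ">p2", "mkvl", "aaX"), f)
  p <- read_fasta(f, species = "spA")
  expect_equal(p$protein_id, c("p1", "p2"))
  expect_equal(p$sequence, c("MKKL", "MKVLAAX"))
  expect_equal(p$length, c(4L, 7L))

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(p, out)
  p2 <- read_fasta(out, species = "spA")
  expect_identical(p, p2)
})

test_that("FASTA edge cases: empty file and sequence before header", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), f)
  expect_equal(nrow(read_fasta(f)), 0L)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("MKKL", ">p1", "MKVL"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("species registry validation enforces the closed lifestyle set", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tlifestyle\tphylum\tfamily",
               "Fungus unus\tWhite rot\tBasidiomycota\tFamA",
               "Fungus duo\tUnknown\tBasidiomycota\tFamB"), f)
  expect_error(load_species_registry(f), "Unknown.*allowed|allowed")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tlifestyle\tphylum\tfamily",
               "Fungus unus\tWhite rot\tBasidiomycota\tFamA",
               "Fungus unus\tBrown rot\tBasidiomycota\tFamB"), f2)
  expect_error(load_species_registry(f2), "duplicate")
})

test_that("packaged registry has the printed species census", {
  reg <- species_registry()
  expect_equal(nrow(reg), 49L)
  expect_equal(sum(reg$lifestyle == "Ectomycorrhizal"), 11L)
  expect_equal(sum(reg$lifestyle == "White rot"), 12L)
  expect_equal(sum(reg$lifestyle == "Brown rot"), 8L)
  expect_equal(anyDuplicated(reg$name), 0L)
})

test_that("predictor dialect parsers handle the documented formats", {
  sp <- withr::local_tempfile()
  writeLines(c("# SignalP-4.1 euk predictions",
               "# name Cmax pos Ymax pos Smax pos Smean D ? Dmaxcut Networks-used",
               "p1 0.87 19 0.88 19 0.95 10 0.90 0.89 Y 0.450 SignalP-noTM",
               "p2 0.10 2 0.10 2 0.12 1 0.10 0.10 N 0.450 SignalP-noTM",
               "p3 0.70 23 0.71 23 0.80 12 0.75 0.73 Y 0.450 SignalP-TM"), sp)
  s <- parse_signalp(sp)
  expect_equal(s$sp_present, c(TRUE, FALSE, TRUE))
  # cleavage stored as last residue of the signal peptide (Ymax pos - 1)
  expect_equal(s$sp_cleavage_pos, c(18L, 0L, 22L))
  expect_equal(s$sp_dscore, c(0.89, 0.10, 0.73))

  tm <- withr::local_tempfile()
  writeLines(c("p1\tlen=120\tExpAA=0.10\tFirst60=0.02\tPredHel=0\tTopology=o",
               "p2\tlen=300\tExpAA=44.1\tFirst60=1.2\tPredHel=2\tTopology=i7-29o44-66i",
               "p3\tlen=200\tExpAA=21.0\tFirst60=19.9\tPredHel=1\tTopology=i5-27o"), tm)
  t <- parse_tmhmm(tm)
  expect_equal(t$tm_n_helices, c(0L, 2L, 1L))
  expect_equal(t$tm_helices, c("", "7-29;44-66", "5-27"))
  expect_equal(parse_helices("7-29;44-66")[[1]],
               matrix(c(7L, 44L, 29L, 66L), ncol = 2,
                      dimnames = list(NULL, c("start", "end"))))

  tp <- withr::local_tempfile()
  writeLines(c("### targetp v1.1 prediction results",
               "Name    Len   mTP  SP  other  Loc  RC",
               "----------------------------------------",
               "p1      120  0.05 0.95 0.02   S    1",
               "p2      300  0.80 0.05 0.10   M    2",
               "p3      200  0.10 0.20 0.70   _    3"), tp)
  p <- parse_targetp(tp)
  expect_equal(p$targetp_loc, c("S", "M", "O"))

  wp <- withr::local_tempfile()
  writeLines(c("# k used for kNN is: 27",
               "p1 extr 21, mito 4, nucl 2",
               "p2 cyto 15, nucl 10",
               "p3 extr 12, plas 12, cyto 3"), wp)
  w <- parse_wolfpsort(wp)
  expect_equal(wolfpsort_top_labels(w$wolfpsort_top),
               list("extr", "cyto", c("extr", "plas")))

  ev <- parse_predictor_outputs(sp, tm, tp, wp)
  expect_equal(nrow(ev), 3L)
  expect_equal(ev$protein_id, c("p1", "p2", "p3"))
})

test_that("proteins missing from one predictor output are excluded with a warning", {
  sp <- withr::local_tempfile()
  writeLines(c("p1 0.9 19 0.9 19 0.9 10 0.9 0.9 Y 0.45 SignalP-noTM",
               "p2 0.1 2 0.1 2 0.1 1 0.1 0.1 N 0.45 SignalP-noTM"), sp)
  tm <- withr::local_tempfile()
  writeLines(c("p1 len=120 ExpAA=0.1 First60=0.0 PredHel=0 Topology=o",
               "p2 len=90 ExpAA=0.1 First60=0.0 PredHel=0 Topology=o"), tm)
  tp <- withr::local_tempfile()
  writeLines(c("p1 120 0.05 0.95 0.02 S 1"), tp)  # p2 missing here
  wp <- withr::local_tempfile()
  writeLines(c("p1 extr 21, mito 4", "p2 cyto 20"), wp)
  expect_warning(ev <- parse_predictor_outputs(sp, tm, tp, wp), "p2")
  expect_equal(ev$protein_id, "p1")

  tp2 <- withr::local_tempfile()
  writeLines(c("q9 120 0.05 0.95 0.02 S 1"), tp2)
  expect_error(suppressWarnings(parse_predictor_outputs(sp, tm, tp2, wp)),
               "no protein identifiers")
})

test_that("malformed predictor lines are reported with their line number", {
  sp <- withr::local_tempfile()
  writeLines(c("p1 0.9 19 0.9 19 0.9 10 0.9 0.9 Y 0.45 SignalP-noTM",
               "p2 garbage"), sp)
  expect_error(parse_signalp(sp), "line 2")
  tm <- withr::local_tempfile()
  writeLines("p1 len=120 PredHel=2 Topology=i7-29o", tm)
  expect_error(parse_tmhmm(tm), "line 1")
})

test_that("cluster fixture expands printed abbreviations against the registry", {
  reg <- species_registry()
  cl <- load_cluster_fixture(reg)
  expect_equal(nrow(cl), 25L)
  expect_equal(lengths(cl$members), cl$n_species)
  expect_true(all(unlist(cl$members) %in% reg$name))
  # every member maps to exactly one registry record
  expect_equal(anyDuplicated(reg$name), 0L)
  expect_equal(length(cl$members[[which(cl$cluster_id == 92)]]), 5L)
  expect_equal(length(cl$members[[which(cl$cluster_id == 0)]]), 21L)
  expect_equal(cl$length_min[cl$cluster_id == 0], 179L)
  expect_equal(cl$length_max[cl$cluster_id == 0], 186L)
})
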