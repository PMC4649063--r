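test_that("global identity handles the boundary cases", {
  s <- random_aa(100)
  r <- global_identity(s, s)
  expect_equal(r$identity, 1)
  expect_equal(r$denominator, 100L)

  r2 <- global_identity("AAAA", "TTTT")
  expect_equal(r2$identity, 0)

  # a single internal deletion: all residues of the shorter sequence match
  r3 <- global_identity("MKKLLAV", "MKKLAV")
  expect_equal(r3$aligned_matches, 6L)
  expect_equal(r3$denominator, 6L)
  expect_equal(r3$identity, 1)

  expect_error(global_identity("", "AAAA"), "non-empty")
})

test_that("identity is symmetric and X never counts as a match", {
  set.seed(7)
  for (i in 1:8) {
    a <- random_aa(sample(30:80, 1))
    b <- random_aa(sample(30:80, 1))
    ra <- global_identity(a, b)
    rb <- global_identity(b, a)
    expect_equal(ra$identity, rb$identity)
    expect_equal(ra$aligned_matches, rb$aligned_matches)
  }
  expect_equal(global_identity("AXAX", "AXAX")$aligned_matches, 2L)
  expect_equal(global_identity(strrep("X", 10), strrep("X", 10))$identity, 0)
})

test_that("identity agrees with exhaustive alignment enumeration on tiny sequences", {
  set.seed(19)
  cases <- list(c("MKKLLA", "MKKLA"), c("MKVLAV", "MKVLAV"),
                c("ACDEFG", "ACDFG"), c("WWYYHH", "HHYYWW"))
  for (i in 1:6) {
    cases[[length(cases) + 1]] <- c(random_aa(sample(4:6, 1)),
                                    random_aa(sample(4:6, 1)))
  }
  for (cs in cases) {
    got <- global_identity(cs[1], cs[2])
    oracle <- enumerate_global_alignment(cs[1], cs[2])
    # the implementation must realize an optimal alignment's match count
    expect_true(got$aligned_matches %in% oracle$matches,
                info = paste(cs, collapse = " vs "))
    expect_equal(got$identity,
                 got$aligned_matches / min(nchar(cs[1]), nchar(cs[2])))
  }
})

test_that("greedy clustering groups identical sequences and respects the threshold", {
  s <- random_aa(120)
  p <- rbind(make_protein("a1", s, "sp1"), make_protein("b1", s, "sp2"),
             make_protein("c1", s, "sp3"))
  cl <- greedy_cluster(p)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$n_species, 3L)
  expect_equal(cl$clusters$cluster_id, 0L)

  # two sequences just below the threshold stay apart (strict >= rule)
  base <- strrep("ACDEFGHIKL", 10)                     # 100 aa
  mut <- paste0(strrep("ACDEFGHIKL", 6),               # 60 identical
                paste(rep("W", 40), collapse = ""))    # 40 mismatched
  id <- global_identity(base, mut)$identity
  expect_lt(id, 0.70)
  p2 <- rbind(make_protein("a", base, "sp1"), make_protein("b", mut, "sp2"))
  expect_equal(nrow(greedy_cluster(p2, 0.70)$clusters), 2L)
  expect_equal(nrow(greedy_cluster(p2, id)$clusters), 1L)
})

test_that("a planted family clusters together while unrelated sequences stay apart", {
  fam <- plant_ssp_family(150, 6, paste0("sp", 1:6), 0.85, seed = 31)
  rand <- do.call(rbind, lapply(1:4, function(i) {
    make_protein(paste0("r", i), random_aa(150), paste0("sp", i))
  }))
  prots <- rbind(
    data.frame(protein_id = fam$members$protein_id,
               species = fam$members$species,
               sequence = fam$members$sequence,
               length = nchar(fam$members$sequence),
               stringsAsFactors = FALSE),
    rand)
  cl <- greedy_cluster(prots, 0.70)
  expect_equal(nrow(cl$clusters), 5L)  # one family + four singletons
  fam_cl <- cl$members$cluster_id[cl$members$protein_id %in%
                                    fam$members$protein_id]
  expect_equal(length(unique(fam_cl)), 1L)
  expect_equal(sum(cl$clusters$n_members), nrow(prots))
})

test_that("clustering is invariant to input order and monotone in the threshold", {
  set.seed(5)
  fam1 <- plant_ssp_family(100, 4, paste0("sp", 1:4), 0.9)
  fam2 <- plant_ssp_family(140, 3, paste0("sp", 1:3), 0.8)
  prots <- rbind(
    data.frame(protein_id = paste0("f1_", 1:4), species = fam1$members$species,
               sequence = fam1$members$sequence,
               length = nchar(fam1$members$sequence), stringsAsFactors = FALSE),
    data.frame(protein_id = paste0("f2_", 1:3), species = fam2$members$species,
               sequence = fam2$members$sequence,
               length = nchar(fam2$members$sequence), stringsAsFactors = FALSE),
    do.call(rbind, lapply(1:5, function(i) {
      make_protein(paste0("r", i), random_aa(sample(80:200, 1)), "spX")
    })))
  cl <- greedy_cluster(prots, 0.70)
  for (perm in 1:3) {
    clp <- greedy_cluster(prots[sample(nrow(prots)), ], 0.70)
    expect_identical(cl$members, clp$members)
    expect_identical(cl$clusters, clp$clusters)
  }
  n_clusters <- vapply(c(0.5, 0.7, 0.9, 1.0), function(th) {
    nrow(greedy_cluster(prots, th)$clusters)
  }, numeric(1))
  expect_true(all(diff(n_clusters) >= 0))
})

test_that("representatives are longest members and filtering keeps ids", {
  set.seed(13)
  fam <- plant_ssp_family(120, 5, paste0("sp", 1:5), 0.9)
  prots <- data.frame(protein_id = fam$members$protein_id,
                      species = fam$members$species,
                      sequence = fam$members$sequence,
                      length = nchar(fam$members$sequence),
                      stringsAsFactors = FALSE)
  prots <- rbind(prots, make_protein("solo", random_aa(90), "sp9"))
  cl <- greedy_cluster(prots)
  for (i in seq_len(nrow(cl$clusters))) {
    m <- cl$members[cl$members$cluster_id == cl$clusters$cluster_id[i], ]
    expect_true(cl$clusters$representative[i] %in% m$protein_id)
    expect_equal(max(m$length), m$length[m$protein_id ==
                                           cl$clusters$representative[i]])
  }
  f <- filter_clusters(cl, min_species = 3)
  expect_equal(f$clusters$cluster_id, 0L)   # ids preserved, singleton dropped
  # species count, not member count, is what is filtered
  same_sp <- do.call(rbind, lapply(1:3, function(i) {
    make_protein(paste0("s", i), fam$members$sequence[i], "only_one")
  }))
  cl2 <- greedy_cluster(same_sp)
  expect_equal(nrow(filter_clusters(cl2, 3)$clusters), 0L)
})

test_that("species-specific SSP detection ignores intra-species similarity", {
  s <- random_aa(150)
  p <- rbind(make_protein("a", s, "sp1"),
             make_protein("b", s, "sp2"),
             make_protein("c", random_aa(150), "sp1"),
             make_protein("d", random_aa(140), "sp2"))
  sp <- species_specific_ssps(p)
  expect_false("a" %in% sp)
  expect_false("b" %in% sp)
  expect_true(all(c("c", "d") %in% sp))

  # identical SSPs in the SAME species only remain species-specific
  p2 <- rbind(make_protein("a", s, "sp1"), make_protein("b", s, "sp1"),
              make_protein("d", random_aa(140), "sp2"))
  expect_true(all(c("a", "b") %in% species_specific_ssps(p2)))

  expect_warning(r <- species_specific_ssps(p2[1:2, ]), "single-species")
  expect_equal(r, c("a", "b"))
})
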