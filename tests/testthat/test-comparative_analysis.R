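test_that("lifestyle profiles classify fixture clusters as printed", {
  reg <- species_registry()
  cl <- load_cluster_fixture(reg)
  pr <- lifestyle_profiles(cl, reg)

  expect_equal(pr$specificity[pr$cluster_id == 92], "ECM_only")
  expect_equal(pr$specificity[pr$cluster_id == 16], "saprotroph_only")
  expect_equal(pr$specificity[pr$cluster_id == 0], "shared_ECM_saprotroph")
  # section headings of the fixture agree with the computed specificity
  map <- c(ecm_only = "ECM_only", ecm_saprotroph = "shared_ECM_saprotroph",
           saprotroph_only = "saprotroph_only")
  expect_equal(pr$specificity, unname(map[cl$section]))
})

test_that("clusters outside the declared groups fall into the other bucket", {
  reg <- data.frame(name = c("pat1", "pat2", "ecm1"),
                    lifestyle = c("Pathogen", "Pathogen", "Ectomycorrhizal"),
                    phylum = "x", family = "y", stringsAsFactors = FALSE)
  p <- lifestyle_profile(c("pat1", "pat2"), reg)
  expect_equal(p$specificity, "other")
  expect_equal(p$region, character(0))
  # ECM mixed with an out-of-scope lifestyle is not ECM_only
  p2 <- lifestyle_profile(c("ecm1", "pat1"), reg)
  expect_equal(p2$specificity, "other")
  expect_error(lifestyle_profile("nope", reg), "absent from registry")
})

test_that("venn partition counts every in-scope profile exactly once", {
  profs <- data.frame(
    cluster_id = 1:4,
    lifestyles = c("ECM", "white_rot", "ECM+white_rot", "other"),
    region = c("ECM", "white_rot", "ECM+white_rot", ""),
    specificity = c("ECM_only", "saprotroph_only", "shared_ECM_saprotroph",
                    "other"),
    stringsAsFactors = FALSE)
  v <- venn_partition(profs)
  expect_equal(sum(v$n_clusters), 3L)  # the empty-region profile is excluded
  expect_equal(sort(v$region), c("ECM", "ECM+white_rot", "white_rot"))
  expect_equal(v$n_clusters[v$region == "ECM"], 1L)

  reg <- species_registry()
  pr <- lifestyle_profiles(load_cluster_fixture(reg), reg)
  vf <- venn_partition(pr)
  expect_equal(sum(vf$n_clusters), nrow(pr))       # conservation
  expect_equal(vf$n_clusters[vf$region == "ECM"], 17L)
})

test_that("enrichment p-values equal the hypergeometric tail and fisher.test", {
  set.seed(23)
  for (i in 1:200) {
    n1 <- sample(0:25, 1)
    n2 <- sample(0:25, 1)
    a <- if (n1 > 0) sample(0:n1, 1) else 0L
    c <- if (n2 > 0) sample(0:n2, 1) else 0L
    p <- enrichment_pvalue(a, n1 - a, c, n2 - c)
    expect_equal(p, hyper_tail_oracle(a, n1 - a, c, n2 - c),
                 tolerance = 1e-12)
    if (n1 > 0 && n2 > 0 && a + c > 0 && a + c < n1 + n2) {
      ft <- fisher.test(matrix(c(a, n1 - a, c, n2 - c), 2, byrow = TRUE),
                        alternative = "greater")
      expect_equal(p, unname(ft$p.value), tolerance = 1e-9)
    }
  }
  # degenerate margins are not errors
  expect_equal(enrichment_pvalue(0, 0, 5, 7), 1)
  expect_equal(enrichment_pvalue(3, 4, 0, 0), 1)
  expect_equal(enrichment_pvalue(5, 0, 7, 0), 1)   # domain everywhere
})

test_that("a planted over-represented domain is the top enrichment", {
  sim <- generate_proteome(simulation_config(
    seed = 41, n_species = 4,
    lifestyles = c("Ectomycorrhizal", "White rot", "Brown rot",
                   "Litter decayers"),
    proteome_size = 2500, secreted_fraction = 0.2))
  enr <- data.frame(lifestyle = "Ectomycorrhizal", pfam = "PF00007",
                    multiplier = 10, stringsAsFactors = FALSE)
  hits <- generate_hit_tables(sim, domain_enrichment = enr, seed = 17)
  dec <- decide_secreted(sim$evidence, sim$proteins)
  ann <- annotate_secretome(dec, sim$proteins, hits)
  res <- pfam_enrichment(ann, sim$registry, "ECM")
  expect_equal(res$pfam[1], "PF00007")
  expect_true(res$enriched[1])
  expect_true(all(res$adjusted_p >= res$p_value))
  # contingency conservation: each tested table covers all secreted proteins
  expect_true(all(res$a + res$b + res$c + res$d == nrow(ann)))
})

test_that("a domain present in every protein is never enriched", {
  ann <- data.frame(species = rep(c("s1", "s2"), each = 10),
                    pfam_domains = "PF11111", stringsAsFactors = FALSE)
  reg <- data.frame(name = c("s1", "s2"),
                    lifestyle = c("Ectomycorrhizal", "White rot"),
                    phylum = "x", family = "y", stringsAsFactors = FALSE)
  res <- pfam_enrichment(ann, reg, "ECM")
  expect_equal(res$p_value, 1)
  expect_false(res$enriched)
})

test_that("Holm adjustment is monotone, conservative and order-invariant", {
  set.seed(29)
  p <- runif(15)^2
  adj <- p.adjust(p, "holm")
  expect_equal(adj, holm_oracle(p))
  expect_true(all(adj >= p))
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  perm <- sample(15)
  expect_equal(p.adjust(p[perm], "holm"), adj[perm])
})

test_that("SSP proportion comparisons separate distinct groups and not identical ones", {
  mk_summary <- function(ssp_pcts, lifestyles) {
    n <- length(ssp_pcts)
    data.frame(species = sprintf("s%02d", 1:n),
               proteome_size = 1000L, secretome_size = 100L,
               ssp_count = round(ssp_pcts), specific_ssp_count = 10L,
               stringsAsFactors = FALSE)
  }
  mk_registry <- function(lifestyles) {
    n <- length(lifestyles)
    data.frame(name = sprintf("s%02d", 1:n), lifestyle = lifestyles,
               phylum = "x", family = "y", stringsAsFactors = FALSE)
  }
  # clearly separated groups: means 30 vs 15, small spread, n = 8 each
  set.seed(37)
  v <- c(30 + round(rnorm(8, 0, 2)), 15 + round(rnorm(8, 0, 2)))
  ls <- rep(c("Ectomycorrhizal", "White rot"), each = 8)
  st <- ssp_proportion_stats(mk_summary(v, ls), mk_registry(ls))
  expect_lt(st$t_pvalues["White rot", "Ectomycorrhizal"], 0.01)
  expect_false(st$letters[["Ectomycorrhizal"]] ==
                 st$letters[["White rot"]])

  # identical groups: p = 1 and a shared letter
  v2 <- rep(c(20, 22, 24, 26, 21, 23, 25, 27), 2)
  st2 <- ssp_proportion_stats(mk_summary(v2, ls), mk_registry(ls))
  expect_equal(unname(st2$t_pvalues["White rot", "Ectomycorrhizal"]), 1)
  expect_equal(st2$letters[["Ectomycorrhizal"]], st2$letters[["White rot"]])

  # fewer than two qualifying lifestyles is an error
  ls3 <- c(rep("Ectomycorrhizal", 8), rep("White rot", 2))
  expect_error(ssp_proportion_stats(mk_summary(v[1:10], ls3),
                                    mk_registry(ls3)),
               "fewer than two")
})

test_that("size correlation matches the closed-form Pearson computation", {
  reg <- data.frame(name = sprintf("s%02d", 1:10),
                    lifestyle = rep("White rot", 10),
                    phylum = "x", family = "y", stringsAsFactors = FALSE)
  # perfectly linear
  s1 <- data.frame(species = reg$name, proteome_size = 1000 * (1:10),
                   secretome_size = 50 * (1:10), stringsAsFactors = FALSE)
  expect_equal(size_correlation(s1, reg)$r_squared, 1)
  # orthogonal by construction (r = 0)
  x <- c(-2, -1, 0, 1, 2)
  y <- c(1, -1, 0, -1, 1) # even function: cov = 0
  reg5 <- reg[1:5, ]
  s2 <- data.frame(species = reg5$name, proteome_size = x + 10,
                   secretome_size = y + 5, stringsAsFactors = FALSE)
  expect_equal(size_correlation(s2, reg5)$r_squared, 0)
  # noisy linear data against the sum-formula oracle
  set.seed(11)
  px <- round(runif(10, 5000, 20000))
  py <- round(0.06 * px + rnorm(10, 0, 80))
  s3 <- data.frame(species = reg$name, proteome_size = px,
                   secretome_size = py, stringsAsFactors = FALSE)
  expect_equal(size_correlation(s3, reg)$r_squared,
               pearson_oracle(px, py)^2, tolerance = 1e-12)
  # zero variance is reported as missing, not an error
  s4 <- data.frame(species = reg$name, proteome_size = 7000,
                   secretome_size = 50 * (1:10), stringsAsFactors = FALSE)
  expect_true(is.na(size_correlation(s4, reg)$r))
})
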