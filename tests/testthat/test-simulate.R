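# The synthetic-data generators and their planted-truth contracts.

small_config <- function(...) {
  simulation_config(n_genes = 300L, n_chromosomes = 4L, n_families = 3L,
                    family_size = 12L, cluster_sizes = c(3L, 2L),
                    n_mutants = 6L, background_disruption_rate = 0,
                    ...)
}

test_that("planted clusters are exactly recovered by detection", {
  for (seed in c(2L, 13L, 27L)) {
    g <- simulate_genome(small_config(seed = seed))
    for (fam in names(g$families)) {
      p <- detect_clusters(g$annotation, g$families[[fam]], fam)
      planted <- g$truth$families[[fam]]
      # detection orders runs by genomic position; compare as sets of runs
      expect_setequal(vapply(p$clusters, function(x) paste(sort(x), collapse = "+"), ""),
                      vapply(planted$clusters, function(x) paste(sort(x), collapse = "+"), ""))
      expect_setequal(p$singletons, planted$singletons)
      expect_length(p$unplaced, 0L)
    }
  }
})

test_that("generation is deterministic: same seed, same bytes", {
  cfg <- small_config(seed = 8L)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)

  f1 <- tempfile(); f2 <- tempfile()
  write_bed(g1$annotation, f1); write_bed(g2$annotation, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  write_gmt(g1$families, f1); write_gmt(g2$families, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  c1 <- simulate_compendium(g1, cfg)
  c2 <- simulate_compendium(g2, cfg)
  expect_identical(c1$compendium$values, c2$compendium$values)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(families = list(
    list(name = "f", size = 4L, cluster_sizes = c(3L, 2L)))), "exceed")
  expect_error(simulation_config(families = list(
    list(name = "f", size = 4L, cluster_sizes = 1L))), ">= 2")
  expect_error(simulation_config(n_genes = 10L, n_families = 2L,
                                 family_size = 8L), "exceed")
  # genome too small to separate the family members
  tight <- simulation_config(n_genes = 8L, n_chromosomes = 1L,
                             families = list(list(name = "f", size = 8L,
                                                  cluster_sizes = c(2L, 2L))),
                             seed = 1L)
  expect_error(simulate_genome(tight), "increase n_genes")
})

test_that("planted compendium effects land on the recorded cells", {
  g <- simulate_genome(small_config(seed = 5L))
  fam <- names(g$families)[1L]
  planted <- data.frame(mutant = "mut001", family = fam,
                        target = "clustered", effect = 2, penetrance = 1)
  cfg <- small_config(seed = 5L, planted_disruptions = planted)
  sim <- simulate_compendium(g, cfg)
  cells <- sim$truth$planted_cells
  clustered <- unlist(g$truth$families[[fam]]$clusters)
  expect_setequal(cells$gene, clustered)
  expect_true(all(abs(cells$shift) == 2))
  # each hit gene moved by its recorded shift beyond baseline noise
  vals <- sim$compendium$values["mut001", cells$gene]
  expect_true(all(abs(vals - cells$shift) < 4 * cfg$noise_sd))

  # penetrance 0 leaves the compendium identical to the unplanted one
  cfg0 <- small_config(seed = 5L, planted_disruptions = transform(planted, penetrance = 0))
  base <- small_config(seed = 5L)
  expect_identical(simulate_compendium(g, cfg0)$compendium$values,
                   simulate_compendium(g, base)$compendium$values)
})

test_that("time-course latent structure matches the requested correlations", {
  # rho_cluster = 1: all genes of a cluster share the latent exactly
  # (single-cluster family, so pooling adds no cross-cluster pairs)
  cfg1 <- simulation_config(
    n_genes = 200L, n_chromosomes = 2L,
    families = list(list(name = "f", size = 10L, cluster_sizes = 5L)),
    rho_cluster = 1, rho_singleton = 0, stressors = "only", seed = 6L)
  parts <- truth_partitions(simulate_genome(cfg1))
  tc <- simulate_timecourses(parts, cfg1)$timecourses[[1L]]
  res <- subset_coherence(tc, parts[[1L]])
  expect_equal(res$pcc_clustered, 1, tolerance = 1e-10)

  # rho_cluster = rho_singleton: deviation centred on zero over replicates.
  # A single-cluster family keeps the comparison symmetric (with several
  # clusters, cross-cluster pairs dilute the pooled clustered PCC).
  one_cluster <- simulation_config(
    n_genes = 200L, n_chromosomes = 2L,
    families = list(list(name = "f", size = 10L, cluster_sizes = 5L)),
    rho_cluster = 0.4, rho_singleton = 0.4,
    stressors = sprintf("rep%02d", 1:40), seed = 7L)
  gp <- truth_partitions(simulate_genome(one_cluster))
  sim <- simulate_timecourses(gp, one_cluster)
  panel <- coherence_panel(sim$timecourses, gp)
  dev <- deviation_matrix(panel$clustered, panel$singleton)
  expect_lt(abs(mean(dev)), 0.12)

  # truth records the realized latents
  expect_named(sim$truth$latents, sprintf("rep%02d", 1:40))
})

test_that("synthetic Ct tables round-trip through the ddCt path", {
  lf <- c(BIO4 = 2, BIO3 = -1, FLAT = 0)
  sim <- simulate_ct_table(names(lf), lf, reference_gene = "ACT1",
                           noise_sd = 0, bio_sd = 0, seed = 2L)
  res <- qpcr_panel(sim$table, "ACT1", test = "mutant", control = "WT")
  expect_equal(setNames(res$log2_fold, res$gene), lf)
  expect_equal(res$fold_change, 2^lf, ignore_attr = TRUE)
})
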