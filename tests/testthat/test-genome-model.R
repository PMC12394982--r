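# Annotation parsing, cluster detection and the permutation null.

test_that("BED loading builds per-chromosome ranks and validates input", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrI\t4000\t5000\tg3\t0\t-",
               "chrI\t0\t1000\tg1\t0\t+",
               "chrI\t2000\t3000\tg2\t0\t+"), bed)
  ann <- load_annotation(bed)
  expect_equal(ann$gene_id, c("g1", "g2", "g3"))
  expect_equal(ann$rank, 0:2)
  expect_equal(ann$strand, c("+", "+", "-"))

  writeLines(c("chrI\t0\t1000\tg1", "chrI\t2000\t3000\tg1"), bed)
  expect_error(load_annotation(bed), "duplicated gene_id")

  writeLines(c("chrI\t0\t1000\tg1", "chrI\t5000"), bed)
  expect_error(load_annotation(bed), "line 2")

  expect_error(genome_annotation(data.frame(
    gene_id = "g1", chrom = "chrI", start = 10L, end = 10L)), "start")

  writeLines(character(), bed)
  expect_warning(ann0 <- load_annotation(bed), "empty")
  expect_equal(nrow(ann0), 0L)
})

test_that("GMT families round-trip and malformed lines are rejected", {
  gmt <- tempfile(fileext = ".gmt")
  fams <- list(vmp = c("BIO5", "BIO4", "BIO3", "BIO2"),
               ribi = c("MPP10", "MRX12", "EBP2"))
  write_gmt(fams, gmt)
  expect_equal(read_gmt(gmt), fams)

  writeLines("lonely\tdesc", gmt)
  expect_error(read_gmt(gmt), "malformed GMT line 1")
})

test_that("cluster detection returns maximal runs and a complete partition", {
  ann <- toy_annotation(10L)

  # consecutive ranks -> one run, no singletons
  p <- detect_clusters(ann, c("g3", "g4", "g5"), "tri")
  expect_equal(p$clusters, list(c("g3", "g4", "g5")))
  expect_length(p$singletons, 0L)

  # different chromosomes -> all singletons
  ann2 <- toy_annotation(10L, n_chrom = 2L)
  p2 <- detect_clusters(ann2, c("g1", "g9"), "split")
  expect_length(p2$clusters, 0L)
  expect_setequal(p2$singletons, c("g1", "g9"))

  # ranks 1, 3, 7 with max_intervening = 1 -> pair + singleton
  p3 <- detect_clusters(ann, c("g2", "g4", "g8"), "gap", max_intervening = 1L)
  expect_equal(p3$clusters, list(c("g2", "g4")))
  expect_equal(p3$singletons, "g8")

  # bp gap constraint can break a rank-adjacent run (genes are 2 kb apart)
  p4 <- detect_clusters(ann, c("g3", "g4"), "bp", max_gap_bp = 500L)
  expect_length(p4$clusters, 0L)

  # unplaced members reported, never dropped
  p5 <- detect_clusters(ann, c("g3", "g4", "ghost"), "missing")
  expect_equal(p5$unplaced, "ghost")
  expect_equal(p5$clusters, list(c("g3", "g4")))
})

test_that("partition completeness and run maximality hold on random families", {
  ann <- toy_annotation(60L, n_chrom = 3L)
  set.seed(42)
  for (rep in 1:25) {
    members <- sample(ann$gene_id, sample(3:12, 1L))
    mi <- sample(0:2, 1L)
    p <- detect_clusters(ann, members, "rand", max_intervening = mi)
    flat <- unlist(p$clusters)
    expect_setequal(c(flat, p$singletons, p$unplaced), members)
    expect_equal(length(flat) + length(p$singletons) + length(p$unplaced),
                 length(members))
    # maximality: no singleton is within mi non-family genes of a run end
    ranks <- setNames(ann$rank, ann$gene_id)
    chroms <- setNames(ann$chrom, ann$gene_id)
    for (run in p$clusters) {
      ends <- c(run[1L], run[length(run)])
      for (s in p$singletons) {
        for (e in ends) {
          if (chroms[s] == chroms[e]) {
            expect_gt(abs(ranks[s] - ranks[e]), mi + 1L)
          }
        }
      }
    }
  }
})

test_that("the partition is invariant to input file line order", {
  ann <- toy_annotation(20L, n_chrom = 2L)
  bed <- tempfile(fileext = ".bed")
  write_bed(ann, bed)
  lines <- readLines(bed)
  set.seed(7)
  writeLines(sample(lines), bed)
  shuffled <- load_annotation(bed)
  members <- c("g2", "g3", "g4", "g8", "g15")
  expect_equal(detect_clusters(shuffled, members, "f"),
               detect_clusters(ann, members, "f"))
})

test_that("permutation p-values match exhaustive placement enumeration", {
  ann <- toy_annotation(30L)
  members <- c("g11", "g12", "g13")

  # oracle: statistic over all C(30,3) equally likely placements
  placements <- utils::combn(30L, 3L)
  stats <- apply(placements, 2L, function(rows) {
    runs <- diff(sort(rows)) == 1L
    n_in_runs <- sum(rle(runs)$lengths[rle(runs)$values] + 1L)
    if (length(n_in_runs) == 0L) 0L else n_in_runs
  })
  q_exact <- mean(stats >= 3L)

  sig <- clustering_significance(ann, members, "tri",
                                 n_permutations = 2000L, seed = 11L)
  expect_equal(sig$observed_clustered_count, 3L)
  tol <- 3 * sqrt(q_exact * (1 - q_exact) / 2000) + 1 / 2000
  expect_lt(abs(sig$p_value - q_exact), tol)

  # determinism: same seed, same null
  sig2 <- clustering_significance(ann, members, "tri",
                                  n_permutations = 2000L, seed = 11L)
  expect_identical(sig$null_counts, sig2$null_counts)

  # dispersed family: observed 0, p = 1
  ann3 <- toy_annotation(9L, n_chrom = 3L)
  disp <- clustering_significance(ann3, c("g1", "g4", "g7"), "disp",
                                  n_permutations = 100L, seed = 1L)
  expect_equal(disp$observed_clustered_count, 0L)
  expect_equal(disp$p_value, 1)
})

test_that("permutation p-values are super-uniform for random families", {
  ann <- toy_annotation(100L, n_chrom = 2L)
  set.seed(99)
  p <- vapply(1:200, function(i) {
    members <- sample(ann$gene_id, 5L)
    clustering_significance(ann, members, "null", n_permutations = 150L,
                            seed = i)$p_value
  }, numeric(1L))
  grid <- seq(0.01, 1, by = 0.01)
  excess <- max(stats::ecdf(p)(grid) - grid)
  # one-sided DKW bound at n = 200, alpha = 0.001
  expect_lt(excess, sqrt(log(1 / 0.001) / (2 * 200)))
})

test_that("family selection keeps p <= alpha in stable order", {
  mk <- function(name, p) structure(list(family_name = name, p_value = p),
                                    class = "cluster_significance")
  res <- list(mk("A", 0.01), mk("B", 0.2), mk("C", 0.05))
  expect_equal(select_clustered_families(res), c("A", "C"))
  expect_equal(select_clustered_families(list()), character())
  expect_equal(select_clustered_families(list(mk("A", 1), mk("B", 1))),
               character())
})
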