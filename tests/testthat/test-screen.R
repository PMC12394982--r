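# Disruption calls, the hypergeometric tail, the screen and mutant grouping.

test_that("disrupted genes are called from measured values only", {
  values <- rbind(mutA = c(1.5, -0.2, -2.0, NA),
                  mutB = c(0.1, 0.2, 0.0, 0.3))
  colnames(values) <- paste0("gene", 1:4)
  comp <- expression_compendium(values)

  calls <- call_disrupted(comp, "mutA", threshold = 1)
  expect_setequal(calls$disrupted, c("gene1", "gene3"))
  expect_equal(calls$N, 3L)
  expect_equal(calls$K, 2L)

  expect_equal(call_disrupted(comp, "mutB", threshold = 10)$K, 0L)
  expect_error(call_disrupted(comp, "nope"), "unknown mutant")

  all_na <- expression_compendium(
    matrix(NA_real_, 1L, 3L, dimnames = list("m", paste0("g", 1:3))))
  expect_warning(empty <- call_disrupted(all_na, "m"), "no measured")
  expect_equal(c(empty$N, empty$K), c(0L, 0L))

  # quantile mode: top 25% by |ratio|
  q <- call_disrupted(comp, "mutB", quantile = 0.25)
  expect_equal(q$disrupted, "gene4")
})

test_that("hypergeom_tail matches brute-force enumeration and phyper", {
  expect_identical(hypergeom_tail(20, 6, 5, 0), 1)
  expect_identical(hypergeom_tail(20, 20, 5, 5), 1)
  expect_equal(hypergeom_tail(20, 6, 5, 3), 2036 / 15504, tolerance = 1e-14)

  set.seed(5)
  for (i in 1:50) {
    N <- sample(2:30, 1L); K <- sample(0:N, 1L)
    m <- sample(0:N, 1L); x <- if (m > 0) sample(0:m, 1L) else 0L
    expect_equal(hypergeom_tail(N, K, m, x), enum_hyper_tail(N, K, m, x),
                 tolerance = 1e-12)
    # independent library cross-check on the same case
    expect_equal(hypergeom_tail(N, K, m, x),
                 stats::phyper(x - 1, K, N - K, m, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  # lower tail and log-space stability at genome scale
  expect_equal(hypergeom_tail(20, 6, 5, 3, lower = TRUE),
               stats::phyper(3, 6, 14, 5), tolerance = 1e-12)
  expect_equal(hypergeom_tail(1e5, 1000, 100, 5),
               stats::phyper(4, 1000, 99000, 100, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(hypergeom_tail(10, 4, 12, 1), "<=")
  expect_error(hypergeom_tail(10, 14, 5, 1), "K")
  expect_error(hypergeom_tail(10.5, 4, 5, 1), "integers")
})

test_that("tail probability is monotone in x and in the subset size", {
  for (x in 1:5) {
    expect_gte(hypergeom_tail(40, 10, 8, x), hypergeom_tail(40, 10, 8, x + 1))
  }
  for (m in 4:7) {
    expect_lte(hypergeom_tail(40, 10, m, 4), hypergeom_tail(40, 10, m + 1, 4))
  }
})

test_that("deviation transform is 1 - P and rejects bad input", {
  expect_equal(transform_deviation(1), 0)
  expect_equal(transform_deviation(0.05), 0.95)
  expect_equal(transform_deviation(0), 1)
  expect_true(is.na(transform_deviation(NA)))
  expect_error(transform_deviation(1.2), "\\[0, 1\\]")
})

test_that("the screen scores cluster-targeted disruption and only that", {
  # 100-gene compendium; mutant 'hit' disrupts exactly the clustered triplet
  genes <- sprintf("g%03d", 1:100)
  values <- matrix(0, nrow = 2L, ncol = 100L,
                   dimnames = list(c("hit", "quiet"), genes))
  values["hit", c("g001", "g002", "g003")] <- c(2, -2, 2)
  comp <- expression_compendium(values)

  ptri <- structure(list(family = "tri", members = genes[1:6],
                         clusters = list(c("g001", "g002", "g003")),
                         singletons = genes[4:6], unplaced = character(),
                         params = list(max_intervening = 0L, max_gap_bp = Inf)),
                    class = "cluster_partition")
  pcold <- structure(list(family = "cold", members = genes[11:16],
                          clusters = list(c("g011", "g012")),
                          singletons = genes[13:16], unplaced = character(),
                          params = list(max_intervening = 0L, max_gap_bp = Inf)),
                     class = "cluster_partition")

  scr <- disruption_screen(comp, list(ptri, pcold), threshold = 1)
  cell <- scr$cells[scr$cells$mutant == "hit" & scr$cells$family == "tri", ]
  expect_equal(cell$P, 1 / choose(100, 3), tolerance = 1e-12)
  expect_equal(c(cell$N, cell$K, cell$m, cell$n, cell$x),
               c(100L, 3L, 3L, 6L, 3L))

  # untouched family for the same mutant: x = 0 -> P = 1 -> score 0
  cold <- scr$cells[scr$cells$mutant == "hit" & scr$cells$family == "cold", ]
  expect_equal(cold$score, 0)

  # K = 0 mutant: every cell P = 1, score 0
  expect_true(all(scr$pvalues["quiet", ] == 1))
  expect_true(all(scr$scores["quiet", ] == 0))

  # family with empty clustered subset -> not-applicable cell
  psing <- structure(list(family = "allsingle", members = genes[21:24],
                          clusters = list(), singletons = genes[21:24],
                          unplaced = character(),
                          params = list(max_intervening = 0L, max_gap_bp = Inf)),
                     class = "cluster_partition")
  scr2 <- disruption_screen(comp, list(psing))
  expect_true(all(is.na(scr2$scores)))
})

test_that("screen output is byte-identical across reruns", {
  set.seed(21)
  genes <- sprintf("g%03d", 1:50)
  values <- matrix(stats::rnorm(100, sd = 1), nrow = 2L,
                   dimnames = list(c("m1", "m2"), genes))
  comp <- expression_compendium(values)
  part <- structure(list(family = "f", members = genes[1:5],
                         clusters = list(genes[1:2]), singletons = genes[3:5],
                         unplaced = character(),
                         params = list(max_intervening = 0L, max_gap_bp = Inf)),
                    class = "cluster_partition")
  f1 <- tempfile(); f2 <- tempfile()
  write.table(disruption_screen(comp, part)$cells, f1, sep = "\t")
  write.table(disruption_screen(comp, part)$cells, f2, sep = "\t")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("k-means grouping recovers planted mutant archetypes", {
  set.seed(31)
  n_fam <- 8L
  archetype <- function(base) pmin(pmax(base + stats::rnorm(n_fam, sd = 0.03), 0), 1)
  rows <- rbind(
    t(replicate(10L, archetype(rep(0.97, n_fam)))),          # global disruptor
    t(replicate(10L, archetype(c(rep(0.95, 2L), rep(0.02, 6L))))),  # specific
    t(replicate(10L, archetype(rep(0.02, n_fam)))))          # negligible
  rownames(rows) <- sprintf("mut%02d", 1:30)
  res <- group_mutants(rows, k = 3L, seed = 4L)
  truth <- rep(1:3, each = 10L)
  # labels are arbitrary: check the partition, not the label values
  expect_true(all(tapply(res$groups, truth,
                         function(g) length(unique(g)) == 1L)))
  expect_equal(length(unique(res$groups)), 3L)

  # identical rows always share a label
  two <- rbind(a = rep(0.5, 4L), b = rep(0.5, 4L), c = rep(0, 4L))
  g2 <- group_mutants(two, k = 2L, seed = 1L)$groups
  expect_equal(g2[["a"]], g2[["b"]])

  # k = 1: one group, WCSS equals the total sum of squares
  g1 <- group_mutants(rows, k = 1L, seed = 1L)
  expect_equal(g1$wcss, sum(scale(rows, scale = FALSE)^2))
  expect_error(group_mutants(rows, k = 31L), "exceeds")
})
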