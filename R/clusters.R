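# Cluster detection on the chromosome rank frame, and its permutation null.

# Core run-finder shared by detect_clusters() and the permutation null.
# Takes integer row indices of family members in the annotation and returns a
# list of integer vectors (row indices), one per maximal run of length >= 2.
# Two consecutive members extend a run when they lie on the same chromosome,
# at most max_intervening non-member genes sit between them (rank difference
# minus one), and the bp gap between them is <= max_gap_bp.
.find_runs <- function(annotation, rows, max_intervening, max_gap_bp) {
  if (length(rows) < 2L) return(list())
  chrom <- annotation$chrom[rows]
  rank <- annotation$rank[rows]
  ord <- order(chrom, rank)
  rows <- rows[ord]
  chrom <- chrom[ord]
  rank <- rank[ord]
  start <- annotation$start[rows]
  end <- annotation$end[rows]
  n <- length(rows)
  same_chrom <- chrom[-1L] == chrom[-n]
  intervening <- rank[-1L] - rank[-n] - 1L
  gap_bp <- start[-1L] - end[-n]
  linked <- same_chrom & intervening <= max_intervening & gap_bp <= max_gap_bp
  run_id <- cumsum(c(TRUE, !linked))
  runs <- split(rows, run_id)
  runs[lengths(runs) >= 2L]
}

# Number of family members lying inside runs of length >= 2 (the permutation
# statistic). Kept separate from .find_runs for speed in tight loops.
.clustered_count <- function(annotation, rows, max_intervening, max_gap_bp) {
  sum(lengths(.find_runs(annotation, rows, max_intervening, max_gap_bp)))
}

#' Partition a gene family into clustered and singleton subsets
#'
#' A functional gene cluster is a run of two or more members of the same
#' family lying adjacent (or near-adjacent) along a chromosome. Adjacency is
#' measured on the chromosome rank index: with `max_intervening = 0` (the
#' default) consecutive run members must be immediate genomic neighbours;
#' larger values allow that many non-family genes between consecutive
#' members. `max_gap_bp` additionally bounds the base-pair gap between the
#' end of one member and the start of the next (unlimited by default).
#' Strand is recorded in the annotation but ignored: tandem, convergent and
#' divergent arrangements all count as clustered.
#'
#' Returned runs are maximal: no run can be extended by another family member
#' without violating a constraint. Family members absent from the annotation
#' are reported as `unplaced`, never silently dropped.
#'
#' @param annotation A [genome_annotation()].
#' @param members Character vector of member gene ids.
#' @param family_name Name of the family (carried through to outputs).
#' @param max_intervening Maximum number of non-family genes allowed between
#'   consecutive members of a run. Default 0 (strict adjacency).
#' @param max_gap_bp Maximum base-pair gap between consecutive run members.
#'   Default `Inf`.
#' @return An object of class `cluster_partition`: a list with elements
#'   `family` (name), `members`, `clusters` (list of gene-id vectors, each of
#'   length >= 2, in chromosomal order), `singletons`, `unplaced`, and
#'   `params`.
#' @examples
#' ann <- genome_annotation(data.frame(
#'   gene_id = paste0("g", 1:6), chrom = "chrI",
#'   start = (0:5) * 2000, end = (0:5) * 2000 + 1000
#' ))
#' detect_clusters(ann, c("g2", "g3", "g4", "g6"), "toy")
#' @export
detect_clusters <- function(annotation, members, family_name = "family",
                            max_intervening = 0L, max_gap_bp = Inf) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (nrow(annotation) == 0L) stop("annotation is empty")
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("family has no members")
  stopifnot(max_intervening >= 0L, max_gap_bp >= 0)

  rows <- match(members, annotation$gene_id)
  unplaced <- members[is.na(rows)]
  rows <- rows[!is.na(rows)]
  runs <- .find_runs(annotation, rows, max_intervening, max_gap_bp)
  clusters <- lapply(runs, function(r) annotation$gene_id[r])
  names(clusters) <- NULL
  clustered <- unlist(clusters, use.names = FALSE)
  placed <- annotation$gene_id[rows]
  singletons <- sort(setdiff(placed, clustered))

  structure(list(
    family = family_name,
    members = members,
    clusters = clusters,
    singletons = singletons,
    unplaced = sort(unplaced),
    params = list(max_intervening = as.integer(max_intervening),
                  max_gap_bp = max_gap_bp)
  ), class = "cluster_partition")
}

#' Gene ids in the clustered subset of a partition
#'
#' Pools the members of all of the family's clusters.
#'
#' @param partition A `cluster_partition`.
#' @return Character vector of clustered gene ids.
#' @export
clustered_genes <- function(partition) {
  stopifnot(inherits(partition, "cluster_partition"))
  unlist(partition$clusters, use.names = FALSE)
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("cluster_partition '", x$family, "': ", length(x$clusters),
      " cluster(s) [", sum(lengths(x$clusters)), " genes], ",
      length(x$singletons), " singleton(s), ",
      length(x$unplaced), " unplaced\n", sep = "")
  invisible(x)
}

#' Tabulate one or more cluster partitions
#'
#' @param partitions A `cluster_partition` or list of them.
#' @return A data.frame with columns `family`, `gene`, `chromosome`,
#'   `subset` (`cluster`, `singleton` or `unplaced`) and `cluster_index`
#'   (NA outside clusters).
#' @export
partition_table <- function(partitions) {
  if (inherits(partitions, "cluster_partition")) partitions <- list(partitions)
  rows <- lapply(partitions, function(p) {
    parts <- list()
    if (length(p$clusters) > 0L) {
      parts <- c(parts, lapply(seq_along(p$clusters), function(i) {
        data.frame(family = p$family, gene = p$clusters[[i]],
                   subset = "cluster", cluster_index = i)
      }))
    }
    if (length(p$singletons) > 0L) {
      parts <- c(parts, list(data.frame(family = p$family, gene = p$singletons,
                                        subset = "singleton", cluster_index = NA_integer_)))
    }
    if (length(p$unplaced) > 0L) {
      parts <- c(parts, list(data.frame(family = p$family, gene = p$unplaced,
                                        subset = "unplaced", cluster_index = NA_integer_)))
    }
    do.call(rbind, parts)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation significance of a family's genomic clustering
#'
#' Tests whether a family's members cluster along chromosomes more than
#' expected by chance. The null preserves the genome architecture and
#' relabels membership: in each permutation, family membership is assigned to
#' a uniform random subset of annotated genes of the same size as the placed
#' family, clusters are re-detected, and the statistic — the number of family
#' genes lying inside runs — is recorded. The p-value uses a pseudo-count,
#' `p = (1 + #\{null >= observed\}) / (1 + n_permutations)`, so it is never
#' exactly zero.
#'
#' @inheritParams detect_clusters
#' @param n_permutations Number of membership relabellings (>= 100).
#' @param seed Integer seed making the null reproducible.
#' @return An object of class `cluster_significance`: list with
#'   `family_name`, `observed_clustered_count`, `null_counts`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
clustering_significance <- function(annotation, members, family_name = "family",
                                    max_intervening = 0L, max_gap_bp = Inf,
                                    n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  members <- unique(as.character(members))
  rows <- match(members, annotation$gene_id)
  rows <- rows[!is.na(rows)]
  n_placed <- length(rows)
  if (n_placed > nrow(annotation)) stop("family larger than the genome")
  observed <- .clustered_count(annotation, rows, max_intervening, max_gap_bp)

  n_genes <- nrow(annotation)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_permutations), function(b) {
    fake <- sample.int(n_genes, n_placed)
    .clustered_count(annotation, fake, max_intervening, max_gap_bp)
  }, integer(1L))
  p <- (1 + sum(null_counts >= observed)) / (1 + n_permutations)

  structure(list(
    family_name = family_name,
    observed_clustered_count = observed,
    null_counts = null_counts,
    p_value = p,
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed)
  ), class = "cluster_significance")
}

#' @export
print.cluster_significance <- function(x, ...) {
  cat("cluster_significance '", x$family_name, "': observed ",
      x$observed_clustered_count, " clustered genes, p = ",
      format(x$p_value, digits = 4L), " (", x$n_permutations,
      " permutations)\n", sep = "")
  invisible(x)
}

#' Select families with significant genomic clustering
#'
#' Keeps families whose permutation p-value is at or below `alpha`
#' (inclusive), in the input order.
#'
#' @param results List of `cluster_significance` objects.
#' @param alpha Significance cutoff; families with `p_value <= alpha` pass.
#' @return Character vector of family names.
#' @export
select_clustered_families <- function(results, alpha = 0.05) {
  if (length(results) == 0L) return(character())
  stopifnot(all(vapply(results, inherits, logical(1L), "cluster_significance")))
  keep <- vapply(results, function(r) r$p_value <= alpha, logical(1L))
  vapply(results[keep], `[[`, "", "family_name")
}
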