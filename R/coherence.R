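# Transcriptional coherence of gene sets across stress time-courses.

#' Stress-response time-course
#'
#' Wraps a gene x timepoint matrix of log2 relative expression measured along
#' one stress or nutritional response.
#'
#' @param values Numeric matrix, rows = genes (unique rownames), columns =
#'   ordered timepoints.
#' @param stressor Name of the stressor.
#' @param provenance Free-text dataset tag.
#' @return An object of class `time_course`.
#' @export
time_course <- function(values, stressor, provenance = "unknown") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("time-course needs gene rownames")
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids in time-course")
  if (ncol(values) < 3L) stop("a time-course needs >= 3 timepoints")
  if (is.null(colnames(values))) colnames(values) <- paste0("t", seq_len(ncol(values)))
  structure(list(stressor = stressor, values = values, provenance = provenance),
            class = "time_course")
}

#' Read a time-course from TSV
#'
#' First column gene id, remaining columns timepoints (ordered as in the
#' file); empty cells are missing.
#'
#' @param path Path to the TSV file.
#' @param stressor Stressor name; defaults to the file name.
#' @param provenance Dataset tag.
#' @return A [time_course()].
#' @export
load_timecourse <- function(path, stressor = NULL, provenance = "file") {
  if (!file.exists(path)) stop("time-course file not found: ", path)
  if (is.null(stressor)) stressor <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("time-course needs a gene column plus >= 3 timepoints")
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- as.character(df[[1L]])
  storage.mode(values) <- "double"
  time_course(values, stressor, provenance)
}

#' Write a time-course to TSV
#'
#' @param tc A [time_course()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  df <- data.frame(gene = rownames(tc$values), tc$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Mean pairwise Pearson correlation of a gene set
#'
#' The transcriptional coherence of a gene set is the mean (or median)
#' Pearson correlation over every unordered pair of distinct gene profiles.
#' Genes with any missing timepoint are excluded list-wise before the
#' calculation, as are zero-variance profiles (for which Pearson r is
#' undefined); both exclusions are counted in the attributes. With fewer
#' than two usable genes the coherence is not-applicable (`NA`), which is
#' distinct from a coherence of 0.
#'
#' @param values Numeric gene x timepoint matrix.
#' @param aggregate `"mean"` (default) or `"median"` over pairs.
#' @return A single numeric value in \[-1, 1\] or `NA`, with attributes
#'   `n_used` (genes entering the calculation) and `n_excluded`.
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
#' mean_pairwise_pcc(m)
#' @export
mean_pairwise_pcc <- function(values, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.matrix(values), is.numeric(values))
  complete <- stats::complete.cases(values)
  nonconst <- apply(values, 1L, function(r) stats::sd(r) > 0)
  nonconst[is.na(nonconst)] <- FALSE
  keep <- complete & nonconst
  n_used <- sum(keep)
  out <- if (n_used < 2L) {
    NA_real_
  } else {
    cc <- stats::cor(t(values[keep, , drop = FALSE]))
    pairs <- cc[upper.tri(cc)]
    if (aggregate == "mean") mean(pairs) else stats::median(pairs)
  }
  attr(out, "n_used") <- n_used
  attr(out, "n_excluded") <- nrow(values) - n_used
  out
}

#' Coherence of a family and its clustered/singleton subsets
#'
#' Computes [mean_pairwise_pcc()] three times on the same time-course: for
#' the whole family (clustered and singleton members pooled), for the
#' clustered subset (genes from all of the family's clusters pooled), and
#' for the singleton subset. Partition gene ids are intersected with the
#' time-course's genes first.
#'
#' @param tc A [time_course()].
#' @param partition A [detect_clusters()] partition.
#' @param aggregate Passed to [mean_pairwise_pcc()].
#' @return A one-row data.frame with columns `stressor`, `family`,
#'   `pcc_family`, `pcc_clustered`, `pcc_singleton`, `n_family`,
#'   `n_clustered`, `n_singleton` (the counts are genes actually used).
#' @export
subset_coherence <- function(tc, partition, aggregate = c("mean", "median")) {
  stopifnot(inherits(tc, "time_course"),
            inherits(partition, "cluster_partition"))
  aggregate <- match.arg(aggregate)
  genes <- rownames(tc$values)
  clu <- intersect(clustered_genes(partition), genes)
  sing <- intersect(partition$singletons, genes)
  fam <- c(clu, sing)
  if (length(fam) == 0L) {
    message("family '", partition$family, "' has no genes in stressor '",
            tc$stressor, "'")
  }
  pcc_of <- function(ids) {
    if (length(ids) < 2L) {
      out <- NA_real_
      attr(out, "n_used") <- length(ids)
      out
    } else {
      mean_pairwise_pcc(tc$values[ids, , drop = FALSE], aggregate = aggregate)
    }
  }
  pf <- pcc_of(fam); pc <- pcc_of(clu); ps <- pcc_of(sing)
  data.frame(
    stressor = tc$stressor, family = partition$family,
    pcc_family = as.numeric(pf), pcc_clustered = as.numeric(pc),
    pcc_singleton = as.numeric(ps),
    n_family = attr(pf, "n_used"), n_clustered = attr(pc, "n_used"),
    n_singleton = attr(ps, "n_used"),
    stringsAsFactors = FALSE)
}

#' Stressor x family coherence panel
#'
#' Applies [subset_coherence()] over every (stressor, family) combination and
#' assembles three stressor x family matrices: whole-family, clustered-subset
#' and singleton-subset coherence. Optionally orders the family columns by
#' k-means grouping of the clustered matrix for visualisation.
#'
#' @param timecourses List of [time_course()] objects.
#' @param partitions List of [detect_clusters()] partitions.
#' @param aggregate Passed to [mean_pairwise_pcc()].
#' @param kmeans_k Optional integer; when given, family columns are reordered
#'   by k-means group of the clustered matrix (NA imputed as 0).
#' @param seed Seed for the optional k-means ordering.
#' @return A list of class `coherence_panel` with matrices `family`,
#'   `clustered`, `singleton` (stressors x families) and the long `table`.
#' @export
coherence_panel <- function(timecourses, partitions,
                            aggregate = c("mean", "median"),
                            kmeans_k = NULL, seed = 1L) {
  if (inherits(timecourses, "time_course")) timecourses <- list(timecourses)
  if (inherits(partitions, "cluster_partition")) partitions <- list(partitions)
  stopifnot(length(timecourses) >= 1L, length(partitions) >= 1L)
  aggregate <- match.arg(aggregate)
  rows <- do.call(rbind, lapply(timecourses, function(tc) {
    do.call(rbind, lapply(partitions, function(p) {
      subset_coherence(tc, p, aggregate = aggregate)
    }))
  }))
  stressors <- vapply(timecourses, `[[`, "", "stressor")
  families <- vapply(partitions, `[[`, "", "family")
  shape <- function(col) {
    matrix(rows[[col]], nrow = length(stressors), byrow = TRUE,
           dimnames = list(stressors, families))
  }
  out <- list(family = shape("pcc_family"),
              clustered = shape("pcc_clustered"),
              singleton = shape("pcc_singleton"),
              table = rows)
  if (!is.null(kmeans_k) && length(families) > kmeans_k) {
    imputed <- out$clustered
    imputed[is.na(imputed)] <- 0
    set.seed(seed)
    km <- stats::kmeans(t(imputed), centers = kmeans_k, nstart = 10L)
    ord <- order(km$cluster)
    out$family <- out$family[, ord, drop = FALSE]
    out$clustered <- out$clustered[, ord, drop = FALSE]
    out$singleton <- out$singleton[, ord, drop = FALSE]
  }
  class(out) <- "coherence_panel"
  out
}

#' @export
print.coherence_panel <- function(x, ...) {
  cat("coherence_panel:", nrow(x$clustered), "stressor(s) x",
      ncol(x$clustered), "family(ies)\n")
  invisible(x)
}

#' Clustered-minus-singleton deviation matrix
#'
#' Element-wise signed difference between the clustered-subset and
#' singleton-subset coherence matrices. Positive cells mark conditions
#' where the clustered genes are more transcriptionally coherent than the
#' singletons of the same family; not-applicable cells propagate. The
#' unsigned distance is `abs()` of the result.
#'
#' @param clustered,singleton Numeric matrices with identical dimnames, as
#'   produced by [coherence_panel()].
#' @return A stressor x family matrix of `pcc_clustered - pcc_singleton`.
#' @examples
#' deviation_matrix(matrix(0.692, dimnames = list("DTT", "VMP")),
#'                  matrix(0.010, dimnames = list("DTT", "VMP")))
#' @export
deviation_matrix <- function(clustered, singleton) {
  stopifnot(is.matrix(clustered), is.matrix(singleton))
  if (!identical(dim(clustered), dim(singleton)) ||
      !identical(dimnames(clustered), dimnames(singleton))) {
    stop("clustered and singleton matrices must share shape and labels")
  }
  clustered - singleton
}
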