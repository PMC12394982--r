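# Visualisation helpers. Heatmaps go through pheatmap when available.

#' Heatmap of a screen or coherence matrix
#'
#' Draws the mutant x family deviation-score heatmap (or any stressor x
#' family coherence/deviation matrix). Uses \pkg{pheatmap} when installed;
#' otherwise falls back to [graphics::image()].
#'
#' @param mat Numeric matrix (e.g. `screen$scores` or a coherence matrix).
#' @param filename Optional file path (png/pdf, pheatmap only); `NULL` draws
#'   to the active device.
#' @param cluster Logical; hierarchically cluster rows/columns for display.
#' @param main Plot title.
#' @return Invisibly, the matrix as drawn (NA imputed as 0).
#' @export
plot_score_heatmap <- function(mat, filename = NULL, cluster = TRUE,
                               main = "deviation score") {
  stopifnot(is.matrix(mat))
  shown <- mat
  shown[is.na(shown)] <- 0
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    args <- list(mat = shown, cluster_rows = cluster, cluster_cols = cluster,
                 main = main)
    if (!is.null(filename)) args$filename <- filename
    do.call(pheatmap::pheatmap, args)
  } else {
    graphics::image(t(shown)[, rev(seq_len(nrow(shown))), drop = FALSE],
                    axes = FALSE, main = main)
  }
  invisible(shown)
}

#' Per-family expression profile plot
#'
#' Plots the time-course profiles of a family in three panels — whole
#' family, singletons, clusters — with the mean pairwise Pearson
#' correlation of each subset in the panel title.
#'
#' @param tc A [time_course()].
#' @param partition A [detect_clusters()] partition.
#' @return Invisibly, the [subset_coherence()] row used for the titles.
#' @export
plot_family_profiles <- function(tc, partition) {
  stopifnot(inherits(tc, "time_course"), inherits(partition, "cluster_partition"))
  res <- subset_coherence(tc, partition)
  genes <- rownames(tc$values)
  sets <- list(
    family = intersect(c(clustered_genes(partition), partition$singletons), genes),
    singletons = intersect(partition$singletons, genes),
    clusters = intersect(clustered_genes(partition), genes))
  pccs <- c(res$pcc_family, res$pcc_singleton, res$pcc_clustered)
  old <- graphics::par(mfrow = c(3L, 1L), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  x <- seq_len(ncol(tc$values))
  for (i in seq_along(sets)) {
    ids <- sets[[i]]
    title <- sprintf("%s / %s: %s (PCC = %s)", tc$stressor, partition$family,
                     names(sets)[i],
                     ifelse(is.na(pccs[i]), "n/a", format(pccs[i], digits = 3L)))
    if (length(ids) == 0L) {
      graphics::plot(x, rep(0, length(x)), type = "n", main = title,
                     xlab = "", ylab = "log2 ratio")
      next
    }
    sub <- tc$values[ids, , drop = FALSE]
    graphics::matplot(x, t(sub), type = "l", lty = 1L, main = title,
                      xlab = "", ylab = "log2 ratio")
  }
  invisible(res)
}
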