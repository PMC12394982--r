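# Scoring deletion mutants for cluster-specific transcriptional disruption.

#' Expression compendium of deletion mutants
#'
#' Wraps a mutant x gene matrix of log2 expression ratios versus wild type.
#' Missing measurements are `NA` and are excluded per mutant from every
#' downstream count (never list-wise across mutants).
#'
#' @param values Numeric matrix, rows = mutants, columns = genes, both with
#'   unique dimnames. Entries are log2 ratios; `NA` marks a missing
#'   measurement.
#' @return An object of class `expression_compendium`.
#' @export
expression_compendium <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("compendium matrix needs mutant rownames and gene colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated mutant ids")
  if (anyDuplicated(colnames(values))) stop("duplicated gene ids")
  if (any(is.infinite(values))) stop("compendium values must be finite or NA")
  structure(list(values = values), class = "expression_compendium")
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat("expression_compendium:", nrow(x$values), "mutants x",
      ncol(x$values), "genes;", sum(is.na(x$values)), "missing values\n")
  invisible(x)
}

#' Read a mutant compendium from TSV
#'
#' Expects a tab-separated table with gene ids in the first column and one
#' column of log2 ratios per mutant; empty cells are missing. The GCT dialect
#' (two header lines `#1.2` / dimensions, plus a Description column) is also
#' accepted.
#'
#' @param path Path to the TSV/GCT file.
#' @return An [expression_compendium()].
#' @export
load_compendium <- function(path) {
  if (!file.exists(path)) stop("compendium file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  skip <- 0L
  drop_desc <- FALSE
  if (grepl("^#1\\.2", first)) {
    skip <- 2L
    drop_desc <- TRUE
  }
  df <- utils::read.delim(path, skip = skip, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("compendium needs a gene column plus >= 1 mutant column")
  genes <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  if (drop_desc && tolower(names(df)[1L]) == "description") {
    df <- df[, -1L, drop = FALSE]
  }
  values <- t(as.matrix(df))
  colnames(values) <- genes
  storage.mode(values) <- "double"
  expression_compendium(values)
}

#' Write a compendium to TSV (genes as rows)
#'
#' @param compendium An [expression_compendium()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compendium <- function(compendium, path) {
  stopifnot(inherits(compendium, "expression_compendium"))
  df <- data.frame(gene = colnames(compendium$values),
                   t(compendium$values), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call disrupted genes in one mutant profile
#'
#' A gene is disrupted in a deletion mutant when the magnitude of its log2
#' expression ratio versus wild type reaches `threshold`. Genes with missing
#' measurements are excluded from both the measured total `N` and the calls.
#' Alternatively, `quantile` selects the top fraction of measured genes by
#' absolute ratio, for compendia whose scale is unknown.
#'
#' @param compendium An [expression_compendium()].
#' @param mutant Mutant id (must be a row of the compendium).
#' @param threshold Absolute log2-ratio cutoff (> 0). Default 1 (2-fold).
#' @param quantile Optional fraction in (0, 1); when given, overrides
#'   `threshold` and calls the top `quantile` of measured genes by
#'   absolute ratio.
#' @return An object of class `disruption_calls`: list with `mutant`,
#'   `disrupted` (gene ids), `measured` (gene ids), `threshold`, `N`, `K`.
#' @export
call_disrupted <- function(compendium, mutant, threshold = 1, quantile = NULL) {
  stopifnot(inherits(compendium, "expression_compendium"))
  if (!mutant %in% rownames(compendium$values)) {
    stop("unknown mutant: ", mutant)
  }
  row <- compendium$values[mutant, ]
  measured <- names(row)[!is.na(row)]
  vals <- row[measured]
  if (length(measured) == 0L) {
    warning("mutant '", mutant, "' has no measured genes")
    disrupted <- character()
  } else if (!is.null(quantile)) {
    stopifnot(quantile > 0, quantile < 1)
    cut <- stats::quantile(abs(vals), probs = 1 - quantile, names = FALSE)
    disrupted <- measured[abs(vals) >= cut]
  } else {
    stopifnot(threshold > 0)
    disrupted <- measured[abs(vals) >= threshold]
  }
  structure(list(
    mutant = mutant,
    disrupted = disrupted,
    measured = measured,
    threshold = if (is.null(quantile)) threshold else NA_real_,
    N = length(measured),
    K = length(disrupted)
  ), class = "disruption_calls")
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `x` disrupted genes inside a subset of
#' size `m`, when `K` of the `N` measured genes are disrupted and the subset
#' is exchangeable with the rest of the genome: `P(X >= x)` for
#' `X ~ Hypergeometric(N, K, m)`. Computed by a log-space sum of binomial
#' coefficients, stable for `N` up to at least 1e5. `x = 0` returns exactly 1.
#'
#' @param N Total measured genes (population size).
#' @param K Disrupted genes among them (successes in the population).
#' @param m Subset size (number of draws).
#' @param x Observed disrupted genes in the subset.
#' @param lower If `TRUE`, return the lower tail `P(X <= x)` instead.
#' @return Tail probability in \[0, 1\].
#' @examples
#' hypergeom_tail(N = 20, K = 6, m = 5, x = 3)
#' @export
hypergeom_tail <- function(N, K, m, x, lower = FALSE) {
  stopifnot(length(N) == 1L, length(K) == 1L, length(m) == 1L, length(x) == 1L)
  if (any(c(N, K, m, x) != floor(c(N, K, m, x)))) {
    stop("N, K, m, x must be integers")
  }
  if (!(x >= 0 && x <= m && m <= N)) {
    stop("require 0 <= x <= m <= N (got N=", N, ", m=", m, ", x=", x, ")")
  }
  if (!(K >= 0 && K <= N)) stop("require 0 <= K <= N (got K=", K, ", N=", N, ")")
  # exact 1 for the full-support tails, avoiding summation round-off
  if (!lower && x == 0) return(1)
  if (lower && x == m) return(1)
  j <- if (lower) seq.int(0L, x) else seq.int(x, m)
  # support of X is max(0, m - (N - K)) .. min(K, m); out-of-support terms
  # get lchoose = -Inf and vanish
  lt <- lchoose(K, j) + lchoose(N - K, m - j) - lchoose(N, m)
  lt <- lt[is.finite(lt)]
  if (length(lt) == 0L) return(0)
  mx <- max(lt)
  p <- exp(mx + log(sum(exp(lt - mx))))
  min(max(p, 0), 1)
}

#' Deviation score of a p-value
#'
#' Transforms a tail probability into the deviation score used for
#' visualisation: the (scalar Euclidean) distance from 1.0, i.e. `1 - P`.
#' Scores near 1 indicate strong cluster-specific disruption.
#'
#' @param P Probability (or vector of probabilities) in \[0, 1\]; `NA` passes
#'   through.
#' @return `1 - P`.
#' @export
transform_deviation <- function(P) {
  ok <- is.na(P) | (P >= 0 & P <= 1)
  if (!all(ok)) stop("P must lie in [0, 1]")
  1 - P
}

#' Screen a compendium for cluster-specific disruption
#'
#' For every (mutant, family) pair, asks whether the mutant's transcriptional
#' disruption concentrates in the family's clustered subset. Per mutant, the
#' disrupted set is called with [call_disrupted()]; per family, the clustered
#' subset and family membership are intersected with that mutant's measured
#' genes, and the upper-tail hypergeometric probability of observing at least
#' the seen number of disrupted genes in the clustered subset is computed
#' (population = all `N` measured genes, of which `K` are disrupted; draws =
#' the `m` clustered genes). The score is the deviation `1 - P`.
#'
#' Cells whose clustered subset is empty after intersection are marked
#' not-applicable (`NA`) and excluded from mutant grouping. A
#' Benjamini-Hochberg adjusted column is emitted alongside the raw p-values
#' as a convenience; the scores themselves are computed from raw p-values.
#'
#' @param compendium An [expression_compendium()].
#' @param partitions List of [detect_clusters()] partitions (one per family).
#' @param threshold Absolute log2-ratio disruption cutoff; see
#'   [call_disrupted()].
#' @param quantile Optional top-fraction disruption mode; see
#'   [call_disrupted()].
#' @param tail `"upper"` (default) scores excess disruption of the clustered
#'   subset; `"lower"` scores depletion.
#' @return An object of class `screen_matrix`: list with `cells` (long
#'   data.frame: mutant, family, N, K, m, n, x, P, p_adjust, score),
#'   `pvalues` and `scores` (mutant x family matrices), `mutant_groups`
#'   (NULL until [group_mutants()] is run), and `params`.
#' @export
disruption_screen <- function(compendium, partitions, threshold = 1,
                              quantile = NULL, tail = c("upper", "lower")) {
  stopifnot(inherits(compendium, "expression_compendium"))
  tail <- match.arg(tail)
  if (inherits(partitions, "cluster_partition")) partitions <- list(partitions)
  stopifnot(length(partitions) > 0L,
            all(vapply(partitions, inherits, logical(1L), "cluster_partition")))
  mutants <- rownames(compendium$values)
  families <- vapply(partitions, `[[`, "", "family")
  if (anyDuplicated(families)) stop("duplicated family names in partitions")

  fam_members <- lapply(partitions, function(p) {
    union(clustered_genes(p), p$singletons)
  })
  fam_clustered <- lapply(partitions, clustered_genes)
  genome <- colnames(compendium$values)
  lost <- sum(vapply(fam_members, function(g) sum(!g %in% genome), 0L))
  if (lost > 0L) {
    message(lost, " partition gene(s) absent from the compendium; ",
            "intersection taken per cell")
  }

  cells <- vector("list", length(mutants) * length(families))
  i <- 0L
  for (mu in mutants) {
    calls <- call_disrupted(compendium, mu, threshold = threshold,
                            quantile = quantile)
    measured <- calls$measured
    disrupted <- calls$disrupted
    for (f in seq_along(families)) {
      fam_meas <- intersect(fam_members[[f]], measured)
      clu_meas <- intersect(fam_clustered[[f]], measured)
      m <- length(clu_meas)
      x <- sum(clu_meas %in% disrupted)
      if (m == 0L || calls$N == 0L) {
        P <- NA_real_
      } else {
        P <- hypergeom_tail(calls$N, calls$K, m, x, lower = tail == "lower")
      }
      i <- i + 1L
      cells[[i]] <- data.frame(
        mutant = mu, family = families[f],
        N = calls$N, K = calls$K, m = m, n = length(fam_meas), x = x,
        P = P, stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, cells)
  cells$p_adjust <- stats::p.adjust(cells$P, method = "BH")
  cells$score <- transform_deviation(cells$P)

  pvalues <- matrix(cells$P, nrow = length(mutants), byrow = TRUE,
                    dimnames = list(mutants, families))
  scores <- matrix(cells$score, nrow = length(mutants), byrow = TRUE,
                   dimnames = list(mutants, families))
  structure(list(
    cells = cells, pvalues = pvalues, scores = scores,
    mutant_groups = NULL,
    params = list(threshold = threshold, quantile = quantile, tail = tail)
  ), class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat("screen_matrix:", nrow(x$scores), "mutants x", ncol(x$scores),
      "families;", sum(is.na(x$scores)), "not-applicable cell(s)\n")
  if (!is.null(x$mutant_groups)) {
    cat("mutant groups:", paste(table(x$mutant_groups), collapse = "/"),
        "(k =", length(unique(x$mutant_groups)), ")\n")
  }
  invisible(x)
}

#' Group mutants by their disruption-score profiles
#'
#' Runs k-means on the mutant x family score matrix to separate broad
#' behavioural classes of remodeler mutants (e.g. global disruptors,
#' family-specific disruptors, and mutants with negligible effect).
#' Not-applicable cells are imputed as 0 (no evidence of disruption) for the
#' clustering only. Scores already lie in \[0, 1\] and are not re-scaled.
#'
#' @param x A `screen_matrix` from [disruption_screen()], or a plain numeric
#'   matrix of score rows.
#' @param k Number of groups (default 3).
#' @param seed Integer seed; with `nstart` restarts this makes labels
#'   reproducible.
#' @param nstart Number of random k-means restarts.
#' @return For a `screen_matrix` input, the same object with `mutant_groups`
#'   (named integer vector) and `wcss` (within-group sum of squares) filled
#'   in; for a matrix input, a list with `groups` and `wcss`.
#' @export
group_mutants <- function(x, k = 3L, seed = 1L, nstart = 10L) {
  scores <- if (inherits(x, "screen_matrix")) x$scores else x
  stopifnot(is.matrix(scores))
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(scores)) stop("k exceeds the number of mutants")
  imputed <- scores
  imputed[is.na(imputed)] <- 0
  set.seed(seed)
  km <- stats::kmeans(imputed, centers = k, nstart = nstart)
  groups <- km$cluster
  names(groups) <- rownames(scores)
  if (inherits(x, "screen_matrix")) {
    x$mutant_groups <- groups
    x$k_groups <- as.integer(k)
    x$wcss <- km$tot.withinss
    x
  } else {
    list(groups = groups, wcss = km$tot.withinss)
  }
}
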