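# Relative expression from qPCR cycle-threshold tables (2^(-ddCt) method).

#' Read a long-format Ct table
#'
#' Expects a tab-separated table with columns `sample`, `gene`, `replicate`,
#' `ct` and optionally `biological` (biological-replicate index, for nested
#' averaging of technical within biological replicates).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with validated columns.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("Ct table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ct_table(df)
}

#' Validate a Ct table
#'
#' @param df Data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @return The validated data.frame.
#' @export
validate_ct_table <- function(df) {
  required <- c("sample", "gene", "replicate", "ct")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("Ct table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) {
    stop("all Ct values must be finite and > 0")
  }
  df
}

# Mean, variance-of-the-mean and n for one (sample, gene) group. With a
# `biological` column, technical replicates are averaged within each
# biological replicate first and the spread is taken across biologicals.
.ct_group_stats <- function(df, sample, gene) {
  rows <- df[df$sample == sample & df$gene == gene, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no Ct measurements for gene '", gene, "' in sample '", sample, "'")
  }
  vals <- if (!is.null(rows$biological)) {
    as.numeric(tapply(rows$ct, rows$biological, mean))
  } else {
    rows$ct
  }
  n <- length(vals)
  list(mean = mean(vals),
       var_of_mean = if (n > 1L) stats::var(vals) / n else 0,
       n = n)
}

#' Relative expression by the 2^(-ddCt) method
#'
#' Implements the standard Livak relative quantification. Per sample, the
#' replicate Ct values of the target and reference genes are averaged and
#' differenced (`dCt = mean Ct(gene) - mean Ct(reference)`); the test
#' condition is then normalised to the control
#' (`ddCt = dCt(test) - dCt(control)`), giving a fold change of `2^(-ddCt)`
#' and a log2 fold change of `-ddCt`. The standard error is propagated from
#' the replicate variances of the four (sample x gene) groups by the delta
#' method: on the log2 scale the variances of the four group means add; on
#' the fold scale `sem_fold = fold * ln(2) * sem_log2`.
#'
#' When the table has a `biological` column, technical replicates are
#' averaged within each biological replicate before any statistics
#' (nested averaging), so the SEM reflects biological spread.
#'
#' @param table Ct table as from [read_ct_table()].
#' @param gene Target gene id.
#' @param reference_gene Reference gene id (e.g. `"ACT1"`); must be measured
#'   in both samples.
#' @param test,control Sample labels of the test and control conditions.
#' @return A one-row data.frame of class `relative_expression` with columns
#'   `gene`, `test`, `control`, `delta_delta_ct`, `fold_change`,
#'   `log2_fold`, `sem_log2`, `sem_fold`.
#' @examples
#' ct <- data.frame(sample = rep(c("mut", "wt"), each = 2),
#'                  gene = rep(c("BIO4", "ACT1"), 2),
#'                  replicate = 1, ct = c(20, 15, 22, 15))
#' delta_delta_ct(ct, "BIO4", "ACT1", test = "mut", control = "wt")
#' @export
delta_delta_ct <- function(table, gene, reference_gene, test, control) {
  table <- validate_ct_table(table)
  g_test <- .ct_group_stats(table, test, gene)
  r_test <- .ct_group_stats(table, test, reference_gene)
  g_ctrl <- .ct_group_stats(table, control, gene)
  r_ctrl <- .ct_group_stats(table, control, reference_gene)

  d_ct_test <- g_test$mean - r_test$mean
  d_ct_ctrl <- g_ctrl$mean - r_ctrl$mean
  ddct <- d_ct_test - d_ct_ctrl
  fold <- 2^(-ddct)
  sem_log2 <- sqrt(g_test$var_of_mean + r_test$var_of_mean +
                     g_ctrl$var_of_mean + r_ctrl$var_of_mean)
  out <- data.frame(
    gene = gene, test = test, control = control,
    delta_delta_ct = ddct, fold_change = fold, log2_fold = -ddct,
    sem_log2 = sem_log2, sem_fold = fold * log(2) * sem_log2,
    stringsAsFactors = FALSE)
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' Relative expression for a panel of genes
#'
#' Convenience wrapper applying [delta_delta_ct()] to each target gene in the
#' table (every gene except the reference).
#'
#' @inheritParams delta_delta_ct
#' @param genes Target genes; defaults to all non-reference genes present.
#' @return A data.frame with one row per gene.
#' @export
qpcr_panel <- function(table, reference_gene, test, control, genes = NULL) {
  table <- validate_ct_table(table)
  if (is.null(genes)) genes <- setdiff(unique(table$gene), reference_gene)
  out <- do.call(rbind, lapply(genes, function(g) {
    delta_delta_ct(table, g, reference_gene, test, control)
  }))
  rownames(out) <- NULL
  out
}
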