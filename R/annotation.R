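#' Genome annotation objects
#'
#' A `genome_annotation` holds ordered gene coordinates: one row per gene with
#' its chromosome, BED-style 0-based half-open coordinates, strand, and the
#' per-chromosome rank of the gene along the chromosome (0-based, ordered by
#' start coordinate). The rank index is the frame on which cluster detection
#' operates: two genes are adjacent when their ranks on the same chromosome
#' differ by one.
#'
#' @param genes A data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   and optionally `strand` (one of `+`, `-`, `*`; defaults to `*`).
#' @return An object of class `genome_annotation`: the input data.frame sorted
#'   by chromosome and start, with an added integer `rank` column.
#' @examples
#' ann <- genome_annotation(data.frame(
#'   gene_id = c("g1", "g2", "g3"),
#'   chrom   = "chrI",
#'   start   = c(0, 2000, 4000),
#'   end     = c(1000, 3000, 5000)
#' ))
#' ann$rank
#' @export
genome_annotation <- function(genes) {
  stopifnot(is.data.frame(genes))
  required <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(genes) == 0L) {
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), rank = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("genome_annotation", "data.frame")
    return(out)
  }
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (is.null(genes$strand)) genes$strand <- "*"
  genes$strand <- as.character(genes$strand)

  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0L) {
    stop("duplicated gene_id in annotation: ", paste(utils::head(dup, 5L), collapse = ", "))
  }
  bad <- which(!(genes$start < genes$end))
  if (length(bad) > 0L) {
    stop("start must be < end (0-based half-open); offending gene(s): ",
         paste(genes$gene_id[utils::head(bad, 5L)], collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }

  ord <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, c("gene_id", "chrom", "start", "end", "strand"), drop = FALSE]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                           FUN = function(i) seq_along(i) - 1L)
  genes$rank <- as.integer(genes$rank)
  rownames(genes) <- NULL
  class(genes) <- c("genome_annotation", "data.frame")
  genes
}

#' Read gene coordinates from a BED-like file
#'
#' Parses a tab-separated BED file with at least four columns
#' (chrom, start, end, name); column 6, when present, is taken as the strand.
#' Coordinates follow the BED convention (0-based, half-open). Lines starting
#' with `#`, `track` or `browser` and blank lines are skipped.
#'
#' @param path Path to the BED file.
#' @return A [genome_annotation()].
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("annotation file is empty: ", path)
    return(genome_annotation(data.frame(gene_id = character(), chrom = character(),
                                        start = integer(), end = integer())))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("malformed BED line ", idx[which(nf < 4L)[1L]],
         ": fewer than 4 tab-separated columns")
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad) > 0L) {
    stop("malformed BED line ", idx[bad[1L]], ": non-integer start/end")
  }
  strand <- vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else "*", "")
  genome_annotation(data.frame(
    gene_id = vapply(fields, `[[`, "", 4L),
    chrom = vapply(fields, `[[`, "", 1L),
    start = starts,
    end = ends,
    strand = strand,
    stringsAsFactors = FALSE
  ))
}

#' Write an annotation to a BED file
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotation, path) {
  df <- as.data.frame(annotation)
  bed <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = df$gene_id, score = 0L, strand = df$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene families from a GMT file
#'
#' GMT is the standard gene-set format: one set per line, tab-separated, with
#' the set name in column 1, a free-text description in column 2, and member
#' gene ids in the remaining columns.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors, one per family.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("malformed GMT line ", short[1L], ": need name, description, >= 1 member")
  }
  fams <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(fams) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(fams))) {
    stop("duplicated family name in GMT: ",
         names(fams)[duplicated(names(fams))][1L])
  }
  fams
}

#' Write gene families to a GMT file
#'
#' @param families Named list of character vectors.
#' @param path Output path.
#' @param description Description placed in GMT column 2 (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(families, path, description = "na") {
  stopifnot(is.list(families), !is.null(names(families)))
  lines <- vapply(seq_along(families), function(i) {
    paste(c(names(families)[i], description, families[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x), "genes on",
      length(unique(x$chrom)), "chromosome(s)\n")
  if (nrow(x) > 0L) print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}
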