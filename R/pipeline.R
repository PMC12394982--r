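# End-to-end orchestration: simulate or ingest -> partition -> screen ->
# coherence -> report, with a validated single-file configuration.

.config_schema <- list(
  top = c("seed", "simulate", "inputs", "cluster", "screen", "coherence",
          "plots"),
  simulate = c("n_genes", "n_chromosomes", "families", "n_families",
               "family_size", "cluster_sizes", "n_mutants",
               "planted_disruptions", "noise_sd", "background_disruption_rate",
               "background_effect", "n_timepoints", "rho_cluster",
               "rho_singleton", "stressors", "gene_length", "intergenic",
               "seed"),
  inputs = c("bed", "gmt", "compendium", "manifest"),
  cluster = c("max_intervening", "max_gap_bp", "n_permutations", "alpha"),
  screen = c("threshold", "quantile", "tail", "kmeans_k"),
  coherence = c("aggregate", "kmeans_k")
)

#' Validate a pipeline run configuration
#'
#' A run configuration is a nested list (typically read from a YAML file)
#' with sections `simulate` or `inputs` (exactly one), and optional
#' `cluster`, `screen`, `coherence` and `plots` sections. Unknown keys are
#' rejected by name; every seed is explicit (top-level `seed` is required).
#'
#' @param config A named list, or the path to a YAML file.
#' @return The validated configuration list, invisibly usable downstream.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown) > 0L) {
      stop("unknown configuration key(s) in ", where, ": ",
           paste(unknown, collapse = ", "))
    }
  }
  check_keys(config, .config_schema$top, "top level")
  if (is.null(config$seed)) stop("configuration must set an explicit 'seed'")
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    stop("configuration needs exactly one of 'simulate' or 'inputs'")
  }
  if (has_sim) check_keys(config$simulate, .config_schema$simulate, "'simulate'")
  if (has_inp) {
    check_keys(config$inputs, .config_schema$inputs, "'inputs'")
    for (key in c("bed", "gmt")) {
      if (is.null(config$inputs[[key]])) {
        stop("'inputs' is missing required field '", key, "'")
      }
    }
  }
  for (sec in c("cluster", "screen", "coherence")) {
    if (!is.null(config[[sec]])) {
      check_keys(config[[sec]], .config_schema[[sec]],
                 paste0("'", sec, "'"))
    }
  }
  config
}

.cfg <- function(config, section, key, default) {
  val <- config[[section]][[key]]
  if (is.null(val)) default else val
}

#' Run the full cluster-coherence pipeline
#'
#' Executes the stages in dependency order: obtain data (simulated from the
#' `simulate` section, or loaded from the `inputs` paths), partition each
#' family into clustered/singleton subsets, assess clustering significance
#' by permutation, screen the mutant compendium for cluster-specific
#' disruption, and compute the clustered-vs-singleton coherence panel over
#' the time-courses. All tables are written to `out_dir` as TSV and a JSON
#' run report with parameters, per-stage record counts, warnings, and MD5
#' checksums of every output is written alongside. Reruns with the same
#' configuration reproduce identical checksums.
#'
#' @param config Configuration list or YAML path; see
#'   [validate_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The run report, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  warnings_log <- character()
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }
  outputs <- character()
  emit <- function(name) outputs <<- c(outputs, file.path(out_dir, name))

  seed <- as.integer(config$seed)
  # ---- stage 1: data ----
  compendium <- NULL
  timecourses <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- if (is.null(sim_args$seed)) seed else sim_args$seed
    sim_cfg <- do.call(simulation_config, sim_args)
    genome <- simulate_genome(sim_cfg)
    annotation <- genome$annotation
    families <- genome$families
    comp_sim <- simulate_compendium(genome, sim_cfg)
    compendium <- comp_sim$compendium
    tc_sim <- simulate_timecourses(truth_partitions(genome), sim_cfg)
    timecourses <- tc_sim$timecourses
    write_bed(annotation, file.path(out_dir, "genome.bed")); emit("genome.bed")
    write_gmt(families, file.path(out_dir, "families.gmt")); emit("families.gmt")
    truth <- list(genome = genome$truth, compendium = comp_sim$truth["planted_cells"],
                  timecourse = tc_sim$truth[c("rho_cluster", "rho_singleton")])
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    emit("truth.json")
  } else {
    annotation <- load_annotation(config$inputs$bed)
    families <- read_gmt(config$inputs$gmt)
    if (!is.null(config$inputs$compendium)) {
      compendium <- load_compendium(config$inputs$compendium)
    }
    if (!is.null(config$inputs$manifest)) {
      manifest <- yaml::read_yaml(config$inputs$manifest)
      base <- dirname(config$inputs$manifest)
      timecourses <- lapply(names(manifest), function(st) {
        path <- manifest[[st]]
        if (!file.exists(path)) path <- file.path(base, manifest[[st]])
        load_timecourse(path, stressor = st)
      })
    }
  }

  # ---- stage 2: partitions ----
  max_intervening <- .cfg(config, "cluster", "max_intervening", 0L)
  max_gap_bp <- .cfg(config, "cluster", "max_gap_bp", Inf)
  partitions <- lapply(names(families), function(fam) {
    detect_clusters(annotation, families[[fam]], fam,
                    max_intervening = max_intervening,
                    max_gap_bp = max_gap_bp)
  })
  names(partitions) <- names(families)
  unplaced <- sum(vapply(partitions, function(p) length(p$unplaced), 0L))
  if (unplaced > 0L) note(unplaced, " family gene(s) unplaced in annotation")
  ptab <- partition_table(partitions)
  utils::write.table(ptab, file.path(out_dir, "partitions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emit("partitions.tsv")

  # ---- stage 3: clustering significance ----
  n_perm <- .cfg(config, "cluster", "n_permutations", 1000L)
  alpha <- .cfg(config, "cluster", "alpha", 0.05)
  selected <- names(families)
  sig_results <- NULL
  if (n_perm > 0L) {
    sig_results <- lapply(names(families), function(fam) {
      clustering_significance(annotation, families[[fam]], fam,
                              max_intervening = max_intervening,
                              max_gap_bp = max_gap_bp,
                              n_permutations = n_perm, seed = seed)
    })
    sig_tab <- data.frame(
      family = vapply(sig_results, `[[`, "", "family_name"),
      observed_clustered = vapply(sig_results, `[[`, 0L,
                                  "observed_clustered_count"),
      p_value = vapply(sig_results, `[[`, 0, "p_value"),
      n_permutations = n_perm)
    utils::write.table(sig_tab, file.path(out_dir, "clustering_significance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("clustering_significance.tsv")
    selected <- select_clustered_families(sig_results, alpha = alpha)
    note(length(selected), " of ", length(families),
         " families pass clustering alpha = ", alpha)
  }

  # ---- stage 4: disruption screen ----
  screen <- NULL
  if (!is.null(compendium) && length(selected) > 0L) {
    screen <- disruption_screen(
      compendium, partitions[selected],
      threshold = .cfg(config, "screen", "threshold", 1),
      quantile = .cfg(config, "screen", "quantile", NULL),
      tail = .cfg(config, "screen", "tail", "upper"))
    kk <- .cfg(config, "screen", "kmeans_k", 3L)
    if (kk >= 1L && kk <= nrow(screen$scores)) {
      screen <- group_mutants(screen, k = kk, seed = seed)
    }
    write_matrix <- function(mat, name) {
      df <- data.frame(mutant = rownames(mat), mat, check.names = FALSE)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(name)
    }
    write_matrix(screen$pvalues, "pvalues.tsv")
    write_matrix(screen$scores, "scores.tsv")
    utils::write.table(screen$cells, file.path(out_dir, "cells.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("cells.tsv")
  }

  # ---- stage 5: coherence ----
  panel <- NULL
  if (!is.null(timecourses) && length(selected) > 0L) {
    panel <- coherence_panel(
      timecourses, partitions[selected],
      aggregate = .cfg(config, "coherence", "aggregate", "mean"),
      kmeans_k = .cfg(config, "coherence", "kmeans_k", NULL),
      seed = seed)
    write_cmat <- function(mat, name) {
      df <- data.frame(stressor = rownames(mat), mat, check.names = FALSE)
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit(name)
    }
    write_cmat(panel$family, "coherence_family.tsv")
    write_cmat(panel$clustered, "coherence_clustered.tsv")
    write_cmat(panel$singleton, "coherence_singleton.tsv")
    dev <- deviation_matrix(panel$clustered, panel$singleton)
    write_cmat(dev, "deviation.tsv")
    dev_long <- data.frame(
      stressor = rep(rownames(dev), times = ncol(dev)),
      family = rep(colnames(dev), each = nrow(dev)),
      deviation = as.vector(dev),
      abs_deviation = abs(as.vector(dev)))
    utils::write.table(dev_long, file.path(out_dir, "deviation_long.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("deviation_long.tsv")
  }

  # ---- stage 6: report ----
  checksums <- tools::md5sum(outputs)
  names(checksums) <- basename(outputs)
  report <- list(
    package = "clustercoherence",
    version = as.character(utils::packageVersion("clustercoherence")),
    parameters = config,
    counts = list(
      genes = nrow(annotation),
      families = length(families),
      families_selected = length(selected),
      mutants = if (is.null(compendium)) 0L else nrow(compendium$values),
      stressors = if (is.null(timecourses)) 0L else length(timecourses),
      partition_rows = nrow(ptab),
      screen_cells = if (is.null(screen)) 0L else nrow(screen$cells)),
    warnings = as.list(warnings_log),
    outputs = as.list(checksums),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(report)
}
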