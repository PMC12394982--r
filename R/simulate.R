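# Synthetic genomes, compendia, time-courses and Ct tables with planted,
# recorded structure, so every analysis stage has a recovery-based oracle.

.default_stressors <- c(
  "menadione_high", "menadione_low", "DTT", "hyperosmotic", "hypoosmotic",
  "diamide", "heat_29_33", "heat_30_37", "heat_25_37", "heat_37",
  "H2O2", "MMS", "nitrogen_starvation", "glucose_to_glycerol")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults mirror
#' the scale of the study design the package targets: a yeast-sized genome
#' (6000 genes on 16 chromosomes), 38 gene families whose members are partly
#' arranged in adjacent clusters, a compendium of 165 deletion mutants, and
#' 14 stress time-courses in which clustered genes share a latent response.
#' All sizes can be overridden for fast tests.
#'
#' @param n_genes Total genes in the genome.
#' @param n_chromosomes Number of chromosomes (genes split near-equally).
#' @param families List of family descriptors `list(name=, size=,
#'   cluster_sizes=)`, where `cluster_sizes` is an integer vector (each
#'   >= 2, possibly empty). `NULL` builds `n_families` families of
#'   `family_size` members with `cluster_sizes` each.
#' @param n_families,family_size,cluster_sizes Used only when
#'   `families = NULL`. Default: 38 families of 40 members with one triplet
#'   and two pair clusters each.
#' @param n_mutants Number of deletion mutants in the compendium.
#' @param planted_disruptions `NULL` or a data.frame with columns `mutant`,
#'   `family`, `target` (`"clustered"`, `"singleton"` or `"both"`),
#'   `effect` (log2 magnitude) and `penetrance` (fraction in \[0, 1\]).
#' @param noise_sd Baseline log2 noise s.d. of the compendium.
#' @param background_disruption_rate Fraction of (mutant, gene) cells given a
#'   background (cluster-agnostic) expression shift, for realism.
#' @param background_effect Log2 magnitude of the background shift.
#' @param n_timepoints Timepoints per stress time-course (>= 3).
#' @param rho_cluster,rho_singleton Latent-factor correlation of clustered
#'   and singleton genes (pairwise expected Pearson r within a cluster is
#'   `rho_cluster`).
#' @param stressors Character vector of stressor names.
#' @param gene_length,intergenic Gene length and intergenic gap in bp used to
#'   lay out coordinates.
#' @param seed Integer master seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 6000L, n_chromosomes = 16L,
                              families = NULL, n_families = 38L,
                              family_size = 40L,
                              cluster_sizes = c(3L, 2L, 2L),
                              n_mutants = 165L,
                              planted_disruptions = NULL,
                              noise_sd = 0.25,
                              background_disruption_rate = 0.05,
                              background_effect = 2,
                              n_timepoints = 8L,
                              rho_cluster = 0.7, rho_singleton = 0,
                              stressors = .default_stressors,
                              gene_length = 1000L, intergenic = 200L,
                              seed = 1L) {
  if (is.null(families)) {
    families <- lapply(seq_len(n_families), function(i) {
      list(name = sprintf("family%02d", i), size = as.integer(family_size),
           cluster_sizes = as.integer(cluster_sizes))
    })
  }
  for (f in families) {
    stopifnot(!is.null(f$name), !is.null(f$size))
    if (length(f$cluster_sizes) > 0L && any(f$cluster_sizes < 2L)) {
      stop("cluster sizes must be >= 2 (family '", f$name, "')")
    }
    if (sum(f$cluster_sizes) > f$size) {
      stop("total clustered genes exceed family size (family '", f$name, "')")
    }
  }
  if (sum(vapply(families, `[[`, 0L, "size")) > n_genes) {
    stop("family members exceed n_genes")
  }
  stopifnot(noise_sd >= 0, background_disruption_rate >= 0,
            background_disruption_rate <= 1, n_timepoints >= 3L,
            rho_cluster >= 0, rho_cluster <= 1,
            rho_singleton >= 0, rho_singleton <= 1)
  if (!is.null(planted_disruptions)) {
    stopifnot(is.data.frame(planted_disruptions),
              all(c("mutant", "family", "target", "effect", "penetrance")
                  %in% names(planted_disruptions)),
              all(planted_disruptions$target
                  %in% c("clustered", "singleton", "both")),
              all(planted_disruptions$penetrance >= 0),
              all(planted_disruptions$penetrance <= 1))
  }
  structure(list(
    n_genes = as.integer(n_genes), n_chromosomes = as.integer(n_chromosomes),
    families = families, n_mutants = as.integer(n_mutants),
    planted_disruptions = planted_disruptions, noise_sd = noise_sd,
    background_disruption_rate = background_disruption_rate,
    background_effect = background_effect,
    n_timepoints = as.integer(n_timepoints),
    rho_cluster = rho_cluster, rho_singleton = rho_singleton,
    stressors = stressors, gene_length = as.integer(gene_length),
    intergenic = as.integer(intergenic), seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a genome with planted family clusters
#'
#' Lays `n_genes` out on `n_chromosomes` with regular coordinates, then
#' places each family: clusters first, as adjacent runs at uniform random
#' non-overlapping positions, then the remaining members as singletons at
#' positions with no same-family neighbour (so no accidental clusters
#' arise). Placement is retried a bounded number of times; persistent
#' failure raises an error suggesting a larger genome. Strands are drawn
#' uniformly, and are irrelevant to clustering.
#'
#' @param config A [simulation_config()].
#' @param seed Seed; defaults to `config$seed`.
#' @return A list with `annotation` (a [genome_annotation()]), `families`
#'   (named list of member id vectors) and `truth` (the planted placements:
#'   per family, `clusters` as a list of gene-id runs and `singletons`).
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$n_genes
  chrom_of <- sort(rep_len(seq_len(config$n_chromosomes), n))
  idx_in_chrom <- stats::ave(seq_len(n), chrom_of, FUN = seq_along)
  step <- config$gene_length + config$intergenic
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = sprintf("chr%02d", chrom_of),
    start = (idx_in_chrom - 1L) * step,
    end = (idx_in_chrom - 1L) * step + config$gene_length,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE)

  occupied <- logical(n)            # gene already assigned to some family
  fam_of <- character(n)            # family owning each position ("" = none)
  chrom_id <- chrom_of              # integer chromosome per global index

  neighbour_same_family <- function(pos, fam) {
    for (d in c(-1L, 1L)) {
      q <- pos + d
      if (q >= 1L && q <= n && chrom_id[q] == chrom_id[pos] &&
          fam_of[q] == fam) return(TRUE)
    }
    FALSE
  }

  truth_families <- list()
  members_list <- list()
  for (f in config$families) {
    fam <- f$name
    clusters <- list()
    for (s in f$cluster_sizes) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        pos0 <- sample.int(n - s + 1L, 1L)
        window <- pos0:(pos0 + s - 1L)
        if (length(unique(chrom_id[window])) != 1L) next
        if (any(occupied[window])) next
        # buffer: no same-family gene immediately flanking the run
        if (neighbour_same_family(window[1L], fam) ||
            neighbour_same_family(window[s], fam)) next
        occupied[window] <- TRUE
        fam_of[window] <- fam
        clusters <- c(clusters, list(genes$gene_id[window]))
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place a cluster of size ", s, " for family '", fam,
             "'; increase n_genes or reduce cluster sizes")
      }
    }
    n_singletons <- f$size - sum(f$cluster_sizes)
    singles <- character(n_singletons)
    for (i in seq_len(n_singletons)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        pos <- sample.int(n, 1L)
        if (occupied[pos]) next
        if (neighbour_same_family(pos, fam)) next
        occupied[pos] <- TRUE
        fam_of[pos] <- fam
        singles[i] <- genes$gene_id[pos]
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place a singleton for family '", fam,
             "'; increase n_genes")
      }
    }
    truth_families[[fam]] <- list(clusters = clusters,
                                  singletons = sort(singles))
    members_list[[fam]] <- c(unlist(clusters, use.names = FALSE), singles)
  }

  list(annotation = genome_annotation(genes),
       families = members_list,
       truth = list(families = truth_families, seed = seed))
}

#' Simulate a deletion-mutant expression compendium
#'
#' Baseline log2 ratios are Gaussian noise. Each planted disruption adds a
#' shift of magnitude `effect` (sign drawn per gene and recorded) to the
#' target subset of the named family in the named mutant, each gene
#' independently with probability `penetrance`. A background disruption of
#' magnitude `background_effect` is applied to a random
#' `background_disruption_rate` fraction of the remaining cells, with no
#' cluster preference.
#'
#' @param genome Output of [simulate_genome()].
#' @param config A [simulation_config()].
#' @param seed Seed; defaults to `config$seed + 1`.
#' @return A list with `compendium` (an [expression_compendium()]) and
#'   `truth` (`planted_cells`: data.frame of mutant, family, gene, shift;
#'   `background_cells`: count per mutant).
#' @export
simulate_compendium <- function(genome, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  gene_ids <- genome$annotation$gene_id
  mutants <- sprintf("mut%03d", seq_len(config$n_mutants))
  values <- matrix(stats::rnorm(length(mutants) * length(gene_ids),
                                sd = config$noise_sd),
                   nrow = length(mutants),
                   dimnames = list(mutants, gene_ids))

  planted <- config$planted_disruptions
  planted_cells <- NULL
  if (!is.null(planted) && nrow(planted) > 0L) {
    rows <- vector("list", nrow(planted))
    for (i in seq_len(nrow(planted))) {
      pd <- planted[i, ]
      if (!pd$mutant %in% mutants) stop("unknown planted mutant: ", pd$mutant)
      tf <- genome$truth$families[[pd$family]]
      if (is.null(tf)) stop("unknown planted family: ", pd$family)
      target <- switch(pd$target,
        clustered = unlist(tf$clusters, use.names = FALSE),
        singleton = tf$singletons,
        both = c(unlist(tf$clusters, use.names = FALSE), tf$singletons))
      hit <- target[stats::runif(length(target)) < pd$penetrance]
      if (length(hit) > 0L) {
        shift <- sample(c(-1, 1), length(hit), replace = TRUE) * pd$effect
        values[pd$mutant, hit] <- values[pd$mutant, hit] + shift
        rows[[i]] <- data.frame(mutant = pd$mutant, family = pd$family,
                                gene = hit, shift = shift,
                                stringsAsFactors = FALSE)
      }
    }
    planted_cells <- do.call(rbind, rows)
  }

  background_cells <- integer(length(mutants))
  names(background_cells) <- mutants
  if (config$background_disruption_rate > 0) {
    planted_key <- if (is.null(planted_cells)) character() else
      paste(planted_cells$mutant, planted_cells$gene)
    mask <- matrix(stats::runif(length(values)) <
                     config$background_disruption_rate,
                   nrow = nrow(values), dimnames = dimnames(values))
    if (length(planted_key) > 0L) {
      key <- outer(mutants, gene_ids, paste)
      mask[key %in% planted_key] <- FALSE
    }
    signs <- sample(c(-1, 1), sum(mask), replace = TRUE)
    values[mask] <- values[mask] + signs * config$background_effect
    background_cells <- rowSums(mask)
  }

  list(compendium = expression_compendium(values),
       truth = list(planted_cells = planted_cells,
                    background_cells = background_cells,
                    seed = seed))
}

#' Simulate stress-response time-courses
#'
#' For every stressor, each cluster of each family receives its own latent
#' response profile (standard normal per timepoint); each clustered gene is
#' `sqrt(rho_cluster) * latent + sqrt(1 - rho_cluster) * noise`, so the
#' expected pairwise Pearson correlation of two genes in the same cluster is
#' `rho_cluster`. Singleton members of a family share an analogous
#' family-level latent with weight `rho_singleton`. Only family genes are
#' emitted (plus optional extra noise genes).
#'
#' @param partitions List of [detect_clusters()] partitions (or the
#'   `families`/`truth` of [simulate_genome()] converted to partitions).
#' @param config A [simulation_config()].
#' @param seed Seed; defaults to `config$seed + 2`.
#' @param n_noise_genes Extra unrelated pure-noise genes to include.
#' @return A list with `timecourses` (list of [time_course()]) and `truth`
#'   (realized latents per stressor, plus the rho values).
#' @export
simulate_timecourses <- function(partitions, config, seed = config$seed + 2L,
                                 n_noise_genes = 0L) {
  stopifnot(inherits(config, "simulation_config"))
  if (inherits(partitions, "cluster_partition")) partitions <- list(partitions)
  set.seed(seed)
  tp <- config$n_timepoints
  tp_labels <- paste0("min", seq(0L, by = 15L, length.out = tp))
  rc <- config$rho_cluster
  rs <- config$rho_singleton

  latents <- list()
  tcs <- lapply(config$stressors, function(st) {
    rows <- list()
    lat_st <- list()
    for (p in partitions) {
      fam_lat <- list(clusters = list(), singleton = NULL)
      for (ci in seq_along(p$clusters)) {
        lat <- stats::rnorm(tp)
        fam_lat$clusters[[ci]] <- lat
        for (g in p$clusters[[ci]]) {
          rows[[g]] <- sqrt(rc) * lat + sqrt(1 - rc) * stats::rnorm(tp)
        }
      }
      if (length(p$singletons) > 0L) {
        lat <- stats::rnorm(tp)
        fam_lat$singleton <- lat
        for (g in p$singletons) {
          rows[[g]] <- sqrt(rs) * lat + sqrt(1 - rs) * stats::rnorm(tp)
        }
      }
      lat_st[[p$family]] <- fam_lat
    }
    if (n_noise_genes > 0L) {
      for (i in seq_len(n_noise_genes)) {
        rows[[sprintf("noise%04d", i)]] <- stats::rnorm(tp)
      }
    }
    latents[[st]] <<- lat_st
    values <- do.call(rbind, rows)
    colnames(values) <- tp_labels
    time_course(values, stressor = st, provenance = "synthetic")
  })
  list(timecourses = tcs,
       truth = list(rho_cluster = rc, rho_singleton = rs,
                    latents = latents, seed = seed))
}

#' Simulate a long-format qPCR Ct table
#'
#' Generates technical-within-biological replicate Ct values for a panel of
#' target genes plus a reference gene, in a test and a control sample, with
#' known planted log2 fold changes (`log2_fold = -ddCt`, so a planted value
#' of 2 yields a fourfold induction).
#'
#' @param genes Character vector of target gene ids.
#' @param log2_fold Named numeric vector of planted log2 fold changes (test
#'   vs control), one per gene.
#' @param reference_gene Reference gene id.
#' @param test,control Sample labels.
#' @param n_biological,n_technical Replicate structure.
#' @param base_ct,ref_ct Mean Ct of targets (control) and of the reference.
#' @param noise_sd Ct noise s.d. (applied per technical replicate).
#' @param bio_sd Biological replicate Ct s.d.
#' @param seed Integer seed.
#' @return A list with `table` (data.frame: sample, gene, biological,
#'   replicate, ct) and `truth` (the planted log2 folds).
#' @export
simulate_ct_table <- function(genes, log2_fold, reference_gene = "ACT1",
                              test = "mutant", control = "WT",
                              n_biological = 2L, n_technical = 3L,
                              base_ct = 20, ref_ct = 15,
                              noise_sd = 0.1, bio_sd = 0.1, seed = 1L) {
  stopifnot(all(genes %in% names(log2_fold)))
  set.seed(seed)
  rows <- list()
  for (smp in c(test, control)) {
    for (g in c(genes, reference_gene)) {
      mean_ct <- if (g == reference_gene) {
        ref_ct
      } else if (smp == test) {
        base_ct - log2_fold[[g]]   # lower Ct = higher expression
      } else {
        base_ct
      }
      for (b in seq_len(n_biological)) {
        bio_shift <- stats::rnorm(1L, sd = bio_sd)
        for (r in seq_len(n_technical)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = smp, gene = g, biological = b, replicate = r,
            ct = mean_ct + bio_shift + stats::rnorm(1L, sd = noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(table = do.call(rbind, rows),
       truth = list(log2_fold = log2_fold, seed = seed))
}

#' Partitions implied by a simulated genome's truth
#'
#' Convenience accessor that rebuilds `cluster_partition` objects directly
#' from the planted truth (no detection involved), for oracle-style tests
#' and for feeding the coherence simulator.
#'
#' @param genome Output of [simulate_genome()].
#' @param max_intervening,max_gap_bp Parameters recorded on the partitions.
#' @return Named list of `cluster_partition` objects.
#' @export
truth_partitions <- function(genome, max_intervening = 0L, max_gap_bp = Inf) {
  out <- lapply(names(genome$truth$families), function(fam) {
    tf <- genome$truth$families[[fam]]
    structure(list(
      family = fam,
      members = c(unlist(tf$clusters, use.names = FALSE), tf$singletons),
      clusters = tf$clusters,
      singletons = tf$singletons,
      unplaced = character(),
      params = list(max_intervening = as.integer(max_intervening),
                    max_gap_bp = max_gap_bp)
    ), class = "cluster_partition")
  })
  names(out) <- names(genome$truth$families)
  out
}
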