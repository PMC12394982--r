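---
title: "Methods: detecting functional gene clusters and measuring their transcriptional coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting functional gene clusters and measuring their transcriptional coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustercoherence)
```

## The question

In budding yeast, many functionally related gene families — ribosomal
proteins, ribosome-biogenesis factors, vitamin-metabolic enzymes and others —
place a fraction of their members in adjacent chromosomal runs ("functional
gene clusters") while the remaining members sit in isolation as singletons.
Two empirical questions follow:

1. Do chromatin-remodeler deletion mutants disrupt transcription
   *specifically* in the clustered subset of a family, beyond what their
   overall disruption level predicts?
2. Across stress-response time-courses, are clustered members more
   transcriptionally coherent (mutually correlated) than the singleton
   members of the same family?

This package implements the full analysis path for both questions, plus a
synthetic-data generator with planted effects so that every stage can be
validated by recovery rather than by eyeballing.

## Cluster detection

Genes are ordered per chromosome by start coordinate (BED convention,
0-based half-open), giving each gene an integer rank. A cluster of a family
is a maximal run of members in which consecutive members are separated by at
most `max_intervening` non-family genes and at most `max_gap_bp` base pairs.

* `max_intervening = 0` by default: strict adjacency. The well-characterised
  validation clusters in this system — a *BIO5–BIO4–BIO3*-style triplet, a
  convergent pair, a tandem pair — are all immediately adjacent, and a strict
  default makes the detected runs unambiguous. The parameter is exposed for
  analyses that want to tolerate interleaved genes.
* `max_gap_bp = Inf` by default: adjacency is a rank notion; the bp bound is
  an optional extra constraint and the only place where the coordinate
  convention matters.
* Strand is recorded but ignored: tandem, convergent and divergent
  arrangements all count as clustered.

Family members absent from the annotation are reported as `unplaced` and
excluded from both subsets — never silently dropped, because a partition that
quietly loses genes corrupts every downstream count.

## Clustering significance

Whether a family clusters "more than expected" is assessed by a permutation
null that preserves the genome and relabels membership: each permutation
assigns the family to a uniform random subset of annotated genes of the same
size, re-detects runs, and records the number of member genes inside runs.
This preserves chromosome number, gene density and genome architecture
exactly, which a coordinate-shuffling null would not. The p-value uses the
standard pseudo-count form

$$p = \frac{1 + \#\{T_\text{null} \ge T_\text{obs}\}}{1 + B}$$

so it is never exactly zero and is super-uniform under the null (verified by
simulation in the test suite, and exactly against complete placement
enumeration on a 30-gene genome where all $\binom{30}{3}$ placements can be
scored). Families are retained when $p \le \alpha$ with $\alpha = 0.05$,
boundary inclusive.

## The disruption screen

For one mutant, a gene is *disrupted* when its absolute log2 expression
ratio versus wild type reaches a threshold. The compendium this analysis is
designed for does not publish the cutoff it used, so the package defaults to
`threshold = 1` (2-fold), the conventional microarray choice, and also
offers a quantile mode (top fraction by absolute ratio) for compendia whose
scale is unknown. Genes missing in a mutant's profile are removed from that
mutant's universe entirely — from $N$, $K$, $m$, $n$ and $x$ — on a per-cell
basis, never list-wise across mutants.

Given, for one (mutant, family) cell,

* $N$ — measured genes in this mutant, $K$ — disrupted among them,
* $m$ — clustered-subset members among the measured genes,
* $x$ — disrupted genes inside the clustered subset,

the cell's statistic is the upper hypergeometric tail

$$P \;=\; \Pr(X \ge x), \qquad X \sim \mathrm{Hypergeom}(N, K, m),$$

the probability that at least the observed number of disrupted genes would
land in the clustered subset if disruption were placed at random among the
measured genes. Two modelling choices deserve a note:

* **Tail direction.** The upper tail is the reading consistent with scoring
  *disruption of* the clustered subset; the lower tail (depletion) is
  available behind the `tail` argument.
* **Sampling frame.** The clustered subset (size $m$) is the draw and the
  $K$ disrupted genes are the successes in the population of all $N$
  measured genes. Descriptions of this statistic sometimes conflate the
  clustered-subset size with the observed success count; the implementation
  keeps them separate as $m$ and $x$.

The tail is computed by a log-space sum of `lchoose` terms
(log-sum-exp), exact at $x=0$ by construction and stable to $N \sim 10^5$;
the test suite checks agreement with brute-force binomial-coefficient
enumeration to $10^{-12}$ for every valid case with $N \le 30$, and against
`phyper` as an independent library cross-check.

For visualisation the p-values are transformed to a deviation score
$1 - P$ (the distance from 1), so strong cluster-specific disruption
approaches 1. No multiple-testing correction enters the scores; a
Benjamini–Hochberg column is emitted alongside as a convenience and is
clearly an extension. Mutants are grouped by k-means on their score rows
(`k = 3` by default, matching the three qualitative behaviours this kind of
screen separates: global disruptors, family-specific disruptors, negligible
effect), with a fixed seed, 10 restarts, and no row re-scaling since scores
already live in $[0,1]$. Not-applicable cells (families whose clustered
subset vanishes after intersection with the measured genes) are excluded
from scoring and imputed as 0 only for the k-means step.

## Transcriptional coherence

The coherence of a gene set across a time-course is the mean Pearson
correlation over all unordered pairs of distinct gene profiles. Choices:

* **Aggregation.** The mean over pairs (median available by flag).
* **Missing data.** Genes with any missing timepoint are excluded list-wise
  per stressor before the calculation — not pairwise-complete correlation —
  so every pair is computed on the same timepoints.
* **Zero-variance profiles** are excluded (Pearson r is undefined for them)
  and counted in the `n_used`/`n_excluded` attributes.
* **Not-applicable is not zero.** A subset with fewer than two usable genes
  yields `NA`, which propagates; collapsing it to 0 would fabricate
  "no correlation" out of "no data".

For each family the coherence is computed three ways on the same matrix —
whole family, clustered subset (all clusters pooled), singleton subset — and
the stressor × family matrices of subset coherences are differenced cell by
cell into the deviation matrix

$$\Delta = \mathrm{PCC}_\text{clustered} - \mathrm{PCC}_\text{singleton}.$$

The signed difference is used because positive and negative deviations mean
different things biologically (clusters more coherent vs less coherent than
singletons); the unsigned distance is emitted as an extra column for users
who want a magnitude. Coherence is computed per stressor, never on a
concatenation across stressors, so each cell is interpretable as a response
to one stimulus.

One property of pooling deserves emphasis: each cluster has its own latent
response, so when a family has several clusters the pooled clustered-subset
PCC includes cross-cluster pairs and is *diluted* relative to the
within-cluster correlation. Recovery checks of a planted within-cluster
correlation therefore use single-cluster families; on real families the
pooled value is a conservative summary of within-cluster coherence.

## qPCR quantification

Relative expression uses the standard Livak $2^{-\Delta\Delta C_T}$ method:
replicate $C_T$ values are averaged per (sample, gene) group,
$\Delta C_T = \overline{C_T}(\text{gene}) - \overline{C_T}(\text{reference})$
per sample, $\Delta\Delta C_T = \Delta C_T(\text{test}) -
\Delta C_T(\text{control})$, fold change $2^{-\Delta\Delta C_T}$. Averaging
means before differencing (rather than pairing replicates) matches the
canonical formulation. When a `biological` column is present, technical
replicates are averaged within each biological replicate first (nested
averaging), so the error reflects biological spread and unbalanced technical
replication cannot skew the mean. The standard error is propagated by the
delta method: on the log2 scale the variances of the four group means add,
$\mathrm{SEM}_{\log_2} = \sqrt{\sum_i s_i^2/n_i}$, and on the fold scale
$\mathrm{SEM}_\text{fold} = \text{fold} \cdot \ln 2 \cdot
\mathrm{SEM}_{\log_2}$. Exact invariants — swapping test and control negates
the log2 fold; adding a constant to every $C_T$ changes nothing — are
enforced in the tests.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the study
conditions the package targets: a yeast-scale genome (6000 genes, 16
chromosomes), 38 families whose members are partly clustered, 165 deletion
mutants, 14 stress time-courses. Each piece emulates the statistical
structure the analysis assumes, not the physics of microarrays:

* **Genome.** Genes laid out at regular coordinates; each family's clusters
  placed as adjacent runs at uniform random non-overlapping positions, then
  singletons at positions with no same-family neighbour, so no accidental
  runs arise and the planted partition is the unique correct answer.
  Placement failure after bounded retries is an error suggesting a larger
  genome, never a silent partial placement.
* **Compendium.** Baseline log2 ratios are Gaussian
  (`noise_sd = 0.25`); planted disruptions add $\pm$`effect` (sign drawn per
  gene, recorded in the truth) to the target subset with the given
  penetrance; a background disruption rate (default 5%, magnitude 2) hits
  random cells with no cluster preference, which both adds realism and makes
  the null calibration non-trivial ($K > 0$). Gaussian noise is sufficient
  because the screen consumes thresholded calls only; heavy-tailed
  microarray error models would change nothing downstream of the threshold.
* **Time-courses.** One latent profile per (stressor, cluster), standard
  normal per timepoint; a clustered gene is $\sqrt{\rho_c}\,\text{latent} +
  \sqrt{1-\rho_c}\,\text{noise}$, so the expected pairwise correlation
  within a cluster is exactly $\rho_c$. Singletons share an analogous
  family-level latent with weight $\rho_s$. The exchangeable single-latent
  structure is the simplest model producing the clustered-vs-singleton
  coherence contrast; it requires $\rho \ge 0$. Defaults
  $\rho_c = 0.7$, $\rho_s = 0$.
* **Ct tables.** Known log2 folds converted to Ct shifts with technical-
  within-biological noise.

Everything is deterministic given `(config, seed)`, byte-for-byte in the
emitted files, and every generator returns the realized truth alongside the
data so that expected outcomes are computable without re-running the
analysis.

What passing the recovery tests does **not** show about real data: real
compendia have correlated noise across genes (shared hybridisation
artefacts), mutant-specific measurement quality, and essential genes missing
entirely; real time-courses have autocorrelated timepoints and
non-exchangeable cluster structure. The tests validate the *statistics*
— calibration of the hypergeometric null, recovery of planted contrasts —
not the biology.

## Validation problem sizes

The test suite and the acceptance script use deliberately small problem
sizes chosen to give tight Monte-Carlo error at interactive runtimes: the
hypergeometric sweep covers every valid case with $N \le 30$ (~128k tails);
null calibration uses 200 compendia of 20 mutants × 10 families on a
300-gene genome (40k p-values, so the binomial standard error at
$\alpha = 0.05$ is ~0.001); planted-disruption recovery uses 100 replicate
compendia; coherence recovery uses 100 replicate stressors at 50 genes × 8
timepoints; and the permutation-vs-enumeration check uses a 30-gene genome
where complete enumeration is exact. With 8 timepoints the pairwise Pearson
estimator has a small negative bias ($E[r] \approx \rho(1 -
(1-\rho^2)/(2(T-1))) \approx 0.674$ at $\rho = 0.7$), which the ±0.1
recovery tolerance accommodates; the tolerance is a property of the
estimator at that sample size, not a fudge.

## Known limitations

* The permutation null relabels genes uniformly; it does not preserve
  chromatin-domain structure or gene-length biases, so families confined to
  unusual genomic contexts may be mis-calibrated in ways uniform relabelling
  cannot see.
* The disruption threshold is a free parameter; absolute reproduction of any
  particular published screen requires knowing its cutoff, which is not
  always reported. Conclusions should be checked across thresholds.
* The hypergeometric frame treats genes as exchangeable within a mutant;
  co-regulation of neighbours *outside* the family (neighboring-gene
  effects) violates exchangeability and can inflate apparent
  cluster-specificity — this is precisely the effect the screen is designed
  to detect, but it cannot distinguish direct from indirect (epistatic)
  disruption.
* Subset-coherence differences are reported, not tested: no significance
  test for $\Delta$ is fabricated. Bootstrap machinery over gene pairs can
  be built from `mean_pairwise_pcc` if a user wants one, but none is
  endorsed as canonical.

## A worked micro-example

```{r example}
cfg <- simulation_config(
  n_genes = 300, n_chromosomes = 4, n_families = 4, family_size = 12,
  cluster_sizes = c(3, 2), n_mutants = 10,
  planted_disruptions = data.frame(
    mutant = "mut001", family = "family01",
    target = "clustered", effect = 2, penetrance = 1),
  stressors = c("DTT", "hyperosmotic"), seed = 7)

genome <- simulate_genome(cfg)
parts <- lapply(names(genome$families), function(f)
  detect_clusters(genome$annotation, genome$families[[f]], f))

sig <- clustering_significance(genome$annotation, genome$families[[1]],
                               "family01", n_permutations = 500, seed = 7)
sig

comp <- simulate_compendium(genome, cfg)
scr <- disruption_screen(comp$compendium, parts, threshold = 1)
round(scr$scores[1:3, ], 3)

tcs <- simulate_timecourses(parts, cfg)
panel <- coherence_panel(tcs$timecourses, parts)
round(deviation_matrix(panel$clustered, panel$singleton), 3)
```

The planted (mutant, family) cell scores near 1 while unplanted cells score
near 0, and the deviation matrix is positive: the clustered subsets are more
coherent than the singletons, as planted.
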