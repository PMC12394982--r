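Package: clustercoherence
Title: Transcriptional Coordination of Functional Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether functionally related gene families that
    form chromosomal clusters are transcriptionally coordinated. Detects
    clustered subsets of gene families from gene coordinates, assesses
    clustering significance by permutation, screens deletion-mutant expression
    compendia for cluster-specific transcriptional disruption with a
    hypergeometric tail statistic, quantifies clustered-versus-singleton
    transcriptional coherence across stress time-courses as mean pairwise
    Pearson correlation, and computes qPCR relative expression by the
    2^(-ddCt) method. A synthetic-data generator with planted effects makes
    every stage of the pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
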