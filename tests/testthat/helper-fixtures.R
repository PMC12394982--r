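# Shared fixtures built in code.

# Evenly spaced genes: n per chromosome layout, 1 kb genes with 1 kb gaps.
toy_annotation <- function(n, n_chrom = 1L, prefix = "g") {
  chrom <- sort(rep_len(seq_len(n_chrom), n))
  idx <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  genome_annotation(data.frame(
    gene_id = paste0(prefix, seq_len(n)),
    chrom = paste0("chr", chrom),
    start = (idx - 1L) * 2000L,
    end = (idx - 1L) * 2000L + 1000L,
    strand = rep(c("+", "-"), length.out = n)))
}

# Rank-based AUC: P(score_pos > score_neg), ties counted half.
rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Brute-force upper-tail hypergeometric by direct binomial-coefficient sums;
# independent oracle for hypergeom_tail().
enum_hyper_tail <- function(N, K, m, x) {
  j <- x:m
  sum(choose(K, j) * choose(N - K, m - j)) / choose(N, m)
}
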