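# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and wilcox.test / p.adjust): straight
# enumeration, brute-force scans and hand arithmetic.

# Exact two-sided rank-sum p by full enumeration of rank assignments
# (no ties assumed). W is the Mann-Whitney U of group x.
enum_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(N, m)
  w_all <- colSums(matrix(seq_len(N)[combos], nrow = m)) - m * (m + 1) / 2
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  list(statistic = w_obs, p = min(1, 2 * min(lo, hi)))
}

# Monte-Carlo permutation p for the rank-sum statistic (midranks kept).
perm_ranksum_p <- function(x, y, B = 1e5, seed = 1) {
  set.seed(seed)
  m <- length(x); N <- m + length(y)
  r <- rank(c(x, y))
  center <- m * (N + 1) / 2
  w_obs <- sum(r[seq_len(m)])
  w_perm <- vapply(seq_len(B), function(i) sum(r[sample.int(N, m)]), 0)
  mean(abs(w_perm - center) >= abs(w_obs - center) - 1e-9)
}

# BH step-up from its definition: q_(i) = min_{j>=i} p_(j) * m / j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force feature labels for one position against gene_model objects:
# plain loops over the stored intervals, same label semantics as the
# annotator contract (multi-label, ncRNA for noncoding transcript bodies,
# strand-aware flanks, intergenic when nothing overlaps).
brute_labels <- function(chrom, pos, models) {
  labs <- character()
  for (m in models) {
    if (m$chrom != chrom) next
    f <- m$features
    for (k in seq_len(nrow(f)))
      if (pos >= f$start[k] && pos <= f$end[k]) labs <- c(labs, f$feature[k])
    if (!m$coding && pos >= m$tx_start && pos <= m$tx_end)
      labs <- c(labs, "ncRNA")
    if (!is.null(m$flanks)) {
      fl <- m$flanks
      for (k in seq_len(nrow(fl)))
        if (pos >= fl$start[k] && pos <= fl$end[k])
          labs <- c(labs, fl$feature[k])
    }
  }
  if (length(labs) == 0) "intergenic" else sort(unique(labs))
}

# Small fully-paired editing matrix from an explicit value matrix.
toy_matrix <- function(values, pos = NULL) {
  n_p <- ncol(values) / 2
  if (is.null(pos)) pos <- 100L * seq_len(nrow(values))
  sites <- genomic_sites("chrT", pos)
  colnames(values) <- c(paste0("t", seq_len(n_p)), paste0("n", seq_len(n_p)))
  editing_matrix(values, sites,
                 condition = rep(c("tumor", "normal"), each = n_p),
                 pair_id = rep(paste0("p", seq_len(n_p)), 2))
}

# Hand-written SAM over a short reference, for CIGAR/quality edge cases.
write_toy_sam <- function(records, ref_name = "amp", ref_len = 50,
                          path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", ref_name, "\tLN:", ref_len),
               records), path)
  path
}

sam_read <- function(qname, pos, cigar, seq, qual = strrep("I", nchar(seq)),
                     mapq = 60, ref = "amp") {
  paste(qname, 0, ref, pos, mapq, cigar, "*", 0, 0, seq, qual, sep = "\t")
}
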