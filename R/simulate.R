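#' Specification for a synthetic paired tumor/normal editing cohort
#'
#' Null sites draw editing levels independently from a Beta distribution
#' in both conditions; truly differential sites shift the tumor values
#' additively by `delta` (clipped to [0, 1]). The defaults emulate a
#' desk-scale breast cancer cohort: 100 tumor/normal pairs, 1,000 sites,
#' low-level background editing Beta(2, 40) (mean about 4.8%), 10%
#' missingness.
#'
#' @param n_pairs number of tumor/normal pairs.
#' @param n_sites total number of sites.
#' @param n_diff number of truly differential sites (tumor-shifted).
#' @param base_alpha,base_beta Beta parameters of the null editing level.
#' @param delta additive tumor shift for differential sites (proportion).
#' @param missing_rate per-cell probability of missingness, in [0, 1).
#' @param seed integer RNG seed.
#' @return list of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(n_pairs = 100L, n_sites = 1000L, n_diff = 50L,
                            base_alpha = 2, base_beta = 40, delta = 0.15,
                            missing_rate = 0.1, seed = 1L) {
  if (n_diff > n_sites) stop("n_diff must not exceed n_sites")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  base_mean <- base_alpha / (base_alpha + base_beta)
  if (base_mean + delta > 1)
    stop("infeasible spec: base mean + delta exceeds 1")
  structure(list(n_pairs = as.integer(n_pairs), n_sites = as.integer(n_sites),
                 n_diff = as.integer(n_diff), base_alpha = base_alpha,
                 base_beta = base_beta, delta = delta,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

#' Simulate a paired tumor/normal editing matrix with known truth
#'
#' @param spec a [cohort_sim_spec()].
#' @return list with `matrix` (an [editing_matrix()]) and `truth`
#'   (data.frame site_id, is_diff, true_delta).
#' @export
simulate_cohort_matrix <- function(spec) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  set.seed(spec$seed)
  n_s <- spec$n_sites; n_p <- spec$n_pairs
  sites <- genomic_sites(chrom = "chrS",
                         pos = 1000L + 100L * seq_len(n_s))
  diff_idx <- sort(sample.int(n_s, spec$n_diff))
  vals <- matrix(stats::rbeta(n_s * 2L * n_p, spec$base_alpha,
                              spec$base_beta), nrow = n_s)
  tumor_cols <- seq_len(n_p)
  vals[diff_idx, tumor_cols] <-
    pmin(1, vals[diff_idx, tumor_cols] + spec$delta)
  if (spec$missing_rate > 0)
    vals[stats::runif(length(vals)) < spec$missing_rate] <- NA_real_
  pad <- formatC(seq_len(n_p), width = nchar(n_p), flag = "0")
  colnames(vals) <- c(paste0("tumor_", pad), paste0("normal_", pad))
  em <- editing_matrix(vals, sites,
                       condition = rep(c("tumor", "normal"), each = n_p),
                       pair_id = rep(paste0("p", pad), 2L))
  truth <- data.frame(site_id = sites$site_id,
                      is_diff = seq_len(n_s) %in% diff_idx,
                      true_delta = ifelse(seq_len(n_s) %in% diff_idx,
                                          spec$delta, 0),
                      stringsAsFactors = FALSE)
  list(matrix = em, truth = truth)
}

#' Specification for simulated amplicon sequencing reads
#'
#' Emulates paired gDNA/cDNA amplicon sequencing of one PCR product:
#' reads copied from the reference, with G substituted at edit sites (per
#' read, with probability equal to the site's true editing rate — cDNA
#' template only) followed by uniform substitution sequencing error.
#'
#' @param reference amplicon sequence (character, ACGT).
#' @param rates named numeric vector of true editing rates in [0, 1];
#'   names are 1-based positions which must be A in the reference.
#' @param depth number of reads.
#' @param read_length read length; default the full reference length, so
#'   per-site coverage equals `depth`. Shorter reads are placed uniformly.
#' @param error_rate per-base substitution error probability.
#' @param ref_name reference (amplicon) name used in the SAM.
#' @param seed integer RNG seed.
#' @return list of class `amplicon_sim_spec`.
#' @export
amplicon_sim_spec <- function(reference, rates = numeric(), depth = 100L,
                              read_length = NULL, error_rate = 1e-3,
                              ref_name = "amplicon", seed = 1L) {
  reference <- toupper(reference)
  bases <- strsplit(reference, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("reference must contain only A, C, G, T")
  if (depth < 1) stop("depth must be >= 1")
  pos <- as.integer(names(rates))
  if (length(rates) > 0) {
    if (any(is.na(pos)) || any(pos < 1) || any(pos > length(bases)))
      stop("edit site outside reference bounds")
    if (any(bases[pos] != "A"))
      stop("editing rates may only be assigned at A positions")
    if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  }
  if (is.null(read_length)) read_length <- length(bases)
  if (read_length > length(bases))
    stop("read_length exceeds reference length")
  structure(list(reference = reference, bases = bases, rates = rates,
                 depth = as.integer(depth),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, ref_name = ref_name,
                 seed = as.integer(seed)),
            class = "amplicon_sim_spec")
}

#' Simulate aligned amplicon reads to a SAM file
#'
#' gDNA-templated reads never carry injected editing (G appears at A
#' positions only through sequencing error); cDNA-templated reads carry G
#' at each edit site independently per read with probability equal to the
#' site's true rate. Reads are emitted pre-aligned (ungapped, full-match
#' CIGAR, MAPQ 60, base quality Q40).
#'
#' @param spec an [amplicon_sim_spec()].
#' @param template "cdna" (editing injected) or "gdna" (genotype only).
#' @param sam_path output SAM path.
#' @return list with `sam` (path), `ref_name`, and `truth` (data.frame
#'   pos, true_rate; the injected per-site G fraction — all zero for
#'   gDNA).
#' @export
simulate_amplicon_reads <- function(spec, template = c("cdna", "gdna"),
                                    sam_path = tempfile(fileext = ".sam")) {
  stopifnot(inherits(spec, "amplicon_sim_spec"))
  template <- match.arg(template)
  set.seed(spec$seed + (template == "gdna"))
  L <- length(spec$bases); rl <- spec$read_length
  starts <- if (rl == L) rep(1L, spec$depth)
            else sample.int(L - rl + 1L, spec$depth, replace = TRUE)
  edit_pos <- as.integer(names(spec$rates))
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  recs <- character(spec$depth)
  for (i in seq_len(spec$depth)) {
    s <- starts[i]; e <- s + rl - 1L
    read <- spec$bases[s:e]
    if (template == "cdna" && length(edit_pos) > 0) {
      cov <- edit_pos[edit_pos >= s & edit_pos <= e]
      if (length(cov) > 0) {
        hit <- stats::runif(length(cov)) < spec$rates[as.character(cov)]
        read[cov[hit] - s + 1L] <- "G"
      }
    }
    if (spec$error_rate > 0) {
      err <- which(stats::runif(rl) < spec$error_rate)
      for (j in err) read[j] <- sample(alt[[read[j]]], 1L)
    }
    recs[i] <- paste(sprintf("read%05d", i), 0L, spec$ref_name, s, 60L,
                     paste0(rl, "M"), "*", 0L, 0L,
                     paste(read, collapse = ""),
                     strrep("I", rl), sep = "\t")
  }
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", spec$ref_name, "\tLN:", L))
  writeLines(c(header, recs), sam_path)
  truth_rate <- if (template == "cdna" && length(edit_pos) > 0)
    unname(spec$rates) else rep(0, length(edit_pos))
  list(sam = sam_path, ref_name = spec$ref_name,
       truth = data.frame(pos = edit_pos, true_rate = truth_rate))
}

#' Positions of A bases in an amplicon reference
#'
#' @param reference amplicon sequence (character).
#' @return integer vector of 1-based A positions.
#' @export
a_positions <- function(reference) {
  which(strsplit(toupper(reference), "")[[1]] == "A")
}

#' Deterministic toy gene-model fixture with hand-computed expectations
#'
#' Writes a small GTF of three transcripts — a plus-strand coding gene, a
#' minus-strand coding gene, and a noncoding RNA — covering every feature
#' class including both 1 kb flanks, plus a probe table whose expected
#' labels were worked out by hand from the interval layout (boundary
#' positions included). Regeneration is byte-identical.
#'
#' @param dir output directory.
#' @return list with `gtf` (path), `probes` (data.frame chrom, pos,
#'   expected_labels — comma-collapsed sorted label sets), and
#'   `probes_path` (TSV copy of the table).
#' @export
make_gene_model_fixture <- function(dir = tempdir()) {
  gtf <- file.path(dir, "toy_models.gtf")
  row <- function(chrom, src, type, start, end, strand, gene, tx) {
    sprintf('%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            chrom, src, type, start, end, strand, gene, tx)
  }
  lines <- c(
    # geneA: chr1 plus-strand coding; tx 2000-2899
    row("chr1", "toy", "transcript", 2000L, 2899L, "+", "geneA", "txA1"),
    row("chr1", "toy", "exon", 2000L, 2199L, "+", "geneA", "txA1"),
    row("chr1", "toy", "exon", 2500L, 2899L, "+", "geneA", "txA1"),
    row("chr1", "toy", "five_prime_utr", 2000L, 2099L, "+", "geneA", "txA1"),
    row("chr1", "toy", "CDS", 2100L, 2199L, "+", "geneA", "txA1"),
    row("chr1", "toy", "CDS", 2500L, 2700L, "+", "geneA", "txA1"),
    row("chr1", "toy", "three_prime_utr", 2701L, 2899L, "+", "geneA", "txA1"),
    # geneB: chr1 minus-strand coding; tx 6000-7499 (5' end at 7499)
    row("chr1", "toy", "transcript", 6000L, 7499L, "-", "geneB", "txB1"),
    row("chr1", "toy", "exon", 6000L, 6399L, "-", "geneB", "txB1"),
    row("chr1", "toy", "exon", 7000L, 7499L, "-", "geneB", "txB1"),
    row("chr1", "toy", "five_prime_utr", 7300L, 7499L, "-", "geneB", "txB1"),
    row("chr1", "toy", "CDS", 7000L, 7299L, "-", "geneB", "txB1"),
    row("chr1", "toy", "CDS", 6200L, 6399L, "-", "geneB", "txB1"),
    row("chr1", "toy", "three_prime_utr", 6000L, 6199L, "-", "geneB", "txB1"),
    # geneC: chr2 plus-strand noncoding; tx 3000-3999
    row("chr2", "toy", "transcript", 3000L, 3999L, "+", "geneC", "txC1"),
    row("chr2", "toy", "exon", 3000L, 3299L, "+", "geneC", "txC1"),
    row("chr2", "toy", "exon", 3700L, 3999L, "+", "geneC", "txC1"))
  writeLines(lines, gtf)
  probes <- data.frame(
    chrom = c(rep("chr1", 19), rep("chr2", 3), "chr3"),
    pos = c(2050L, 2150L, 2350L, 2800L, 1500L, 1999L, 2000L, 999L, 1000L,
            2899L, 2900L, 3899L, 3900L, 6100L, 7400L, 6500L, 7600L, 8499L,
            8500L, 3100L, 3500L, 2500L, 100L),
    expected_labels = c(
      "5UTR,exon", "CDS,exon", "intron", "3UTR,exon", "upstream",
      "upstream", "5UTR,exon", "intergenic", "upstream",
      "3UTR,exon", "downstream", "downstream", "intergenic",
      "3UTR,exon", "5UTR,exon", "intron", "upstream", "upstream",
      "intergenic", "exon,ncRNA", "intron,ncRNA", "upstream",
      "intergenic"),
    stringsAsFactors = FALSE)
  probes_path <- file.path(dir, "toy_models_probes.tsv")
  utils::write.table(probes, probes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(gtf = gtf, probes = probes, probes_path = probes_path)
}

#' Simulate a relapse-free survival cohort with a true expression cutoff
#'
#' Expression is bimodal (two Gaussian modes on the log2 TPM scale) so a
#' true stratifying cutoff exists at the mode midpoint; event times are
#' exponential with the high-expression group's hazard multiplied by
#' `hr_true`. Censoring, when drawn, replaces the event time with a
#' uniform draw on (0, t).
#'
#' @param n number of patients.
#' @param hr_true hazard ratio of the high- vs low-expression group.
#' @param censor_rate per-patient censoring probability.
#' @param seed integer RNG seed.
#' @param modes means of the low/high expression modes (log2 TPM).
#' @param mode_sd within-mode standard deviation.
#' @param base_rate baseline hazard (events per month) of the low group.
#' @return list with `records` (data.frame patient_id, expression,
#'   rfs_months, event) and `truth` (true cutoff, group labels, hr_true).
#' @export
simulate_survival_cohort <- function(n, hr_true = 2, censor_rate = 0.2,
                                     seed = 1L, modes = c(4, 8),
                                     mode_sd = 0.5, base_rate = 1 / 60) {
  set.seed(seed)
  if (n == 0) {
    rec <- data.frame(patient_id = character(), expression = numeric(),
                      rfs_months = numeric(), event = integer())
    return(list(records = rec,
                truth = list(cutoff = mean(modes), group = character(),
                             hr_true = hr_true)))
  }
  high <- stats::runif(n) < 0.5
  expression <- stats::rnorm(n, mean = ifelse(high, modes[2], modes[1]),
                             sd = mode_sd)
  t_event <- stats::rexp(n, rate = base_rate * ifelse(high, hr_true, 1))
  censored <- stats::runif(n) < censor_rate
  time <- ifelse(censored, stats::runif(n) * t_event, t_event)
  rec <- data.frame(
    patient_id = sprintf("pt%04d", seq_len(n)),
    expression = expression,
    rfs_months = time,
    event = as.integer(!censored),
    stringsAsFactors = FALSE)
  list(records = rec,
       truth = list(cutoff = mean(modes),
                    group = ifelse(high, "high", "low"),
                    hr_true = hr_true))
}
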