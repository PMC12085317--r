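# SAM files are converted to sorted, indexed BAM once per R session;
# keyed by normalized path + mtime so a rewritten file is re-converted.
.bam_cache <- new.env(parent = emptyenv())

sam_as_bam <- function(path) {
  if (grepl("\\.bam$", path)) return(path)
  key <- paste0(normalizePath(path), "@", file.mtime(path))
  hit <- .bam_cache[[key]]
  if (!is.null(hit) && file.exists(hit)) return(hit)
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  .bam_cache[[key]] <- bam
  bam
}

sam_ref_info <- function(path) {
  h <- Rsamtools::scanBamHeader(sam_as_bam(path))[[1]]$targets
  data.frame(ref = names(h), len = as.integer(h), stringsAsFactors = FALSE)
}

#' Pileup base counts at editing sites
#'
#' Counts aligned read bases covering each site, after mapping- and
#' base-quality filters. Reads whose alignment places a deletion across
#' the site are excluded from the base counts and tallied in
#' `n_del_skipped`; bases failing the quality filter are tallied in
#' `n_low_qual_skipped`, so that
#' depth + n_del_skipped + n_low_qual_skipped equals the number of
#' quality-mapped reads overlapping the position.
#'
#' @param sam path to a SAM (plain text) or BAM file of aligned amplicon
#'   reads.
#' @param sites data.frame of sites ([genomic_sites()]); `chrom` must
#'   name references present in the SAM header.
#' @param min_base_qual minimum base quality (Phred; default 20).
#' @param min_map_qual minimum mapping quality (default 20).
#' @return data.frame of class `pileup_counts`: site columns plus A, C,
#'   G, T, depth, n_del_skipped, n_low_qual_skipped. Uncovered sites get
#'   zero counts.
#' @export
pileup_base_counts <- function(sam, sites, min_base_qual = 20L,
                               min_map_qual = 20L) {
  bam <- sam_as_bam(sam)
  which <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos, sites$pos))
  sbp <- Rsamtools::ScanBamParam(which = which)
  run <- function(minq) {
    pp <- Rsamtools::PileupParam(
      max_depth = 1000000L, min_base_quality = as.integer(minq),
      min_mapq = as.integer(min_map_qual), min_nucleotide_depth = 0L,
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      include_deletions = TRUE, include_insertions = FALSE)
    Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  }
  filt <- run(min_base_qual)
  raw <- run(0L)
  key <- paste(sites$chrom, sites$pos)
  grab <- function(p, nuc) {
    sel <- p[p$nucleotide %in% nuc, , drop = FALSE]
    agg <- tapply(sel$count, paste(sel$seqnames, sel$pos), sum)
    cnt <- as.integer(agg[key])
    cnt[is.na(cnt)] <- 0L
    cnt
  }
  out <- sites
  for (b in c("A", "C", "G", "T")) out[[b]] <- grab(filt, b)
  out$depth <- out$A + out$C + out$G + out$T
  out$n_del_skipped <- grab(raw, "-")
  raw_depth <- grab(raw, c("A", "C", "G", "T"))
  out$n_low_qual_skipped <- raw_depth - out$depth
  class(out) <- c("pileup_counts", "data.frame")
  out
}

#' Editing percentage (G%) from pileup counts
#'
#' G% = 100 * G / (A + C + G + T), the fraction of read bases carrying G
#' at a genomic A position. With `denominator = "ag"` only A and G calls
#' enter the denominator (error bases ignored rather than diluting).
#' Zero-depth sites return NA (flagged low-coverage downstream).
#'
#' @param counts a `pileup_counts` data.frame ([pileup_base_counts()]) or
#'   any data.frame with A, C, G, T columns.
#' @param denominator "total" (default) or "ag".
#' @return numeric vector of percentages in [0, 100], NA at zero depth.
#' @export
editing_percent <- function(counts, denominator = c("total", "ag")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "total")
    counts$A + counts$C + counts$G + counts$T else counts$A + counts$G
  ifelse(den > 0, 100 * counts$G / den, NA_real_)
}

#' Genotype confirmation from gDNA pileup
#'
#' A candidate editing site must be genomically A: the gDNA-templated
#' amplicon must cover it adequately and show essentially no G (a
#' heterozygous A/G DNA variant shows ~50% G and fails).
#'
#' @param gdna a `pileup_counts` data.frame for the gDNA amplicon.
#' @param max_g_percent maximum tolerated gDNA G% (default 1.0).
#' @param min_depth minimum gDNA depth (default 100).
#' @param denominator passed to [editing_percent()].
#' @return logical vector with attribute `reason` ("ok", "low_coverage",
#'   or "gdna_not_A") per site.
#' @export
genotype_check <- function(gdna, max_g_percent = 1.0, min_depth = 100L,
                           denominator = "total") {
  gp <- editing_percent(gdna, denominator)
  low <- gdna$depth < min_depth
  not_a <- !low & gp > max_g_percent
  ok <- !low & !not_a
  attr(ok, "reason") <- ifelse(low, "low_coverage",
                               ifelse(not_a, "gdna_not_A", "ok"))
  ok
}

#' Discover and quantify A-to-I(G) editing from paired amplicons
#'
#' Scans every A position of the amplicon reference in both the gDNA- and
#' cDNA-templated alignments. Each position passing the gDNA genotype
#' check is reported, flagged `predicted` when it was on the a priori
#' candidate list and novel otherwise; a position is called `edited` when
#' its cDNA G% reaches `min_cdna_g_percent`, it is not a known SNP, and
#' coverage thresholds hold. Positions failing checks are still reported
#' with an explanatory status, never dropped.
#'
#' @param gdna_sam,cdna_sam aligned reads (SAM/BAM) from the gDNA- and
#'   cDNA-templated amplicons; both headers must describe the same
#'   reference.
#' @param a_sites data.frame of candidate A positions ([genomic_sites()]),
#'   e.g. every A of the amplicon (`genomic_sites(ref, a_positions(seq))`).
#' @param predicted_sites site_id vector (or sites data.frame) of the a
#'   priori predictions; others are reported as novel.
#' @param snps optional [snp_table()] for SNP exclusion.
#' @param min_cdna_g_percent minimum cDNA G% to call a site edited
#'   (default 5.0).
#' @param min_depth minimum depth in each amplicon (default 100).
#' @param max_gdna_g_percent genotype threshold, see [genotype_check()].
#' @param min_base_qual,min_map_qual quality filters, see
#'   [pileup_base_counts()].
#' @param denominator G% denominator, see [editing_percent()].
#' @return data.frame of class `edit_site_calls`: one row per A position
#'   with gDNA/cDNA counts, `g_percent_gdna`, `g_percent_cdna`,
#'   `genotype_ok`, `snp_flagged`, `predicted`, and `status` in
#'   {edited, not_edited, excluded_snp, excluded_genotype, low_coverage}.
#' @export
discover_and_quantify <- function(gdna_sam, cdna_sam, a_sites,
                                  predicted_sites = character(),
                                  snps = NULL,
                                  min_cdna_g_percent = 5.0,
                                  min_depth = 100L,
                                  max_gdna_g_percent = 1.0,
                                  min_base_qual = 20L, min_map_qual = 20L,
                                  denominator = "total") {
  rg <- sam_ref_info(gdna_sam); rc <- sam_ref_info(cdna_sam)
  if (!identical(rg, rc))
    stop("gDNA and cDNA alignments describe different references")
  if (!all(a_sites$ref_base == "A"))
    stop("all candidate sites must have ref_base A")
  g <- pileup_base_counts(gdna_sam, a_sites, min_base_qual, min_map_qual)
  c_ <- pileup_base_counts(cdna_sam, a_sites, min_base_qual, min_map_qual)
  gp_g <- editing_percent(g, denominator)
  gp_c <- editing_percent(c_, denominator)
  geno <- genotype_check(g, max_gdna_g_percent, min_depth, denominator)
  if (is.character(predicted_sites)) pred_ids <- predicted_sites
  else pred_ids <- predicted_sites$site_id
  snpf <- if (is.null(snps)) rep(FALSE, nrow(a_sites))
          else snp_flag(a_sites, snps)
  low <- g$depth < min_depth | c_$depth < min_depth
  status <- ifelse(low, "low_coverage",
            ifelse(!geno, "excluded_genotype",
            ifelse(snpf, "excluded_snp",
            ifelse(!is.na(gp_c) & gp_c >= min_cdna_g_percent,
                   "edited", "not_edited"))))
  out <- a_sites
  for (b in c("A", "C", "G", "T", "depth")) {
    out[[paste0("gdna_", b)]] <- g[[b]]
    out[[paste0("cdna_", b)]] <- c_[[b]]
  }
  out$g_percent_gdna <- gp_g
  out$g_percent_cdna <- gp_c
  out$genotype_ok <- as.logical(geno)
  out$snp_flagged <- snpf
  out$predicted <- a_sites$site_id %in% pred_ids
  out$status <- status
  class(out) <- c("edit_site_calls", "data.frame")
  out
}

#' Compare editing between two conditions
#'
#' Per-site difference and fold change of cDNA G% between two call sets
#' (e.g. tumor cell line vs normal tissue, or ADAR1 knockdown vs
#' non-targeting control). A zero denominator yields an infinite fold
#' change, flagged in `fold_defined`; the difference is always reported.
#'
#' @param calls_a,calls_b `edit_site_calls` data.frames over the same
#'   sites (a is the numerator condition).
#' @return data.frame: site columns, `g_percent_a`, `g_percent_b`,
#'   `delta` (a - b, percentage points), `fold` (a / b), `fold_defined`.
#' @export
compare_editing <- function(calls_a, calls_b) {
  miss_a <- setdiff(calls_b$site_id, calls_a$site_id)
  miss_b <- setdiff(calls_a$site_id, calls_b$site_id)
  if (length(miss_a) > 0 || length(miss_b) > 0)
    stop("site sets differ; missing from a: ",
         paste(miss_a, collapse = ", "), "; missing from b: ",
         paste(miss_b, collapse = ", "))
  b <- calls_b[match(calls_a$site_id, calls_b$site_id), ]
  out <- calls_a[, c("chrom", "pos", "strand", "ref_base", "site_id")]
  out$g_percent_a <- calls_a$g_percent_cdna
  out$g_percent_b <- b$g_percent_cdna
  out$delta <- out$g_percent_a - out$g_percent_b
  out$fold <- ifelse(out$g_percent_b > 0,
                     out$g_percent_a / out$g_percent_b,
                     ifelse(out$g_percent_a > 0, Inf, NaN))
  out$fold_defined <- is.finite(out$fold)
  out
}
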