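#' Table of known SNP positions
#'
#' Known DNA polymorphisms (e.g. from a dbSNP export) used to exclude
#' genomic variants masquerading as editing sites. Lookup is exact on
#' (chrom, pos); when ref/alt alleles are present, an editing site is only
#' considered matched by a record with ref = A and alt = G (an A-to-G
#' polymorphism is the only DNA change indistinguishable from A-to-I
#' editing in cDNA reads).
#'
#' @param chrom,pos chromosome and 1-based position vectors.
#' @param ref,alt optional allele vectors (NA when unknown).
#' @return data.frame of class `snp_table`.
#' @export
snp_table <- function(chrom = character(), pos = integer(),
                      ref = NA_character_, alt = NA_character_) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = rep_len(as.character(ref), length(chrom)),
                   alt = rep_len(as.character(alt), length(chrom)),
                   stringsAsFactors = FALSE)
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Read known-SNP positions from VCF or BED
#'
#' VCF positions are 1-based and carried through unchanged; BED intervals
#' are 0-based half-open and converted at the boundary (a single-base BED
#' row `chr12 69237003 69237004` becomes position 69237004). The dialect is
#' decided by file extension / `format`, never guessed per row.
#'
#' @param path VCF (`.vcf`) or BED (`.bed`) file.
#' @param format "vcf" or "bed"; inferred from the extension by default.
#' @return a [snp_table()].
#' @export
read_snp_sites <- function(path, format = c("auto", "vcf", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
              else if (grepl("\\.bed(\\.gz)?$", path)) "bed"
              else stop("cannot infer SNP file format from extension: ", path)
  }
  if (format == "vcf") {
    v <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
    fx <- vcfR::getFIX(v)
    if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
    if (nrow(fx) == 0) return(snp_table())
    snp_table(fx[, "CHROM"], as.integer(fx[, "POS"]),
              fx[, "REF"], fx[, "ALT"])
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) GenomicRanges::GRanges())
    if (length(gr) == 0) return(snp_table())
    # rtracklayer already converts to 1-based; expand multi-base intervals
    pos <- unlist(mapply(seq, GenomicRanges::start(gr), GenomicRanges::end(gr),
                         SIMPLIFY = FALSE))
    chrom <- rep(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::width(gr))
    snp_table(chrom, pos)
  }
}

#' Flag sites present in a SNP table
#'
#' @param sites data.frame of sites ([genomic_sites()]).
#' @param snps a [snp_table()].
#' @param allele_aware when TRUE (default) and the table carries alleles,
#'   only ref=A/alt=G records flag a site; allele-free records always flag.
#' @return logical vector, TRUE where the site is a known SNP.
#' @export
snp_flag <- function(sites, snps, allele_aware = TRUE) {
  if (nrow(snps) == 0) return(rep(FALSE, nrow(sites)))
  hit <- snps
  if (allele_aware) {
    compatible <- is.na(hit$ref) | is.na(hit$alt) |
      (hit$ref == "A" & hit$alt == "G")
    hit <- hit[compatible, , drop = FALSE]
  }
  paste(sites$chrom, sites$pos) %in% paste(hit$chrom, hit$pos)
}

#' Write a results table as sorted TSV
#'
#' Rows are written in genomic order (chrom, then pos) with a fixed column
#' order, so output is deterministic and re-readable with
#' [read_results()]. List columns (e.g. multi-label annotations) are
#' collapsed with commas.
#'
#' @param x data.frame carrying `chrom` and `pos` columns (differential
#'   results, edit-site calls, annotations).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_results <- function(x, path) {
  x <- as.data.frame(x)
  if (all(c("chrom", "pos") %in% names(x)) && nrow(x) > 0)
    x <- x[genomic_order(x$chrom, x$pos), , drop = FALSE]
  for (j in seq_along(x))
    if (is.list(x[[j]]))
      x[[j]] <- vapply(x[[j]], paste, "", collapse = ",")
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.delim(path, check.names = FALSE, na.strings = "",
                    stringsAsFactors = FALSE)
}

#' Read a survival cohort TSV
#'
#' Expected columns: `patient_id`, `expression` (continuous, log2 TPM
#' scale), `rfs_months` (relapse-free survival, non-negative), `event`
#' (1 = relapse, 0 = censored); optional `subtype`.
#'
#' @param path TSV path.
#' @return data.frame of patient records.
#' @export
read_survival_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "expression", "rfs_months", "event")
  if (!all(need %in% names(df)))
    stop("survival TSV must have columns: ", paste(need, collapse = ", "))
  if (any(is.na(df$rfs_months)) || any(df$rfs_months < 0))
    stop("rfs_months must be non-negative")
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (relapse)")
  df
}

#' Pipeline configuration
#'
#' All thresholds live in one YAML file; any value omitted falls back to
#' the defaults below, which are also the defaults of the corresponding
#' functions.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(min_pairs = 5L, fdr_q = 0.05, min_delta = 0.05,
       direction = "both", flank_len = 1000L,
       min_depth = 100L, max_gdna_g_percent = 1.0,
       min_cdna_g_percent = 5.0, min_base_qual = 20L, min_map_qual = 20L,
       denominator = "total",
       rfs_min_months = 0, rfs_max_months = 120,
       quantile_range = c(0.1, 0.9), genome = "hg19", seed = 1L)
}

#' @rdname default_config
#' @param path YAML config file.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0)
      warning("unknown config keys ignored: ", paste(unknown, collapse = ", "))
    cfg[intersect(names(user), names(cfg))] <-
      user[intersect(names(user), names(cfg))]
  }
  cfg
}
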