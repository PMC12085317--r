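#' Transcript gene models with derived introns and flanks
#'
#' A gene model holds per-feature intervals (5'UTR, CDS, 3'UTR, exon,
#' intron) for one transcript plus the two derived flanking regions:
#' upstream and downstream are the `flank_len` bases (default 1 kb)
#' 5'-ward of the transcription start and 3'-ward of the transcription
#' end, assigned strand-aware in genome coordinates. Transcripts without
#' any CDS are flagged noncoding (annotated as ncRNA).
#'
#' @param gene_id,tx_id gene / transcript identifiers.
#' @param chrom chromosome name.
#' @param strand "+", "-", or "*" (unknown; flanks then undefined).
#' @param exons data.frame with `start`, `end` (1-based inclusive).
#' @param cds optional CDS intervals, same shape.
#' @param utr5,utr3 optional UTR intervals, same shape.
#' @param tx_start,tx_end transcription boundaries; default the exon span.
#' @param flank_len flank width in bp (default 1000).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, tx_id, chrom, strand, exons,
                       cds = NULL, utr5 = NULL, utr3 = NULL,
                       tx_start = min(exons$start), tx_end = max(exons$end),
                       flank_len = 1000L) {
  stopifnot(nrow(exons) >= 1)
  if (!strand %in% c("+", "-", "*")) stop("strand must be '+', '-' or '*'")
  check_iv <- function(iv, what) {
    if (is.null(iv) || nrow(iv) == 0) return(empty_iv())
    if (any(iv$end < iv$start)) stop(what, " interval with end < start")
    if (any(iv$start < tx_start) || any(iv$end > tx_end))
      stop(what, " intervals out of transcript bounds [", tx_start, ", ",
           tx_end, "] for ", tx_id)
    iv[order(iv$start), c("start", "end"), drop = FALSE]
  }
  exons <- check_iv(exons, "exon")
  cds <- check_iv(cds, "CDS")
  utr5 <- check_iv(utr5, "5'UTR")
  utr3 <- check_iv(utr3, "3'UTR")
  introns <- interval_gaps(exons, tx_start, tx_end)
  feats <- rbind(
    cbind(feature = rep("exon", nrow(exons)), exons),
    cbind(feature = rep("CDS", nrow(cds)), cds),
    cbind(feature = rep("5UTR", nrow(utr5)), utr5),
    cbind(feature = rep("3UTR", nrow(utr3)), utr3),
    cbind(feature = rep("intron", nrow(introns)), introns))
  flanks <- derive_flanks(tx_start, tx_end, strand, flank_len)
  if (!is.null(flanks) &&
      any(flanks$end >= tx_start & flanks$start <= tx_end))
    stop("internal error: flank overlaps transcript body for ", tx_id)
  structure(list(gene_id = gene_id, tx_id = tx_id, chrom = chrom,
                 strand = strand, tx_start = tx_start, tx_end = tx_end,
                 features = feats, flanks = flanks,
                 coding = nrow(cds) > 0, flank_len = flank_len),
            class = "gene_model")
}

empty_iv <- function() data.frame(start = integer(), end = integer())

# gaps between sorted disjoint intervals, within [lo, hi]
interval_gaps <- function(iv, lo, hi) {
  if (nrow(iv) < 2) return(empty_iv())
  iv <- iv[order(iv$start), ]
  gs <- iv$end[-nrow(iv)] + 1L
  ge <- iv$start[-1L] - 1L
  keep <- ge >= gs
  data.frame(start = gs[keep], end = ge[keep])
}

derive_flanks <- function(tx_start, tx_end, strand, flank_len) {
  if (strand == "*") return(NULL)
  left <- data.frame(start = max(1L, tx_start - flank_len),
                     end = tx_start - 1L)
  right <- data.frame(start = tx_end + 1L, end = tx_end + flank_len)
  if (left$end < left$start) left <- NULL
  up <- if (strand == "+") left else right
  dn <- if (strand == "+") right else left
  out <- rbind(if (!is.null(up)) cbind(feature = "upstream", up),
               if (!is.null(dn)) cbind(feature = "downstream", dn))
  out
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%d-%d [%s]%s\n", x$tx_id, x$gene_id,
              x$chrom, x$tx_start, x$tx_end, x$strand,
              if (x$coding) "" else " noncoding"))
  print(table(x$features$feature))
  invisible(x)
}

#' Read gene models from GTF or BED12
#'
#' GTF is parsed feature-rows-as-given (exon / CDS / five_prime_utr /
#' three_prime_utr, Ensembl naming; `5UTR`/`3UTR` accepted as synonyms);
#' introns are derived as exon gaps. For BED12, exons come from the block
#' structure, the CDS from the thick region, and UTRs from the exonic
#' sequence outside it (strand decides which side is 5'); a zero-width
#' thick region (`thickStart == thickEnd`) marks the whole transcript
#' noncoding. Flanks of `flank_len` bp are derived from the transcription
#' boundaries and strand; transcripts with unknown strand load with flanks
#' undefined.
#'
#' @param path GTF (`.gtf`) or BED12 (`.bed`) file.
#' @param flank_len flank width in bp.
#' @param format "gtf" or "bed12"; inferred from the extension by default.
#' @return list of [gene_model()] objects, named by transcript id.
#' @export
read_gene_models <- function(path, flank_len = 1000L,
                             format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed12" else "gtf"
  if (format == "gtf") read_models_gtf(path, flank_len)
  else read_models_bed12(path, flank_len)
}

read_models_gtf <- function(path, flank_len) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- tolower(as.character(md$type))
  tx <- as.character(md$transcript_id)
  gene <- as.character(md$gene_id)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = type, tx = tx, gene = gene,
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$tx), ]
  models <- lapply(split(df, df$tx), function(d) {
    pick <- function(t) d[d$type %in% t, c("start", "end"), drop = FALSE]
    exons <- pick("exon")
    if (nrow(exons) == 0) stop("transcript ", d$tx[1], " has no exon rows")
    txrow <- d[d$type == "transcript", , drop = FALSE]
    tx_start <- if (nrow(txrow)) txrow$start[1] else min(exons$start)
    tx_end <- if (nrow(txrow)) txrow$end[1] else max(exons$end)
    gene_model(gene_id = d$gene[1], tx_id = d$tx[1], chrom = d$chrom[1],
               strand = d$strand[1], exons = exons, cds = pick("cds"),
               utr5 = pick(c("five_prime_utr", "5utr")),
               utr3 = pick(c("three_prime_utr", "3utr")),
               tx_start = tx_start, tx_end = tx_end, flank_len = flank_len)
  })
  models[order(names(models))]
}

read_models_bed12 <- function(path, flank_len) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$blocks))
    stop("BED file lacks block structure; BED12 required for gene models")
  models <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    tx_start <- GenomicRanges::start(gr)[i]
    tx_end <- GenomicRanges::end(gr)[i]
    blk <- gr$blocks[[i]]  # block ranges relative to the feature, 1-based
    exons <- data.frame(start = tx_start + GenomicRanges::start(blk) - 1L,
                        end = tx_start + GenomicRanges::end(blk) - 1L)
    thick <- gr$thick[i]
    strand <- as.character(GenomicRanges::strand(gr))[i]
    coding <- GenomicRanges::width(thick) > 0 &&
      !(GenomicRanges::start(thick) > GenomicRanges::end(thick))
    cds <- utr5 <- utr3 <- NULL
    if (coding) {
      ts <- GenomicRanges::start(thick); te <- GenomicRanges::end(thick)
      cds <- intersect_iv(exons, ts, te)
      left <- intersect_iv(exons, tx_start, ts - 1L)
      right <- intersect_iv(exons, te + 1L, tx_end)
      if (strand == "-") { utr5 <- right; utr3 <- left }
      else { utr5 <- left; utr3 <- right }
    }
    nm <- if (!is.null(gr$name) && !is.na(gr$name[i])) gr$name[i]
          else paste0("tx", i)
    models[[i]] <- gene_model(
      gene_id = nm, tx_id = nm,
      chrom = as.character(GenomeInfoDb::seqnames(gr))[i],
      strand = strand, exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
      tx_start = tx_start, tx_end = tx_end, flank_len = flank_len)
  }
  names(models) <- vapply(models, `[[`, "", "tx_id")
  models[order(names(models))]
}

# clip intervals to [lo, hi], dropping empties
intersect_iv <- function(iv, lo, hi) {
  if (hi < lo) return(empty_iv())
  s <- pmax(iv$start, lo); e <- pmin(iv$end, hi)
  keep <- e >= s
  data.frame(start = s[keep], end = e[keep])
}

#' Flatten gene models to a labeled interval table
#'
#' One row per (feature label, interval, transcript): the body features,
#' the derived flanks, and for noncoding transcripts an `ncRNA` interval
#' spanning the transcript body. This is the table the annotator overlaps
#' sites against.
#'
#' @param models list of [gene_model()] objects.
#' @return data.frame with columns chrom, start, end, strand, feature,
#'   gene_id, tx_id.
#' @export
feature_table <- function(models) {
  rows <- lapply(models, function(m) {
    ft <- m$features
    if (!is.null(m$flanks)) ft <- rbind(ft, m$flanks)
    if (!m$coding)
      ft <- rbind(ft, data.frame(feature = "ncRNA", start = m$tx_start,
                                 end = m$tx_end))
    data.frame(chrom = m$chrom, start = ft$start, end = ft$end,
               strand = m$strand, feature = ft$feature,
               gene_id = m$gene_id, tx_id = m$tx_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(chrom = character(), start = integer(),
                                      end = integer(), strand = character(),
                                      feature = character(),
                                      gene_id = character(),
                                      tx_id = character())
  out
}
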