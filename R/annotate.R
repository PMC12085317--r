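FEATURE_CLASSES <- c("3UTR", "5UTR", "CDS", "exon", "intron", "ncRNA",
                     "upstream", "downstream", "intergenic")
PRIMARY_PRECEDENCE <- c("3UTR", "5UTR", "CDS", "intron", "ncRNA",
                        "upstream", "downstream")

#' Annotate editing sites with genomic feature classes
#'
#' Each site (a single base) is intersected with every feature interval of
#' every transcript and receives ALL overlapping labels (multi-label: a
#' site in a 3'UTR is both `3UTR` and `exon`; a site in a noncoding
#' transcript carries `ncRNA` alongside its exon/intron label). Flank
#' labels (`upstream`, `downstream`) are strand-aware and only reach
#' `flank_len` bp from the transcription boundaries. A site overlapping
#' nothing — including sites on chromosomes absent from the models, which
#' raise a warning — is labeled `intergenic`, exclusively.
#'
#' @param sites data.frame of sites ([genomic_sites()]).
#' @param models list of [gene_model()] objects.
#' @return data.frame of class `site_annotation`: site columns plus list
#'   columns `labels` (feature classes) and `gene_ids`, and a
#'   `primary_label` column applying the precedence
#'   3UTR > 5UTR > CDS > intron > ncRNA > upstream > downstream
#'   (intergenic when nothing overlaps).
#' @export
annotate_sites <- function(sites, models) {
  ft <- feature_table(models)
  labels <- rep(list(character()), nrow(sites))
  genes <- rep(list(character()), nrow(sites))
  if (nrow(ft) > 0 && nrow(sites) > 0) {
    missing_chrom <- !(sites$chrom %in% ft$chrom)
    if (any(missing_chrom))
      warning(sum(missing_chrom), " site(s) on chromosomes absent from the ",
              "gene models; labeled intergenic")
    lvls <- union(unique(sites$chrom), unique(ft$chrom))
    s_gr <- GenomicRanges::GRanges(
      factor(sites$chrom, lvls), IRanges::IRanges(sites$pos, sites$pos))
    f_gr <- GenomicRanges::GRanges(
      factor(ft$chrom, lvls), IRanges::IRanges(ft$start, ft$end))
    hits <- GenomicRanges::findOverlaps(s_gr, f_gr, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (i in unique(qh)) {
      rows <- sh[qh == i]
      labels[[i]] <- sort(unique(ft$feature[rows]))
      genes[[i]] <- sort(unique(ft$gene_id[rows]))
    }
  }
  none <- lengths(labels) == 0
  labels[none] <- list("intergenic")
  out <- sites
  out$labels <- labels
  out$gene_ids <- genes
  out$primary_label <- vapply(labels, function(l) {
    hit <- PRIMARY_PRECEDENCE[PRIMARY_PRECEDENCE %in% l]
    if (length(hit)) hit[1]
    else if ("exon" %in% l) "exon" else "intergenic"
  }, "")
  class(out) <- c("site_annotation", "data.frame")
  out
}

#' @rdname annotate_sites
#' @param site a single-row site data.frame (or chrom/pos via
#'   [genomic_sites()]).
#' @export
annotate_site <- function(site, models) annotate_sites(site, models)

#' Per-gene feature co-occurrence sets
#'
#' For every gene with at least one annotated site, collects the set of
#' feature classes that contain an edited site, and tallies genes per
#' exact feature-set combination — the data behind an UpSet plot of which
#' transcript regions are edited together on single mRNAs. The structural
#' `exon` label is dropped by default (it is implied by 3UTR/5UTR/CDS and
#' would fold every UTR combination into a UTR+exon one); intergenic
#' sites carry no gene and never contribute.
#'
#' @param annotations a `site_annotation` data.frame ([annotate_sites()]).
#' @param drop labels excluded from the sets (default "exon").
#' @return list with `gene_sets` (data.frame gene_id, features) and
#'   `combinations` (data.frame combination, count; count descending,
#'   lexicographic tie-break).
#' @export
cooccurrence_sets <- function(annotations, drop = "exon") {
  pairs <- do.call(rbind, lapply(seq_len(nrow(annotations)), function(i) {
    g <- annotations$gene_ids[[i]]
    l <- setdiff(annotations$labels[[i]], c(drop, "intergenic"))
    if (length(g) == 0 || length(l) == 0) return(NULL)
    expand.grid(gene_id = g, feature = l, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs) || nrow(pairs) == 0)
    return(list(gene_sets = data.frame(gene_id = character(),
                                       features = character()),
                combinations = data.frame(combination = character(),
                                          count = integer())))
  sets <- vapply(split(pairs$feature, pairs$gene_id),
                 function(f) paste(sort(unique(f)), collapse = "+"), "")
  gene_sets <- data.frame(gene_id = names(sets), features = unname(sets),
                          stringsAsFactors = FALSE)
  gene_sets <- gene_sets[order(gene_sets$gene_id), , drop = FALSE]
  tab <- table(gene_sets$features)
  comb <- data.frame(combination = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  comb <- comb[order(-comb$count, comb$combination), , drop = FALSE]
  rownames(comb) <- rownames(gene_sets) <- NULL
  list(gene_sets = gene_sets, combinations = comb)
}
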