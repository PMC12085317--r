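#' Construct a table of genomic sites
#'
#' A site is a single genomic base: the unit at which A-to-I editing is
#' measured. Sites are kept as a plain data frame with one row per site so
#' they compose naturally with the matrix and annotation machinery.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based genomic coordinates.
#' @param strand one of "+", "-", "*" per site; "*" means unknown.
#' @param ref_base reference base at the site; must be one of A, C, G, T.
#'   Sites submitted to editing quantification must be "A".
#' @param site_id optional site identifier; defaults to "chrom:pos".
#' @return data.frame with columns chrom, pos, strand, ref_base, site_id.
#' @examples
#' genomic_sites("chr12", 69237004, "+", "A")
#' @export
genomic_sites <- function(chrom, pos, strand = "*", ref_base = "A",
                          site_id = NULL) {
  n <- length(chrom)
  pos <- as.integer(pos)
  strand <- rep_len(strand, n)
  ref_base <- rep_len(ref_base, n)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("site positions must be 1-based integers >= 1")
  if (!all(strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  if (!all(ref_base %in% c("A", "C", "G", "T")))
    stop("ref_base must be one of A, C, G, T")
  if (is.null(site_id)) site_id <- format_site_id(chrom, pos)
  df <- data.frame(chrom = as.character(chrom), pos = pos, strand = strand,
                   ref_base = ref_base, site_id = as.character(site_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$site_id))
    stop("duplicate site_id: ", paste(unique(df$site_id[duplicated(df$site_id)]),
                                      collapse = ", "))
  df
}

#' Format and parse "chrom:pos" site identifiers
#'
#' Identifiers use 1-based coordinates, e.g. "chr12:69237004", and
#' round-trip exactly through [parse_site_id()].
#'
#' @param chrom,pos chromosome and 1-based position vectors.
#' @return `format_site_id`: character vector of ids.
#' @export
format_site_id <- function(chrom, pos) paste0(chrom, ":", as.integer(pos))

#' @rdname format_site_id
#' @param id character vector of "chrom:pos" identifiers.
#' @return `parse_site_id`: data.frame with columns chrom and pos.
#' @export
parse_site_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)$", id))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed site id: ", paste(utils::head(id[bad], 5), collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2L),
             pos = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' Convert between BED (0-based half-open) and 1-based coordinates
#'
#' Internal coordinates are 1-based inclusive; BED input/output converts at
#' the boundary. For a single-base BED interval the 1-based position equals
#' the BED end (= start + 1).
#'
#' @param start0,end0 BED chromStart/chromEnd.
#' @return `bed_to_pos1`: integer vector of 1-based positions of the bases
#'   covered (for width-1 intervals, a single position per row).
#' @export
bed_to_pos1 <- function(start0, end0) {
  if (any(end0 <= start0)) stop("BED interval with end <= start")
  as.integer(start0) + 1L
}

#' @rdname bed_to_pos1
#' @param pos1 1-based position.
#' @return `pos1_to_bed`: data.frame with 0-based start and half-open end.
#' @export
pos1_to_bed <- function(pos1) {
  data.frame(start = as.integer(pos1) - 1L, end = as.integer(pos1))
}

# Stable genomic row order: chromosome name (natural string order), then pos.
genomic_order <- function(chrom, pos) order(chrom, pos, method = "radix")

sites_as_granges <- function(sites) {
  GenomicRanges::GRanges(sites$chrom,
                         IRanges::IRanges(sites$pos, sites$pos),
                         strand = sites$strand)
}
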