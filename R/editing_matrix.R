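#' Editing-level matrix for a paired tumor/normal cohort
#'
#' The substrate of the differential screen: per-site editing levels
#' (proportions in [0, 1], missing allowed) across samples, together with
#' per-sample condition and optional tumor/normal pairing.
#'
#' @param values numeric matrix, sites x samples, entries in [0, 1] or NA.
#' @param sites data.frame of sites as returned by [genomic_sites()]; row
#'   count must equal `nrow(values)`.
#' @param condition character vector, one of "tumor"/"normal" per sample.
#' @param pair_id optional pairing key per sample; each pair_id may contain
#'   at most one tumor and one normal sample. NA means unpaired.
#' @return an object of class `editing_matrix`.
#' @export
editing_matrix <- function(values, sites, condition, pair_id = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != nrow(sites))
    stop("values has ", nrow(values), " rows but sites has ", nrow(sites))
  if (is.null(colnames(values)))
    stop("values must carry sample ids as column names")
  if (length(condition) != ncol(values))
    stop("condition length must equal the number of samples")
  if (!all(condition %in% c("tumor", "normal")))
    stop("condition must be 'tumor' or 'normal'")
  if (is.null(pair_id)) pair_id <- rep(NA_character_, ncol(values))
  pair_id <- as.character(pair_id)
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("editing level outside [0,1] at site ", sites$site_id[bad[1, 1]],
         ", sample ", colnames(values)[bad[1, 2]])
  for (p in unique(stats::na.omit(pair_id))) {
    cond <- condition[which(pair_id == p)]
    if (sum(cond == "tumor") > 1 || sum(cond == "normal") > 1)
      stop("pair_id '", p, "' maps to more than one ",
           if (sum(cond == "tumor") > 1) "tumor" else "normal", " sample")
  }
  rownames(values) <- sites$site_id
  structure(list(values = values, sites = sites,
                 samples = colnames(values),
                 condition = condition, pair_id = pair_id),
            class = "editing_matrix")
}

#' @export
dim.editing_matrix <- function(x) dim(x$values)

#' @export
print.editing_matrix <- function(x, ...) {
  np <- n_complete_pairs(x)
  cat("editing_matrix:", nrow(x$values), "sites x", ncol(x$values),
      "samples (", sum(x$condition == "tumor"), "tumor /",
      sum(x$condition == "normal"), "normal;", np, "matched pairs )\n")
  cat("missing cells:", sum(is.na(x$values)), "of", length(x$values), "\n")
  invisible(x)
}

# ids of pair keys having both a tumor and a normal sample
complete_pair_ids <- function(x) {
  keys <- unique(stats::na.omit(x$pair_id))
  keys[vapply(keys, function(p) {
    cond <- x$condition[which(x$pair_id == p)]
    any(cond == "tumor") && any(cond == "normal")
  }, TRUE)]
}

n_complete_pairs <- function(x) length(complete_pair_ids(x))

# sites x pairs logical: both members of the pair observed at the site
pair_observed_matrix <- function(x) {
  keys <- complete_pair_ids(x)
  if (length(keys) == 0)
    return(matrix(FALSE, nrow(x$values), 0))
  ti <- vapply(keys, function(p)
    which(x$pair_id == p & x$condition == "tumor"), 1L)
  ni <- vapply(keys, function(p)
    which(x$pair_id == p & x$condition == "normal"), 1L)
  ok <- !is.na(x$values[, ti, drop = FALSE]) &
        !is.na(x$values[, ni, drop = FALSE])
  colnames(ok) <- keys
  ok
}

#' Subset an editing matrix by site
#'
#' @param x an `editing_matrix`.
#' @param i site index (logical, integer or site_id character).
#' @return an `editing_matrix` with the selected sites; samples unchanged.
#' @export
subset_sites <- function(x, i) {
  if (is.character(i)) i <- match(i, x$sites$site_id)
  editing_matrix(x$values[i, , drop = FALSE],
                 x$sites[i, , drop = FALSE],
                 x$condition, x$pair_id)
}

#' Read / write an editing matrix as TSV plus sample metadata
#'
#' The matrix TSV has one row per site (first column `site_id`, in
#' "chrom:pos" form) and one column per sample; empty cells are missing
#' values. Sample condition and pairing travel in a sidecar metadata TSV
#' with columns `sample_id`, `condition`, `pair_id` (empty pair_id means
#' unpaired).
#'
#' @param path matrix TSV path.
#' @param meta_path metadata TSV path; defaults to `path` with a
#'   `.meta.tsv` suffix replacing `.tsv`.
#' @return [read_editing_matrix()]: an `editing_matrix`.
#' @export
read_editing_matrix <- function(path, meta_path = default_meta_path(path)) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                          colClasses = "character")
  if (ncol(df) < 2) stop("matrix TSV needs a site_id column plus samples")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate site id in ", path, ": ",
         ids[duplicated(ids)][1])
  coords <- tryCatch(parse_site_id(ids), error = function(e)
    stop("malformed coordinate in ", path, ": ", conditionMessage(e)))
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  nonnum <- is.na(vals) & !(is.na(df[, -1, drop = FALSE]) |
                            df[, -1, drop = FALSE] == "")
  if (any(nonnum)) {
    w <- which(nonnum, arr.ind = TRUE)[1, ]
    stop("non-numeric editing value at row ", w[1], " (", ids[w[1]], ")")
  }
  meta <- utils::read.delim(meta_path, colClasses = "character",
                            na.strings = "")
  need <- c("sample_id", "condition", "pair_id")
  if (!all(need %in% names(meta)))
    stop("metadata TSV must have columns: ", paste(need, collapse = ", "))
  miss <- setdiff(colnames(vals), meta$sample_id)
  if (length(miss) > 0)
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  meta <- meta[match(colnames(vals), meta$sample_id), ]
  sites <- genomic_sites(coords$chrom, coords$pos, site_id = ids)
  editing_matrix(vals, sites, meta$condition, meta$pair_id)
}

#' @rdname read_editing_matrix
#' @param x an `editing_matrix` to write.
#' @export
write_editing_matrix <- function(x, path,
                                 meta_path = default_meta_path(path)) {
  out <- data.frame(site_id = x$sites$site_id, x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  meta <- data.frame(sample_id = x$samples, condition = x$condition,
                     pair_id = x$pair_id, stringsAsFactors = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(matrix = path, meta = meta_path))
}

default_meta_path <- function(path) {
  sub("\\.tsv$", "", path) |> paste0(".meta.tsv")
}
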