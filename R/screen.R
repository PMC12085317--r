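#' Informative-site filter
#'
#' A site is informative when it is observed (non-missing) in both members
#' of at least `min_pairs` matched tumor/normal pairs. Only such sites
#' enter the differential screen; the sample set is unchanged.
#'
#' @param x an [editing_matrix()] with pairing metadata.
#' @param min_pairs minimum number of complete observed pairs (default 5).
#' @return an `editing_matrix` restricted to informative sites.
#' @export
informative_filter <- function(x, min_pairs = 5L) {
  stopifnot(inherits(x, "editing_matrix"))
  if (n_complete_pairs(x) == 0)
    stop("no tumor/normal pairing metadata: cannot apply informative filter")
  np <- rowSums(pair_observed_matrix(x))
  subset_sites(x, np >= min_pairs)
}

#' Two-sided Wilcoxon rank-sum test for one site
#'
#' Compares tumor against normal editing levels (unpaired). The exact
#' null distribution is enumerated when both groups have at most 8 values
#' and there are no ties; otherwise the normal approximation with midrank
#' tie correction and continuity correction is used. Two identical
#' constant groups carry no rank information and return p = 1.
#'
#' @param tumor_values,normal_values numeric vectors (NAs dropped).
#' @return list with `statistic` (rank-sum W, tumor relative to normal)
#'   and `p_value`; both NA when either group is empty (untestable).
#' @export
rank_sum_test <- function(tumor_values, normal_values) {
  x <- tumor_values[!is.na(tumor_values)]
  y <- normal_values[!is.na(normal_values)]
  if (length(x) == 0 || length(y) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_))
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = min(1, wt$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up: with p-values sorted ascending,
#' q_(i) = min_{j >= i} p_(j) * m / j, capped at 1, returned in the
#' original order. Missing p-values (untestable sites) are excluded from
#' m and stay missing.
#'
#' @param p numeric vector of p-values in [0, 1], NA allowed.
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Differential-editing screen across a cohort
#'
#' The full screen: optional informative-site filtering, a per-site
#' two-sided Wilcoxon rank-sum test of all tumor against all normal
#' values, BH false-discovery adjustment over the testable sites, and an
#' effect-size call. A site is significant when q < `fdr_q` and its mean
#' tumor-normal editing difference reaches `min_delta` (absolute value in
#' "both" mode; positive only in "up_only" mode, for screens focused on
#' tumor-gained editing).
#'
#' @param x an [editing_matrix()].
#' @param fdr_q FDR threshold (default 0.05).
#' @param min_delta minimum mean editing difference, proportion units
#'   (default 0.05, i.e. 5%).
#' @param direction "both" (|delta| >= min_delta) or "up_only"
#'   (delta >= min_delta).
#' @param min_pairs when non-NULL, [informative_filter()] is applied
#'   first with this threshold.
#' @return object of class `editing_screen`: list with `results` (a
#'   data.frame of class `differential_result`, one row per site, in
#'   genomic order) and `params`. Untestable sites (an empty group, after
#'   missing-value removal) are kept with `testable = FALSE` and missing
#'   p/q; all-equal sites are flagged `zero_variance`.
#' @export
call_differential <- function(x, fdr_q = 0.05, min_delta = 0.05,
                              direction = c("both", "up_only"),
                              min_pairs = NULL) {
  stopifnot(inherits(x, "editing_matrix"))
  direction <- match.arg(direction)
  if (!is.null(min_pairs)) x <- informative_filter(x, min_pairs)
  ti <- x$condition == "tumor"; ni <- x$condition == "normal"
  pairs_obs <- if (n_complete_pairs(x) > 0)
    rowSums(pair_observed_matrix(x)) else rep(NA_integer_, nrow(x$values))
  res <- lapply(seq_len(nrow(x$values)), function(i) {
    tv <- x$values[i, ti]; nv <- x$values[i, ni]
    wt <- rank_sum_test(tv, nv)
    tv <- tv[!is.na(tv)]; nv <- nv[!is.na(nv)]
    data.frame(
      n_tumor = length(tv), n_normal = length(nv),
      mean_tumor = if (length(tv)) mean(tv) else NA_real_,
      mean_normal = if (length(nv)) mean(nv) else NA_real_,
      statistic = wt$statistic, p_value = wt$p_value,
      zero_variance = length(tv) > 0 && length(nv) > 0 &&
        length(unique(c(tv, nv))) == 1L)
  })
  res <- do.call(rbind, res)
  out <- cbind(x$sites, res)
  out$n_pairs_observed <- pairs_obs
  out$delta <- out$mean_tumor - out$mean_normal
  out$testable <- !is.na(out$p_value)
  out$q_value <- bh_adjust(out$p_value)
  pass_delta <- if (direction == "both") abs(out$delta) >= min_delta
                else out$delta >= min_delta
  out$significant <- out$testable & out$q_value < fdr_q & pass_delta
  out$direction <- ifelse(is.na(out$delta), NA_character_,
                          ifelse(out$delta >= 0, "up", "down"))
  out <- out[genomic_order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  structure(list(results = out,
                 params = list(fdr_q = fdr_q, min_delta = min_delta,
                               direction = direction,
                               min_pairs = min_pairs),
                 n_sites = nrow(out),
                 n_samples = length(x$samples)),
            class = "editing_screen")
}

#' @export
print.editing_screen <- function(x, ...) {
  cat("Differential editing screen:", x$n_sites, "sites,",
      x$n_samples, "samples\n")
  cat(sprintf("  thresholds: q < %g, %s >= %g\n", x$params$fdr_q,
              if (x$params$direction == "both") "|delta|" else "delta",
              x$params$min_delta))
  cat("  testable:", sum(x$results$testable),
      " significant:", sum(x$results$significant, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
summary.editing_screen <- function(object, ...) {
  r <- object$results
  sig <- r[which(r$significant), , drop = FALSE]
  out <- list(n_sites = nrow(r), n_testable = sum(r$testable),
              n_significant = nrow(sig),
              n_up = sum(sig$direction == "up"),
              n_down = sum(sig$direction == "down"),
              median_delta_significant = stats::median(sig$delta),
              params = object$params)
  class(out) <- "summary.editing_screen"
  out
}

#' @export
print.summary.editing_screen <- function(x, ...) {
  cat("sites:", x$n_sites, " testable:", x$n_testable,
      " significant:", x$n_significant,
      sprintf("(%d up / %d down)\n", x$n_up, x$n_down))
  if (x$n_significant > 0)
    cat("median delta among significant:",
        signif(x$median_delta_significant, 3), "\n")
  invisible(x)
}

#' @export
as.data.frame.editing_screen <- function(x, ...) as.data.frame(x$results)

#' Count significant sites per genomic feature class
#'
#' Multi-label: a significant site contributes to every feature class it
#' maps to; a significant site with no annotation is counted under
#' "unannotated" with a warning.
#'
#' @param screen an `editing_screen` (or `differential_result`
#'   data.frame).
#' @param annotations a `site_annotation` data.frame ([annotate_sites()]),
#'   keyed by site_id.
#' @return data.frame (feature, n_sites), count descending, with
#'   attributes `n_significant` (unique significant sites) and `total`
#'   (sum of per-class counts).
#' @export
feature_summary <- function(screen, annotations) {
  r <- if (inherits(screen, "editing_screen")) screen$results else screen
  sig <- r[which(r$significant), , drop = FALSE]
  idx <- match(sig$site_id, annotations$site_id)
  labs <- vector("list", nrow(sig))
  for (i in seq_along(labs)) {
    l <- if (is.na(idx[i])) character() else annotations$labels[[idx[i]]]
    labs[[i]] <- if (length(l) == 0) "unannotated" else l
  }
  n_unann <- sum(vapply(labs, function(l) "unannotated" %in% l, TRUE))
  if (n_unann > 0)
    warning(n_unann, " significant site(s) without annotation; counted as ",
            "'unannotated'")
  tab <- table(unlist(labs))
  out <- data.frame(feature = names(tab), n_sites = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_sites, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_significant") <- nrow(sig)
  attr(out, "total") <- sum(out$n_sites)
  out
}
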