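#' Dual-luciferase normalization
#'
#' Per replicate, the Firefly reading is divided by the co-transfected
#' Renilla reading (transfection-efficiency control); each ratio is then
#' divided by the mean ratio of the reference condition (e.g. the empty
#' vector, "EV"), so the reference normalizes to 1 and a value of 1.6
#' reads as a 60% activity increase.
#'
#' @param measurements data.frame with columns `condition`, `replicate`,
#'   `firefly`, `renilla`.
#' @param reference_label condition used as the normalizer.
#' @return the input with `ratio` and `normalized` columns added.
#' @export
luciferase_normalize <- function(measurements, reference_label = "EV") {
  need <- c("condition", "replicate", "firefly", "renilla")
  if (!all(need %in% names(measurements)))
    stop("measurements must have columns: ", paste(need, collapse = ", "))
  dup <- duplicated(measurements[c("condition", "replicate")])
  if (any(dup))
    stop("duplicate replicate id within condition: ",
         measurements$condition[dup][1], "/", measurements$replicate[dup][1])
  bad <- which(!(measurements$renilla > 0))
  if (length(bad) > 0)
    stop("non-positive Renilla reading for condition ",
         measurements$condition[bad[1]], ", replicate ",
         measurements$replicate[bad[1]])
  if (!reference_label %in% measurements$condition)
    stop("reference condition '", reference_label, "' not present")
  out <- measurements
  out$ratio <- out$firefly / out$renilla
  ref_mean <- mean(out$ratio[out$condition == reference_label])
  out$normalized <- out$ratio / ref_mean
  out
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param groups named list of numeric vectors (or a data.frame with
#'   `condition` and `value` columns); at least 2 groups, each with at
#'   least 2 values.
#' @return list with `F`, `p_value`, `df`, and `tukey` (data.frame
#'   comparison, diff, lwr, upr, p_adj).
#' @export
anova_tukey <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$condition)
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2))
    stop("group '", names(groups)[sizes < 2][1], "' has fewer than 2 values")
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   condition = factor(rep(names(groups), sizes)))
  fit <- stats::aov(value ~ condition, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$condition
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(F = an[["F value"]][1], p_value = an[["Pr(>F)"]][1],
       df = an[["Df"]], tukey = tukey)
}

#' Densitometry fold-change normalization
#'
#' Western-blot band quantification: each band density is divided by its
#' lane's loading-control density, then by the mean loading-corrected
#' value of the reference condition (e.g. non-targeting siRNA), giving
#' fold changes with the reference at 1.
#'
#' @param bands data.frame with columns `condition`, `replicate`, `band`,
#'   `loading` (loading-control density of the same lane).
#' @param reference_label condition used as the normalizer.
#' @return the input with `corrected` (band/loading) and `fold` columns.
#' @export
densitometry_foldchange <- function(bands, reference_label = "NT") {
  need <- c("condition", "replicate", "band", "loading")
  if (!all(need %in% names(bands)))
    stop("bands must have columns: ", paste(need, collapse = ", "))
  if (any(!(bands$loading > 0)))
    stop("loading-control densities must be positive")
  if (!reference_label %in% bands$condition)
    stop("reference condition '", reference_label, "' not present")
  out <- bands
  out$corrected <- out$band / out$loading
  ref_mean <- mean(out$corrected[out$condition == reference_label])
  out$fold <- out$corrected / ref_mean
  out
}
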