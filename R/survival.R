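#' Relapse-free survival inclusion filter
#'
#' Excludes patients with an RFS time of 0 months or greater than
#' `max_months` (default 120 months = 10 years); 120 itself is retained
#' ("greater than" is exclusive).
#'
#' @param records survival data.frame ([read_survival_cohort()] /
#'   [simulate_survival_cohort()]).
#' @param min_months lower bound, exclusive (default 0).
#' @param max_months upper bound, inclusive (default 120).
#' @return filtered data.frame with attribute `n_excluded`.
#' @export
rfs_filter <- function(records, min_months = 0, max_months = 120) {
  keep <- records$rfs_months > min_months & records$rfs_months <= max_months
  out <- records[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

check_two_groups <- function(groups) {
  g <- factor(groups)
  if (nlevels(g) != 2)
    stop("exactly two non-empty groups required (got ", nlevels(g), ")")
  g
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square; simultaneous events at a tied time
#' all enter that time's risk table together.
#'
#' @param times event/censor times.
#' @param events 1 = event, 0 = censored.
#' @param groups binary group labels.
#' @return list with `chi2` and `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  g <- check_two_groups(groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p_value = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Mantel-Haenszel hazard ratio
#'
#' HR = (O2/E2) / (O1/E1) from the log-rank observed/expected table,
#' i.e. the hazard of the second factor level relative to the first;
#' pass a factor to control which level is the reference (character
#' labels sort alphabetically, so "high"/"low" would make "high" the
#' reference). The 95% CI uses the log-scale variance 1/E1 + 1/E2.
#' Undefined (NA, flagged) when a group has zero observed events.
#'
#' @inheritParams logrank_test
#' @return list with `hr`, `ci95` (length-2), `defined`, and the
#'   observed/expected table.
#' @export
hazard_ratio <- function(times, events, groups) {
  g <- check_two_groups(groups)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  O <- sd$obs; E <- sd$exp
  if (any(O == 0) || any(E == 0))
    return(list(hr = NA_real_, ci95 = c(NA_real_, NA_real_),
                defined = FALSE, obs = O, exp = E,
                levels = levels(g)))
  hr <- (O[2] / E[2]) / (O[1] / E[1])
  se <- sqrt(1 / E[1] + 1 / E[2])
  ci <- exp(log(hr) + c(-1, 1) * stats::qnorm(0.975) * se)
  list(hr = unname(hr), ci95 = unname(ci), defined = TRUE,
       obs = unname(O), exp = unname(E), levels = levels(g))
}

#' Best-cutoff expression stratification
#'
#' Re-implementation of "auto select best cutoff" survival stratification:
#' every observed expression value within the quantile range is tried as a
#' threshold (high = strictly above), the two-group log-rank p is computed
#' for each, and the minimizer is returned together with the full
#' candidate table. Ties on p go to the more balanced split, then to the
#' smaller cutoff. The minimum-p cutoff is selected over many candidate
#' tests, so the reported p-value is anti-conservative and is flagged as
#' such when printed; interpret it descriptively.
#'
#' @param cohort survival data.frame with `expression`, `rfs_months`,
#'   `event` columns (apply [rfs_filter()] first as appropriate).
#' @param quantile_range candidate cutoffs are restricted to observed
#'   expression values within these quantiles (default 10th-90th).
#' @return object of class `cutoff_scan`: chosen_cutoff, chi2, p_value,
#'   hazard_ratio, ci95, n_high, n_low, candidates (data.frame cutoff,
#'   p, n_high, n_low).
#' @export
best_cutoff_scan <- function(cohort, quantile_range = c(0.1, 0.9)) {
  if (nrow(cohort) < 2) stop("insufficient data: need >= 2 patients")
  expr <- cohort$expression
  qr <- stats::quantile(expr, quantile_range, names = FALSE)
  cand <- sort(unique(expr[expr >= qr[1] & expr <= qr[2]]))
  cand <- cand[cand < max(expr)]  # "high" = strictly above must be non-empty
  if (length(cand) < 1)
    stop("no usable cutoff candidates: all expression values equal ",
         "or range empty")
  rows <- lapply(cand, function(cv) {
    hi <- expr > cv
    lr <- logrank_test(cohort$rfs_months, cohort$event,
                       factor(hi, levels = c(FALSE, TRUE),
                              labels = c("low", "high")))
    data.frame(cutoff = cv, p = lr$p_value, chi2 = lr$chi2,
               n_high = sum(hi), n_low = sum(!hi))
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$p, abs(tab$n_high - tab$n_low), tab$cutoff)
  best <- tab[ord[1], ]
  hi <- factor(expr > best$cutoff, levels = c(FALSE, TRUE),
               labels = c("low", "high"))
  hr <- hazard_ratio(cohort$rfs_months, cohort$event, hi)
  structure(list(chosen_cutoff = best$cutoff, logrank_chi2 = best$chi2,
                 p_value = best$p, hazard_ratio = hr$hr, ci95 = hr$ci95,
                 n_high = best$n_high, n_low = best$n_low,
                 candidates = tab),
            class = "cutoff_scan")
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf("best-cutoff stratification: cutoff %.4g (high n=%d, low n=%d)\n",
              x$chosen_cutoff, x$n_high, x$n_low))
  cat(sprintf("  log-rank chi2 %.3f, p %.4g; HR (high vs low) %.3g (95%% CI %.3g-%.3g)\n",
              x$logrank_chi2, x$p_value, x$hazard_ratio, x$ci95[1],
              x$ci95[2]))
  cat("  note: p is the minimum over", nrow(x$candidates),
      "candidate cutoffs and is anti-conservative\n")
  invisible(x)
}
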