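#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimate of the survival function, with simultaneous
#' handling of tied event times and the usual convention that events
#' precede censorings at equal times.
#'
#' @param survival a survival table ([read_survival_table()] layout:
#'   `time`, `event`, optionally `sample_id`).
#' @return an object of class `km_estimate`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv` (step function values), `median` (smallest
#'   time with survival at or below 0.5, `NA` if never reached),
#'   `mean_restricted` (mean survival restricted to follow-up), `n`.
#' @export
km_estimate <- function(survival) {
  if (nrow(survival) < 1L) stop_data("need at least one subject")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = survival)
  ev <- sf$n.event > 0
  med <- unname(summary(sf)$table["median"])
  structure(list(time = sf$time[ev], n_risk = sf$n.risk[ev],
                 n_event = sf$n.event[ev], surv = sf$surv[ev],
                 median = med,
                 mean_restricted = unname(summary(sf, rmean = max(survival$time))$table["rmean"]),
                 n = nrow(survival)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate:", x$n, "subjects,", sum(x$n_event), "events\n")
  cat("  median survival:", x$median, "\n")
  invisible(x)
}

# Pool two survival tables with a group factor; drop empty input errors early.
pool_groups <- function(groupA, groupB) {
  if (nrow(groupA) < 1L || nrow(groupB) < 1L) stop_data("both groups need subjects")
  rbind(data.table::data.table(time = groupA$time, event = groupA$event, group = "A"),
        data.table::data.table(time = groupB$time, event = groupB$event, group = "B"))
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' Standard observed-minus-expected chi-square on 1 degree of freedom, with
#' a two-sided p-value.
#'
#' @param groupA,groupB survival tables (`time`, `event`).
#' @return list with `chi2`, `p`, and the per-group observed (`obs`) and
#'   expected (`exp`) event counts and hypergeometric variance `var`.
#' @export
logrank_test <- function(groupA, groupB) {
  d <- pool_groups(groupA, groupB)
  if (sum(d$event) < 1L) stop_data("log-rank test needs at least one event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       obs = unname(sd$obs), exp = unname(sd$exp),
       var = unname(sd$var[1, 1]))
}

#' Mantel-Haenszel hazard ratio between two groups
#'
#' HR = (O_A/E_A) / (O_B/E_B) from the pooled log-rank risk sets, with a
#' 95% confidence interval from the log-scale normal approximation using
#' the log-rank hypergeometric variance V: `exp(log HR +/- 1.96 / sqrt(V))`.
#' When a group has zero observed events the ratio is degenerate; a 0.5
#' continuity correction is applied to both observed counts and the result
#' is flagged.
#'
#' @param groupA,groupB survival tables (`time`, `event`).
#' @return list with `hr` (A vs B), `ci_low`, `ci_high`, `degenerate`.
#' @export
hazard_ratio_mh <- function(groupA, groupB) {
  lr <- logrank_test(groupA, groupB)
  oA <- lr$obs[1]; oB <- lr$obs[2]
  eA <- lr$exp[1]; eB <- lr$exp[2]
  degenerate <- oA == 0 || oB == 0
  if (degenerate) { oA <- oA + 0.5; oB <- oB + 0.5 }
  hr <- (oA / eA) / (oB / eB)
  se <- 1 / sqrt(lr$var)
  list(hr = hr, ci_low = hr * exp(-1.96 * se), ci_high = hr * exp(1.96 * se),
       degenerate = degenerate)
}

#' Optimal expression cutpoint for survival dichotomization
#'
#' Scans candidate cutoffs (midpoints between consecutive distinct
#' expression values whose split respects the minimum group proportion)
#' and selects the cutoff maximizing the log-rank chi-square between the
#' high (`expression > cutoff`) and low groups; ties break toward the
#' smaller cutoff. Subjects missing from either table are dropped with a
#' message.
#'
#' The p-value at the selected cutoff is the naive log-rank p, which is
#' anti-conservative because the cutoff was chosen to maximize the
#' statistic; when `n_perm > 0` a permutation-adjusted p (expression
#' permuted against survival, the maximal statistic recomputed each time)
#' is reported alongside as a diagnostic.
#'
#' @param expression expression table (`sample_id`, `expression`).
#' @param survival survival table (`sample_id`, `time`, `event`).
#' @param minprop minimum fraction of the cohort per group (default 0.1).
#' @param n_perm permutation replicates for the adjusted p (default 1000;
#'   0 disables).
#' @param seed seed for the permutation draw.
#' @return object of class `cutpoint_result`: `cutoff`, `n_high`, `n_low`,
#'   `logrank_chi2`, `p` (naive), `p_adjusted` (permutation, or `NA`),
#'   `hr`, `ci_low`, `ci_high` (high vs low, Mantel-Haenszel), `minprop`,
#'   `n`, plus the merged data used.
#' @export
optimal_cutpoint <- function(expression, survival, minprop = 0.1,
                             n_perm = 1000L, seed = 1L) {
  d <- merge(expression, survival, by = "sample_id")
  dropped <- nrow(expression) + nrow(survival) - 2L * nrow(d)
  if (dropped > 0) message("optimal_cutpoint: ", dropped,
                           " sample(s) missing from one table were dropped")
  n <- nrow(d)
  if (n < ceiling(1 / minprop)) stop_data("too few samples for minprop = ", minprop)

  scan_best <- function(expr_vals) {
    xs <- sort(unique(expr_vals))
    if (length(xs) < 2L) return(NULL)
    cands <- (xs[-1] + xs[-length(xs)]) / 2
    lim <- ceiling(minprop * n)
    best <- NULL
    for (cut in cands) {
      hi <- factor(expr_vals > cut, levels = c(FALSE, TRUE))
      if (min(table(hi)) < lim) next
      dd <- data.table::data.table(time = d$time, event = d$event, hi = hi)
      chi2 <- unname(survival::survdiff(survival::Surv(time, event) ~ hi,
                                        data = dd)$chisq)
      if (is.null(best) || chi2 > best$chi2 + 1e-12) best <- list(cut = cut, chi2 = chi2)
    }
    best
  }

  best <- scan_best(d$expression)
  if (is.null(best)) stop_data("no candidate cutoff satisfies minprop = ", minprop)

  hi <- d$expression > best$cut
  gA <- d[hi, ]; gB <- d[!hi, ]
  lr <- logrank_test(gA, gB)
  mh <- hazard_ratio_mh(gA, gB)

  p_adj <- NA_real_
  if (n_perm > 0) {
    p_adj <- with_seed(seed, {
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        perm <- sample(d$expression)
        pb <- scan_best(perm)
        if (!is.null(pb) && pb$chi2 >= best$chi2 - 1e-12) exceed <- exceed + 1L
      }
      (exceed + 1) / (n_perm + 1)
    })
  }

  structure(list(cutoff = best$cut, n_high = sum(hi), n_low = sum(!hi),
                 logrank_chi2 = lr$chi2, p = lr$p, p_adjusted = p_adj,
                 hr = mh$hr, ci_low = mh$ci_low, ci_high = mh$ci_high,
                 minprop = minprop, n = n, data = d),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("optimal cutpoint %.4g: high n=%d, low n=%d\n",
              x$cutoff, x$n_high, x$n_low))
  cat(sprintf("  log-rank chi2 = %.3f, naive p = %.4g", x$logrank_chi2, x$p))
  if (!is.na(x$p_adjusted)) cat(sprintf(", permutation p = %.4g", x$p_adjusted))
  cat(sprintf("\n  HR (high vs low) = %.3f [%.3f, %.3f]\n",
              x$hr, x$ci_low, x$ci_high))
  cat("  note: the naive p at a maximally selected cutoff is anti-conservative\n")
  invisible(x)
}
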