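#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper around [survival::survfit()] returning the product-limit
#' curve as a plain table. Ties are handled by the simultaneous-event
#' convention and subjects censored at an event time are counted at risk for
#' that event time (the `survfit` convention).
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return List of class `km_curve`: `table` (data frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`) and `median` (smallest time
#'   with survival <= 0.5, `NA` if never reached).
#' @examples
#' km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
#' km$table$surv  # 2/3, 1/3, 0
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1L) mf_stop("need at least one record", "midflux_input_error")
  if (any(time <= 0)) mf_stop("times must be positive", "midflux_input_error")
  if (!all(event %in% c(0, 1))) mf_stop("event must be 0 or 1", "midflux_input_error")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  tab <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    n_censor = fit$n.censor, surv = fit$surv)
  med <- tab$time[tab$surv <= 0.5 & tab$n_event > 0]
  structure(list(table = tab, median = if (length(med)) med[1L] else NA_real_),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, median = %s\n", nrow(x$table),
              format(x$median)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: at each event time
#' the observed events in each group are compared with their hypergeometric
#' expectation, and the summed difference is referred to chi-square with one
#' degree of freedom (via [survival::survdiff()]).
#'
#' @param time_a,event_a Times and event indicators of group A.
#' @param time_b,event_b Times and event indicators of group B.
#' @return List of class `logrank_result`: `statistic` (chi-square), `p`,
#'   `n` (group sizes), `observed` and `expected` event counts per group.
#' @examples
#' logrank_test(c(2, 4, 6, 8), c(1, 1, 1, 0), c(1, 2, 3, 4), c(1, 1, 1, 1))
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) < 1L || length(time_b) < 1L) {
    mf_stop("both groups must be non-empty", "midflux_input_error")
  }
  if (sum(event_a) + sum(event_b) == 0) {
    mf_stop("log-rank test undefined: no events in either group", "midflux_degenerate_test")
  }
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("a", "b"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(statistic = unname(sd$chisq), p = p,
                 n = unname(sd$n), observed = unname(sd$obs),
                 expected = unname(sd$exp)),
            class = "logrank_result")
}

#' Best-cutoff survival dichotomization
#'
#' Scans every integer expression percentile between the lower and upper
#' quartiles, dichotomizes the cohort at each candidate cutoff (high group:
#' expression strictly greater than the cutoff; ties go low), runs a
#' log-rank test, and keeps the cutoff with the smallest p-value. The
#' selected p-value is optimized over ~51 correlated tests and is therefore
#' anti-conservative; it is returned with an explicit
#' `p_selection_biased = TRUE` flag, and an optional permutation-adjusted
#' p-value (expression labels permuted, min-p re-selected each time) can be
#' requested.
#'
#' @param time,event Survival times and event indicators.
#' @param expr Expression values, one per subject.
#' @param percentiles Integer percentiles to scan; default `25:75`.
#' @param permutations Number of label permutations for the adjusted
#'   p-value; 0 (default) skips it.
#' @return List of class `best_cutoff_result`: `cutoff`, `percentile`,
#'   `statistic`, `p`, `p_selection_biased` (always `TRUE`), `p_permutation`
#'   (`NA` unless requested), `scan` (data frame: `percentile`, `cutoff`,
#'   `n_high`, `statistic`, `p`, `skipped`).
#' @export
best_cutoff <- function(time, event, expr, percentiles = 25:75, permutations = 0) {
  n <- length(time)
  if (n < 20L) mf_stop("best-cutoff scan needs >= 20 records", "midflux_degenerate_input")
  if (length(unique(expr)) < 2L) {
    mf_stop("degenerate input: expression is constant", "midflux_degenerate_input")
  }
  scan <- scan_cutoffs(time, event, expr, percentiles)
  ok <- !scan$skipped
  if (!any(ok)) mf_stop("every candidate percentile was skipped", "midflux_degenerate_input")
  best <- which(ok)[which.min(scan$p[ok])]
  p_perm <- NA_real_
  if (permutations > 0) {
    obs_min <- scan$p[best]
    hits <- 0L
    for (i in seq_len(permutations)) {
      sc <- scan_cutoffs(time, event, sample(expr), percentiles)
      pmin_i <- suppressWarnings(min(sc$p[!sc$skipped], na.rm = TRUE))
      if (is.finite(pmin_i) && pmin_i <= obs_min) hits <- hits + 1L
    }
    p_perm <- (hits + 1) / (permutations + 1)
  }
  structure(list(cutoff = scan$cutoff[best], percentile = scan$percentile[best],
                 statistic = scan$statistic[best], p = scan$p[best],
                 p_selection_biased = TRUE, p_permutation = p_perm, scan = scan),
            class = "best_cutoff_result")
}

scan_cutoffs <- function(time, event, expr, percentiles) {
  scan <- data.frame(percentile = percentiles,
                     cutoff = as.numeric(stats::quantile(expr, percentiles / 100, names = FALSE)),
                     n_high = NA_integer_, statistic = NA_real_, p = NA_real_,
                     skipped = FALSE)
  srv <- survival::Surv(time, event)
  for (i in seq_len(nrow(scan))) {
    high <- expr > scan$cutoff[i]
    scan$n_high[i] <- sum(high)
    if (!any(high) || all(high) ||
        sum(event[high]) + sum(event[!high]) == 0) {
      scan$skipped[i] <- TRUE
      next
    }
    sd <- survival::survdiff(srv ~ high)
    scan$statistic[i] <- unname(sd$chisq)
    scan$p[i] <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  }
  scan
}

#' @export
print.best_cutoff_result <- function(x, ...) {
  cat(sprintf("<best_cutoff_result> percentile %d (cutoff %.4g): chisq = %.3f, p = %.3g\n",
              x$percentile, x$cutoff, x$statistic, x$p))
  cat("  note: p minimized over the percentile scan (selection-biased)\n")
  if (is.finite(x$p_permutation)) cat(sprintf("  permutation-adjusted p = %.3g\n", x$p_permutation))
  invisible(x)
}

#' Pearson correlation with t-test p-value
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    mf_stop("need >= 3 complete pairs", "midflux_input_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    mf_stop("correlation undefined: zero variance", "midflux_degenerate_input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
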