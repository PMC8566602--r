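#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)`, with all
#' events at a tied time handled in one risk-set step and censored-only
#' times reducing the risk set without a step.
#'
#' @param time Non-negative follow-up times (months).
#' @param event Event indicators (1 = death, 0 = censored).
#' @return Object of class `km_fit`: data frame `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` over the distinct observed times, with
#'   `S(0) = 1` implicit before the first row.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop2("need at least one subject")
  if (any(time < 0)) stop2("negative follow-up times")
  if (!all(event %in% c(0, 1))) stop2("event must be 0/1")
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, surv = surv),
            class = c("km_fit", "data.frame"))
}

#' Two-group log-rank (Mantel-Cox) test with O/E hazard ratio
#'
#' At every distinct event time the observed events in group A are compared
#' with the hypergeometric expectation given the pooled risk set;
#' `chi2 = (O_A - E_A)^2 / V` with V the summed hypergeometric variance,
#' and p from the chi-square distribution with 1 df (two-tailed). The
#' hazard ratio is the Mantel-Haenszel-style ratio of observed/expected
#' event ratios `HR = (O_A/E_A) / (O_B/E_B)` — the "log-rank HR" convention
#' of survival-plotting software — with a 95% CI
#' `exp(log HR +/- 1.96 * sqrt(1/E_A + 1/E_B))`. Swapping the group labels
#' inverts HR and leaves chi2 and p unchanged.
#'
#' @param time,event Follow-up times and 0/1 event indicators.
#' @param group Two-level factor/character; the first level is group A
#'   (the HR numerator).
#' @return Object of class `logrank_test`: `chi2`, `p`, `hr`, `hr_ci95`,
#'   `observed`, `expected` (per group), `km` (list of per-group
#'   [km_estimate()] fits).
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop2("exactly two groups required")
  if (any(table(group) == 0)) stop2("both groups must be nonempty")
  if (any(time < 0)) stop2("negative follow-up times")
  if (sum(event) == 0) stop2("no events: log-rank test undefined")
  a <- levels(group)[1]; b <- levels(group)[2]
  ut <- sort(unique(time[event == 1]))
  oa <- ea <- v <- 0
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    na <- sum(at_risk & group == a)
    d <- sum(time == t & event == 1)
    da <- sum(time == t & event == 1 & group == a)
    oa <- oa + da
    ea <- ea + d * na / n
    if (n > 1)
      v <- v + d * (n - d) * na * (n - na) / (n^2 * (n - 1))
  }
  ob <- sum(event) - oa
  eb <- sum(event) - ea
  chi2 <- if (v > 0) (oa - ea)^2 / v else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  hr <- (oa / ea) / (ob / eb)
  se_log <- sqrt(1 / ea + 1 / eb)
  ci <- exp(log(hr) + c(-1, 1) * 1.96 * se_log)
  structure(list(chi2 = chi2, p = p, hr = hr, hr_ci95 = ci,
                 observed = stats::setNames(c(oa, ob), c(a, b)),
                 expected = stats::setNames(c(ea, eb), c(a, b)),
                 km = list(
                   km_estimate(time[group == a], event[group == a]),
                   km_estimate(time[group == b], event[group == b])) |>
                   stats::setNames(c(a, b))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chi2 = %.4f, p = %.4g\n", x$chi2, x$p))
  cat(sprintf("HR (%s vs %s) = %.4f [95%% CI %.4f, %.4f]\n",
              names(x$observed)[1], names(x$observed)[2],
              x$hr, x$hr_ci95[1], x$hr_ci95[2]))
  cat(sprintf("O/E: %s %g/%.4f, %s %g/%.4f\n",
              names(x$observed)[1], x$observed[1], x$expected[1],
              names(x$observed)[2], x$observed[2], x$expected[2]))
  invisible(x)
}

#' Median split of a score
#'
#' Labels samples `"hi"` when strictly above the median and `"lo"`
#' otherwise (ties at the median go to `"lo"`, keeping "hi" strictly above
#' it). With an even number of distinct scores this yields equal halves.
#'
#' @param x Numeric scores (named vector preserved).
#' @return Factor with levels `hi`, `lo`, in input order.
#' @export
median_split <- function(x) {
  if (sum(is.finite(x)) < 2) stop2("need >= 2 finite scores")
  if (length(unique(x[is.finite(x)])) == 1)
    stop2("all scores equal: median split undefined")
  med <- stats::median(x, na.rm = TRUE)
  f <- factor(ifelse(x > med, "hi", "lo"), levels = c("hi", "lo"))
  names(f) <- names(x)
  f
}

#' Truncate follow-up at a horizon
#'
#' Administrative truncation for fixed-horizon analyses (e.g. 15-year
#' overall survival at 180 months): times beyond the horizon are set to the
#' horizon and their events censored. Idempotent.
#'
#' @param meta Data frame with `time` and `event` columns.
#' @param horizon_months Truncation time (months), default 180.
#' @return `meta` with truncated `time`/`event`.
#' @export
truncate_followup <- function(meta, horizon_months = 180) {
  if (horizon_months <= 0) stop2("horizon must be > 0")
  if (!all(c("time", "event") %in% names(meta)))
    stop2("meta needs time and event columns")
  over <- meta$time > horizon_months
  meta$event[over] <- 0L
  meta$time[over] <- horizon_months
  meta
}
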