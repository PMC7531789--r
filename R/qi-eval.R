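#' Exclusion filtering for time-to-antibiotic analysis
#'
#' Among antibiotic recipients, drops records with no recorded triage
#' completion, with a triage-to-antibiotic interval above the cap (treatment
#' intentionally delayed), or with an antibiotic time before the triage time
#' (children brought to the treatment room before routine triage). Records
#' without an antibiotic time pass through untouched. Demographic
#' plausibility is *flagged*, not dropped: ages negative or missing, heights
#' under 25 or over 200 cm or missing, weights under 1 or over 150 kg or
#' missing are counted for the report only.
#'
#' The filter is idempotent: applying it to its own output changes nothing.
#'
#' @param records a data frame with at least `triage_end` and
#'   `iv_antibiotics_time` (minutes; `NA` allowed).
#' @param cap_hours exclusion cap on the interval, in hours (default 5).
#' @return list with `records` (filtered) and `report` (class
#'   `exclusion_report`): `n_input` antibiotic recipients,
#'   `n_missing_triage_time`, `n_over_cap`, `n_negative`, `n_analyzed`, and
#'   the demographic flag counts.
#' @export
apply_exclusions <- function(records, cap_hours = 5) {
  if (!is.numeric(cap_hours) || cap_hours <= 0)
    stop("cap_hours must be positive")
  stopifnot(is.data.frame(records),
            all(c("triage_end", "iv_antibiotics_time") %in% names(records)))
  cap_min <- cap_hours * 60
  iva <- !is.na(records$iv_antibiotics_time)
  tta <- records$iv_antibiotics_time - records$triage_end
  miss <- iva & is.na(records$triage_end)
  over <- iva & !miss & tta > cap_min
  neg <- iva & !miss & tta < 0
  drop <- miss | over | neg
  col_or <- function(nm) if (nm %in% names(records)) records[[nm]] else
    rep(NA_real_, nrow(records))
  age <- col_or("age"); height <- col_or("height"); weight <- col_or("weight")
  report <- structure(list(
    n_input = sum(iva),
    n_missing_triage_time = sum(miss),
    n_over_cap = sum(over),
    n_negative = sum(neg),
    n_analyzed = sum(iva) - sum(miss) - sum(over) - sum(neg),
    n_age_flagged = sum(is.na(age) | age < 0),
    n_height_flagged = sum(is.na(height) | height < 25 | height > 200),
    n_weight_flagged = sum(is.na(weight) | weight < 1 | weight > 150)),
    class = "exclusion_report")
  list(records = records[!drop, , drop = FALSE], report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  excl <- x$n_input - x$n_analyzed
  cat(sprintf(paste0(
    "Antibiotic recipients: %d\n  excluded: %d (%.1f%%) -- %d missing ",
    "triage time, %d over cap, %d antibiotics before triage\n  analyzed: %d\n"),
    x$n_input, excl, 100 * excl / max(x$n_input, 1),
    x$n_missing_triage_time, x$n_over_cap, x$n_negative, x$n_analyzed))
  cat(sprintf("  demographic flags: %d age, %d height, %d weight\n",
              x$n_age_flagged, x$n_height_flagged, x$n_weight_flagged))
  invisible(x)
}

#' Compare pre/post times at the median
#'
#' Summarises both arms with type-7 medians and IQRs, estimates the
#' post-minus-pre shift by median (tau = 0.5) quantile regression of the
#' time on a phase indicator with a rank-inversion 95% confidence interval,
#' reports the Hodges--Lehmann location shift alongside, and tests the
#' arms with a Mann--Whitney U test (exact when both arms have at most 20
#' observations and no ties; tie-corrected normal approximation otherwise).
#'
#' @param pre_times,post_times non-empty numeric vectors of minutes.
#' @param conf_level confidence level for the shift interval.
#' @return an object of class `median_comparison`.
#' @export
compare_medians <- function(pre_times, post_times, conf_level = 0.95) {
  if (!length(pre_times) || !length(post_times))
    stop("both arms must be non-empty")
  pre <- med_iqr(pre_times); post <- med_iqr(post_times)
  y <- c(pre_times, post_times)
  phase <- c(rep(0L, length(pre_times)), rep(1L, length(post_times)))
  fit <- suppressWarnings(quantreg::rq(y ~ phase, tau = 0.5))
  shift <- unname(stats::coef(fit)[2])
  ci <- rq_shift_ci(fit, y, phase, conf_level)
  n_small <- length(pre_times) <= 20 && length(post_times) <= 20
  exact <- n_small && !any(duplicated(y))
  mw <- suppressWarnings(stats::wilcox.test(post_times, pre_times,
                                            exact = exact, correct = TRUE,
                                            conf.int = TRUE,
                                            conf.level = conf_level))
  structure(list(
    median_pre = pre$median, median_post = post$median,
    iqr_pre = c(pre$q1, pre$q3), iqr_post = c(post$q1, post$q3),
    shift_estimate = shift, shift_ci = ci,
    hl_estimate = unname(mw$estimate), hl_ci = as.numeric(mw$conf.int),
    mw_p = mw$p.value, n_pre = length(pre_times),
    n_post = length(post_times), conf_level = conf_level),
    class = "median_comparison")
}

# Rank-inversion CI for the phase coefficient; falls back to a normal-theory
# interval (sandwich) for samples too large for rank inversion.
rq_shift_ci <- function(fit, y, phase, conf_level) {
  n <- length(y)
  ci <- tryCatch({
    if (n <= 5000) {
      s <- suppressWarnings(
        quantreg::summary.rq(fit, se = "rank", alpha = 1 - conf_level))
      unname(s$coefficients["phase", c("lower bd", "upper bd")])
    } else stop("large")
  }, error = function(e) NULL)
  if (is.null(ci)) {
    s <- quantreg::summary.rq(fit, se = "nid")
    est <- s$coefficients["phase", "Value"]
    se <- s$coefficients["phase", "Std. Error"]
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- c(est - z * se, est + z * se)
  }
  as.numeric(ci)
}

#' @export
print.median_comparison <- function(x, ...) {
  cat(sprintf("pre : median %.1f (IQR %.1f-%.1f), n = %d\n",
              x$median_pre, x$iqr_pre[1], x$iqr_pre[2], x$n_pre))
  cat(sprintf("post: median %.1f (IQR %.1f-%.1f), n = %d\n",
              x$median_post, x$iqr_post[1], x$iqr_post[2], x$n_post))
  cat(sprintf("shift (median regression): %.1f min (%d%% CI %.1f to %.1f)\n",
              x$shift_estimate, round(100 * x$conf_level),
              x$shift_ci[1], x$shift_ci[2]))
  cat(sprintf("Hodges-Lehmann: %.1f (%.1f to %.1f); Mann-Whitney p = %.3g\n",
              x$hl_estimate, x$hl_ci[1], x$hl_ci[2], x$mw_p))
  invisible(x)
}

#' Odds ratio for two proportions
#'
#' Sample odds ratio of the second arm against the first, with a Woolf
#' (log-scale) 95% confidence interval using a 0.5 continuity correction
#' when any cell is empty, and a Fisher exact p-value.
#'
#' @param a_events,a_total events and total in the reference arm.
#' @param b_events,b_total events and total in the comparison arm.
#' @param conf_level confidence level.
#' @return list with `or`, `ci`, `p`, and the 2x2 `table`.
#' @export
odds_ratio <- function(a_events, a_total, b_events, b_total,
                       conf_level = 0.95) {
  cells <- c(a_events, a_total, b_events, b_total)
  if (any(cells < 0) || a_events > a_total || b_events > b_total ||
      a_total == 0 || b_total == 0)
    stop("need 0 <= events <= total with totals > 0")
  tab <- matrix(c(b_events, b_total - b_events,
                  a_events, a_total - a_events), nrow = 2, byrow = TRUE,
                dimnames = list(arm = c("b", "a"),
                                outcome = c("event", "no event")))
  cc <- if (any(tab == 0)) 0.5 else 0
  t2 <- tab + cc
  or <- (t2[1, 1] / t2[1, 2]) / (t2[2, 1] / t2[2, 2])
  se <- sqrt(sum(1 / t2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-z, z) * se)
  p <- stats::fisher.test(tab)$p.value
  list(or = unname(or), ci = unname(ci), p = p, table = tab)
}

#' Distribution of times over brackets
#'
#' Allocates analyzed times to half-open brackets `[lo, hi)` covering
#' `[0, Inf)` and exposes the named summaries the one-hour sepsis bundle
#' target cares about: the mass waiting an hour or longer and the mass
#' treated within half an hour.
#'
#' @param times numeric minutes.
#' @param breaks increasing bracket boundaries starting at 0; `Inf` is
#'   appended if absent. Overlap cannot arise from a boundary vector;
#'   non-increasing boundaries are rejected.
#' @return list with `brackets` (data frame: `lo`, `hi`, `n`, `proportion`),
#'   `prop_hour_plus` (share with time >= 60) and `prop_within_30`
#'   (share with time <= 30).
#' @export
time_bracket_distribution <- function(times, breaks = c(0, 30, 60, 90, 120, Inf)) {
  stopifnot(length(times) > 0, all(times >= 0))
  if (is.list(breaks)) {
    # list of c(lo, hi) pairs: must tile [0, Inf) without overlap
    m <- do.call(rbind, breaks)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (m[1, 1] != 0 || any(m[-1, 1] != m[-nrow(m), 2]) ||
        !is.infinite(m[nrow(m), 2]))
      stop("brackets must be non-overlapping, gap-free and cover [0, Inf)")
    breaks <- c(m[, 1], Inf)
  }
  if (any(diff(breaks) <= 0)) stop("bracket boundaries must increase")
  if (breaks[1] != 0) stop("brackets must start at 0")
  if (!is.infinite(breaks[length(breaks)])) breaks <- c(breaks, Inf)
  idx <- findInterval(times, breaks)  # [lo, hi) by default
  n <- tabulate(idx, nbins = length(breaks) - 1)
  list(brackets = data.frame(lo = breaks[-length(breaks)],
                             hi = breaks[-1], n = n,
                             proportion = n / length(times)),
       prop_hour_plus = mean(times >= 60),
       prop_within_30 = mean(times <= 30))
}

#' Relative change between two percentages
#'
#' The percentage change of `to` relative to `from` (for example, a fall
#' from 44.3% to 34.8% of children waiting over an hour is a 21.4%
#' relative decrease, returned as -21.4).
#'
#' @param from,to percentages (or any two positive quantities).
#' @return relative change in percent.
#' @export
relative_change <- function(from, to) {
  stopifnot(from != 0)
  100 * (to - from) / from
}

#' Compare two proportions
#'
#' Chi-squared (default for the over-one-hour comparison) or Fisher exact
#' test for an event proportion between two arms.
#'
#' @param a_events,a_total,b_events,b_total the 2x2 counts.
#' @param method `"chisq"` or `"fisher"`.
#' @return the `htest` result.
#' @export
compare_proportions <- function(a_events, a_total, b_events, b_total,
                                method = c("chisq", "fisher")) {
  method <- match.arg(method)
  tab <- matrix(c(a_events, a_total - a_events,
                  b_events, b_total - b_events), nrow = 2, byrow = TRUE)
  if (method == "chisq") stats::chisq.test(tab) else stats::fisher.test(tab)
}
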