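#' Prioritization adherence from an encounter log
#'
#' Replays the seen events of a log to measure how often the dashboard's
#' prioritization was followed. At each seen event the waiting set is every
#' child already triaged and not yet seen; the child *due* is the top of
#' the severity-then-triage-completion ordering of that set (ties broken by
#' patient id). An event is an *opportunity* attributed to the due child's
#' category -- this matches quoting adherence "in emergency cases": the
#' cases where an emergency child was due. The event counts as adhered when
#' the seen child is the due child; when someone else is seen but the due
#' child is themselves seen within `tolerance_min` minutes (patient
#' movement, dashboard refresh), the event is set aside rather than scored,
#' since the due child's own imminent event records the adherence;
#' otherwise it is a violation. Two kinds of event are excluded as
#' uninformative about whether staff used the dashboard: events with a
#' single waiting child (`n_sole_waiter_excluded`, that child's position
#' was forced) and, when `exclude_concordant` is `TRUE` (the default),
#' events where the due child is also the longest-waiting child
#' (`n_concordant_excluded`), since severity ordering and arrival ordering
#' then agree and first-come-first-served habit alone produces the same
#' service order. Concordance does not depend on what staff did, so the
#' exclusion leaves the remaining events an unbiased sample of the genuine
#' conflict decisions.
#'
#' Records whose `seen_time` precedes `triage_end` are dropped from the
#' replay with a warning and counted in `n_invalid_excluded`.
#'
#' @param records a data frame with `patient_id`, `category`, `triage_end`
#'   and `seen_time` (minutes; untriaged or unseen rows are ignored).
#' @param tolerance_min minutes of slack for patient movement (default 5).
#' @param exclude_concordant drop events where severity and arrival order
#'   agree on the due child (default `TRUE`).
#' @return an `adherence_report`: per-category `n_opportunities`,
#'   `n_adhered`, `proportion`, plus `n_sole_waiter_excluded`,
#'   `n_concordant_excluded`, `n_within_tolerance` and
#'   `n_invalid_excluded`.
#' @export
prioritization_adherence <- function(records, tolerance_min = 5,
                                     exclude_concordant = TRUE) {
  stopifnot(is.data.frame(records),
            all(c("category", "triage_end", "seen_time") %in% names(records)))
  ok <- !is.na(records$triage_end) & !is.na(records$seen_time) &
    !is.na(records$category)
  r <- records[ok, , drop = FALSE]
  invalid <- r$seen_time < r$triage_end
  if (any(invalid)) {
    warning(sum(invalid), " record(s) seen before triage completion ",
            "excluded from adherence replay")
    r <- r[!invalid, , drop = FALSE]
  }
  n <- nrow(r)
  sev <- severity_rank(r$category)
  te <- r$triage_end
  st <- r$seen_time
  pid <- as.character(r$patient_id %||% seq_len(n))
  opp <- adh <- stats::setNames(rep(0L, 3), rev(CATEGORIES))
  sole <- tolzd <- conc <- 0L
  ord <- order(st, te, pid)
  for (i in ord) {
    t <- st[i]
    wait <- which(te <= t & st >= t)
    if (length(wait) < 2) { sole <- sole + length(wait); next }
    due <- wait[order(-sev[wait], te[wait], pid[wait])][1]
    if (exclude_concordant) {
      head_ <- wait[order(te[wait], pid[wait])][1]
      if (due == head_) { conc <- conc + 1L; next }
    }
    cat_due <- r$category[due]
    if (due == i) {
      opp[cat_due] <- opp[cat_due] + 1L
      adh[cat_due] <- adh[cat_due] + 1L
    } else if (st[due] - t <= tolerance_min) {
      tolzd <- tolzd + 1L
    } else {
      opp[cat_due] <- opp[cat_due] + 1L
    }
  }
  structure(list(
    n_opportunities = opp, n_adhered = adh,
    proportion = ifelse(opp > 0, adh / opp, NA_real_),
    tolerance_min = tolerance_min,
    n_sole_waiter_excluded = sole,
    n_concordant_excluded = conc,
    n_within_tolerance = tolzd,
    n_invalid_excluded = sum(invalid)), class = "adherence_report")
}

#' @export
print.adherence_report <- function(x, ...) {
  cat("Prioritization adherence (tolerance", x$tolerance_min, "min)\n")
  for (cat_ in names(x$n_opportunities)) {
    if (x$n_opportunities[cat_] == 0) next
    cat(sprintf("  %-10s %d/%d adhered (%.1f%%)\n", tolower(cat_),
                x$n_adhered[cat_], x$n_opportunities[cat_],
                100 * x$proportion[cat_]))
  }
  cat(sprintf("  excluded: %d sole-waiter, %d concordant, %d within-tolerance, %d invalid\n",
              x$n_sole_waiter_excluded, x$n_concordant_excluded,
              x$n_within_tolerance, x$n_invalid_excluded))
  invisible(x)
}

#' Weekly feedback summary
#'
#' The key per-week numbers fed back to the department: children triaged,
#' median triage duration, median triage-to-antibiotic time, category
#' counts, and the dashboard's warning tally -- priority or emergency
#' children whose wait from triage completion to being seen exceeded one
#' hour (or who were never seen).
#'
#' @param records an encounter log (minutes from origin).
#' @return a data frame, one row per week of the study.
#' @export
weekly_summary <- function(records) {
  stopifnot(is.data.frame(records))
  cols <- c("week", "n_triaged", "median_triage_duration", "median_tta",
            "n_emergency", "n_priority", "n_non_urgent", "n_hour_warnings")
  if (!nrow(records))
    return(stats::setNames(data.frame(matrix(numeric(), ncol = length(cols))),
                           cols))
  wk <- as.integer(floor(records$triage_end / MINUTES_PER_WEEK)) + 1L
  med_or_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) stats::median(x) else NA_real_
  }
  rows <- lapply(sort(unique(wk[!is.na(wk)])), function(w) {
    r <- records[!is.na(wk) & wk == w, , drop = FALSE]
    urgent <- r$category %in% c("EMERGENCY", "PRIORITY")
    wait_seen <- r$seen_time - r$triage_end
    data.frame(
      week = w, n_triaged = nrow(r),
      median_triage_duration = med_or_na(r$triage_end - r$triage_start),
      median_tta = med_or_na(r$iv_antibiotics_time - r$triage_end),
      n_emergency = sum(r$category == "EMERGENCY", na.rm = TRUE),
      n_priority = sum(r$category == "PRIORITY", na.rm = TRUE),
      n_non_urgent = sum(r$category == "NON_URGENT", na.rm = TRUE),
      n_hour_warnings = sum(urgent & (is.na(wait_seen) | wait_seen > 60),
                            na.rm = TRUE))
  })
  do.call(rbind, rows)
}
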