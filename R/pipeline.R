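#' Full quality-improvement evaluation of a pre/post encounter log
#'
#' Runs the whole evaluation over a log carrying both phases: exclusion
#' filtering per phase, the overall and per-category median comparisons,
#' the antibiotic-receipt odds ratio, the time-bracket distribution with
#' the over-one-hour test, the post-phase prioritization adherence, the
#' weekly summaries, and the segmented median regression of the interrupted
#' time series with its counterfactual projection.
#'
#' @param records an encounter log with a `phase` column (`"pre"`/`"post"`),
#'   `category`, `triage_end` and `iv_antibiotics_time`; `seen_time` enables
#'   the adherence metric.
#' @param interruption_week start of the post phase, in weeks from origin.
#' @param cap_hours exclusion cap for [apply_exclusions()].
#' @param tolerance_min adherence tolerance for [prioritization_adherence()].
#' @return a list of class `qi_report` with components `exclusions`,
#'   `overall`, `by_category`, `iva_receipt_or`, `brackets`, `hour_plus`,
#'   `adherence`, `weekly`, `segmented`.
#' @export
evaluate_log <- function(records, interruption_week = 16.5, cap_hours = 5,
                         tolerance_min = 5) {
  stopifnot(is.data.frame(records), "phase" %in% names(records))
  arms <- split(records, records$phase)
  if (!all(c("pre", "post") %in% names(arms)))
    stop("records must contain both a pre and a post phase")
  ex <- lapply(arms[c("pre", "post")], apply_exclusions,
               cap_hours = cap_hours)
  tta <- lapply(ex, function(e) {
    r <- e$records
    (r$iv_antibiotics_time - r$triage_end)[!is.na(r$iv_antibiotics_time)]
  })
  overall <- compare_medians(tta$pre, tta$post)
  by_cat <- list()
  for (cat_ in CATEGORIES) {
    t_pre <- with(ex$pre$records,
                  (iv_antibiotics_time - triage_end)[
                    !is.na(iv_antibiotics_time) & category == cat_])
    t_post <- with(ex$post$records,
                   (iv_antibiotics_time - triage_end)[
                     !is.na(iv_antibiotics_time) & category == cat_])
    if (length(t_pre) >= 2 && length(t_post) >= 2)
      by_cat[[cat_]] <- compare_medians(t_pre, t_post)
  }
  or <- odds_ratio(ex$pre$report$n_input, nrow(arms$pre),
                   ex$post$report$n_input, nrow(arms$post))
  br <- lapply(tta, time_bracket_distribution)
  hour_test <- compare_proportions(sum(tta$pre >= 60), length(tta$pre),
                                   sum(tta$post >= 60), length(tta$post),
                                   method = "chisq")
  adh <- if ("seen_time" %in% names(records))
    prioritization_adherence(arms$post, tolerance_min = tolerance_min)
  else NULL
  analyzed <- rbind(ex$pre$records, ex$post$records)
  seg <- tryCatch(fit_segmented(analyzed, interruption_week),
                  error = function(e) NULL)
  structure(list(
    exclusions = lapply(ex, `[[`, "report"),
    overall = overall, by_category = by_cat, iva_receipt_or = or,
    brackets = br,
    hour_plus = list(pre = br$pre$prop_hour_plus,
                     post = br$post$prop_hour_plus,
                     relative_change = relative_change(
                       100 * br$pre$prop_hour_plus,
                       100 * br$post$prop_hour_plus),
                     p = hour_test$p.value),
    adherence = adh,
    weekly = weekly_summary(records),
    segmented = seg), class = "qi_report")
}

#' @export
print.qi_report <- function(x, ...) {
  cat("== Exclusions (pre) ==\n"); print(x$exclusions$pre)
  cat("== Time to intravenous antibiotics, overall ==\n"); print(x$overall)
  cat(sprintf("== Antibiotic receipt: OR %.2f (%.2f, %.2f), p = %.3g ==\n",
              x$iva_receipt_or$or, x$iva_receipt_or$ci[1],
              x$iva_receipt_or$ci[2], x$iva_receipt_or$p))
  cat(sprintf("== Over one hour: %.1f%% -> %.1f%% (%.1f%% relative, p = %.3g) ==\n",
              100 * x$hour_plus$pre, 100 * x$hour_plus$post,
              x$hour_plus$relative_change, x$hour_plus$p))
  if (!is.null(x$adherence)) {
    cat("== Adherence ==\n"); print(x$adherence)
  }
  if (!is.null(x$segmented)) {
    cat("== Interrupted time series ==\n"); print(x$segmented)
  }
  invisible(x)
}

#' Flatten a QI report to plain lists for JSON export
#'
#' @param x a `qi_report`.
#' @return a nested list of plain numbers suitable for
#'   [jsonlite::write_json()].
#' @export
qi_report_json <- function(x) {
  mc <- function(m) list(
    median_pre = m$median_pre, median_post = m$median_post,
    iqr_pre = m$iqr_pre, iqr_post = m$iqr_post,
    shift = m$shift_estimate, shift_ci = m$shift_ci,
    hl = m$hl_estimate, mw_p = m$mw_p, n_pre = m$n_pre, n_post = m$n_post)
  out <- list(
    exclusions = lapply(x$exclusions, unclass),
    overall = mc(x$overall),
    by_category = lapply(x$by_category, mc),
    iva_receipt_or = x$iva_receipt_or[c("or", "ci", "p")],
    hour_plus = x$hour_plus)
  if (!is.null(x$adherence))
    out$adherence <- list(
      proportion = as.list(x$adherence$proportion),
      opportunities = as.list(x$adherence$n_opportunities),
      sole_waiter_excluded = x$adherence$n_sole_waiter_excluded)
  if (!is.null(x$segmented)) {
    s <- x$segmented
    out$segmented <- list(
      level_pre = s$level_pre, slope_pre = s$slope_pre,
      level_change = s$level_change, slope_change = s$slope_change,
      p_level = s$p_level, p_slope = s$p_slope,
      fitted_end = s$fitted_end, counterfactual_end = s$counterfactual_end)
  }
  out
}
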