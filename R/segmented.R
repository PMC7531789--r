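#' Segmented quantile regression of an interrupted time series
#'
#' Fits, at quantile `tau` (default the median), the standard
#' interrupted-time-series design over *individual* observations:
#'
#'   Q_tau(time) = b0 + b1 * week + b2 * post + b3 * (week - interruption) * post
#'
#' where `week` is continuous weeks since the series start and `post`
#' indicates observations at or after the interruption. `b0`/`b1` are the
#' pre-implementation level and trend, `b2` the immediate level change at
#' the interruption, and `b3` the trend change. The counterfactual
#' projection at any week extrapolates the pre-segment coefficients alone
#' (`b0 + b1 * week`), the no-intervention expectation. Fitting every data
#' point rather than period means keeps the estimate honest about
#' within-period spread; p-values come from the Huber sandwich for quantile
#' regression.
#'
#' @param records either an encounter log (rows with `triage_end` and
#'   `iv_antibiotics_time`, minutes from origin, from which weeks and
#'   intervals are derived) or a data frame with columns `week` and `time`.
#' @param interruption_week the interruption, in weeks since series start.
#'   Observations during an implementation gap simply do not appear in the
#'   data.
#' @param tau the quantile, in (0, 1).
#' @return an object of class `segmented_rq` with methods `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `residuals` and `plot`.
#' @examples
#' df <- data.frame(week = rep(0:21, each = 5),
#'                  time = 50 - 0.2 * rep(0:21, each = 5) + rnorm(110, 0, 4))
#' fit <- fit_segmented(df, interruption_week = 11)
#' coef(fit)
#' @export
fit_segmented <- function(records, interruption_week, tau = 0.5) {
  stopifnot(tau > 0, tau < 1)
  df <- as_its_frame(records)
  pre <- df$week < interruption_week
  for (seg in list(df$week[pre], df$week[!pre]))
    if (length(unique(floor(seg))) < 2)
      stop("each segment needs observations in at least 2 distinct weeks")
  post <- as.integer(!pre)
  wk_since <- pmax(df$week - interruption_week, 0) * post
  fit <- suppressWarnings(
    quantreg::rq(df$time ~ df$week + post + wk_since, tau = tau))
  b <- unname(stats::coef(fit))
  s <- tryCatch(quantreg::summary.rq(fit, se = "nid")$coefficients,
                error = function(e)
                  quantreg::summary.rq(fit, se = "boot", R = 200)$coefficients)
  end_week <- max(df$week)
  structure(list(
    level_pre = b[1], slope_pre = b[2], level_change = b[3],
    slope_change = b[4],
    fitted_end = b[1] + b[2] * end_week + b[3] +
      b[4] * (end_week - interruption_week),
    counterfactual_end = b[1] + b[2] * end_week,
    quantile = tau, p_level = s[3, 4], p_slope = s[4, 4],
    se = s[, 2], interruption_week = interruption_week,
    end_week = end_week, n = nrow(df), data = df, rq_fit = fit),
    class = "segmented_rq")
}

# Accept an encounter log or a bare (week, time) frame.
as_its_frame <- function(records) {
  stopifnot(is.data.frame(records))
  if (all(c("week", "time") %in% names(records)))
    return(records[stats::complete.cases(records[c("week", "time")]),
                   c("week", "time")])
  if (all(c("triage_end", "iv_antibiotics_time") %in% names(records))) {
    keep <- !is.na(records$iv_antibiotics_time) & !is.na(records$triage_end)
    return(data.frame(
      week = records$triage_end[keep] / MINUTES_PER_WEEK,
      time = records$iv_antibiotics_time[keep] - records$triage_end[keep]))
  }
  stop("records must carry (week, time) or (triage_end, iv_antibiotics_time)")
}

#' @export
coef.segmented_rq <- function(object, ...) {
  c(level_pre = object$level_pre, slope_pre = object$slope_pre,
    level_change = object$level_change, slope_change = object$slope_change)
}

#' Predict from a segmented fit
#'
#' @param object a `segmented_rq`.
#' @param week weeks since series start (defaults to the observed weeks).
#' @param counterfactual if `TRUE`, extrapolate the pre-implementation
#'   trend only.
#' @param ... unused.
#' @return predicted times at the fitted quantile.
#' @export
predict.segmented_rq <- function(object, week = object$data$week,
                                 counterfactual = FALSE, ...) {
  base <- object$level_pre + object$slope_pre * week
  if (counterfactual) return(base)
  post <- week >= object$interruption_week
  base + post * (object$level_change +
                 object$slope_change * (week - object$interruption_week))
}

#' @export
fitted.segmented_rq <- function(object, ...) predict(object)

#' @export
residuals.segmented_rq <- function(object, ...)
  object$data$time - predict(object)

#' @export
print.segmented_rq <- function(x, ...) {
  cat(sprintf("Segmented quantile regression (tau = %.2f, n = %d)\n",
              x$quantile, x$n))
  cat(sprintf("  pre level %.1f min, pre trend %+.3f min/week\n",
              x$level_pre, x$slope_pre))
  cat(sprintf("  level change %+.1f min (p = %.3f), trend change %+.3f min/week (p = %.3f)\n",
              x$level_change, x$p_level, x$slope_change, x$p_slope))
  cat(sprintf("  at week %.1f: fitted %.1f min vs counterfactual %.1f min\n",
              x$end_week, x$fitted_end, x$counterfactual_end))
  invisible(x)
}

#' @export
summary.segmented_rq <- function(object, ...) {
  print(object)
  co <- coef(object)
  tab <- cbind(estimate = co, std.error = unname(object$se))
  print(round(tab, 4))
  invisible(tab)
}

#' Plot a segmented fit over weekly boxplots
#'
#' Weekly boxplots of the raw times, overlaid with the fitted pre and post
#' segments and the dashed counterfactual projection.
#'
#' @param x a `segmented_rq`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.segmented_rq <- function(x, ...) {
  df <- x$data
  wk <- floor(df$week)
  graphics::boxplot(df$time ~ wk, at = sort(unique(wk)) + 0.5,
                    xlim = range(df$week), outline = FALSE,
                    xlab = "week of study", ylab = "minutes",
                    col = "grey90", border = "grey55", xaxt = "n", ...)
  graphics::axis(1, at = pretty(df$week))
  pre_w <- seq(min(df$week), x$interruption_week, length.out = 50)
  post_w <- seq(x$interruption_week, max(df$week), length.out = 50)
  graphics::lines(pre_w, predict(x, pre_w), lwd = 2, col = "steelblue4")
  graphics::lines(post_w, predict(x, post_w), lwd = 2, col = "firebrick")
  graphics::lines(post_w, predict(x, post_w, counterfactual = TRUE),
                  lty = 2, lwd = 2, col = "steelblue4")
  graphics::abline(v = x$interruption_week, lty = 3)
  invisible(x)
}
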