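# Severity scale: larger is sicker.
CATEGORIES <- c("NON_URGENT", "PRIORITY", "EMERGENCY")

severity_rank <- function(category) {
  r <- match(category, CATEGORIES)
  if (anyNA(r)) stop("unknown triage category: ",
                     paste(unique(category[is.na(r)]), collapse = ", "))
  r
}

#' Log-normal parameters from a median and interquartile range
#'
#' Durations in the department (waits, triage, consultations, treatments) are
#' right-skewed and strictly positive, so they are modelled as log-normal.
#' The two parameters are recovered from the printed median and IQR by the
#' method of quantiles: `meanlog = log(median)` and
#' `sdlog = log(q3/q1) / (2 * qnorm(0.75))`.
#'
#' @param median,q1,q3 quantiles of the target distribution, in minutes.
#' @return list with `meanlog` and `sdlog`, usable with [stats::rlnorm()].
#' @export
lnorm_from_quantiles <- function(median, q1, q3) {
  stopifnot(q1 > 0, q1 <= median, median <= q3)
  list(meanlog = log(median), sdlog = log(q3 / q1) / (2 * stats::qnorm(0.75)))
}

# Draw n values from a duration spec list(median=, q1=, q3=).
draw_duration <- function(n, spec) {
  p <- lnorm_from_quantiles(spec$median, spec$q1, spec$q3)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

# Independent RNG streams per simulation sub-process, derived from one seed,
# so adding draws to one component does not perturb the others.
STREAMS <- c(arrivals = 1L, demographics = 2L, presentation = 3L,
             service = 4L, adherence = 5L, treatment = 6L)

stream_seed <- function(seed, stream) {
  id <- STREAMS[[stream]]
  as.integer((as.numeric(seed) * 7919 + id * 104729) %% 2147483629)
}

with_stream <- function(seed, stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Type-7 (linear interpolation) quantiles, the package-wide convention for
# medians and IQRs.
med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

MINUTES_PER_WEEK <- 7 * 24 * 60
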