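#' Danger-sign stage of the triage cascade
#'
#' Danger signs are shown first and short-circuit the cascade: the first
#' danger sign present (in the configured order) forces the emergency
#' category regardless of any score or vital sign.
#'
#' @param p a [triage_presentation()].
#' @param cfg a [cascade_config()].
#' @return a `triage_result` with category `"EMERGENCY"` and the triggering
#'   danger sign, or `NULL` if no danger sign is present.
#' @export
evaluate_danger_signs <- function(p, cfg) {
  validate_presentation(p, cfg)
  hit <- cfg$danger_signs[cfg$danger_signs %in% p$danger_signs]
  if (!length(hit)) return(NULL)
  triage_result("EMERGENCY", trigger = hit[1],
                ipsi_risk = NA_real_, risc_score = NA_integer_)
}

#' Logistic admission-risk score (IPSI stage)
#'
#' Inverse-logit of an intercept plus coefficient-weighted predictors: age,
#' temperature, respiratory rate, SpO2, and the presence of cough,
#' difficulty breathing, chest indrawing, lethargy, irritability and
#' diarrhea. Applied to children at or above the configured minimum age
#' (3 months in the shipped default). The score is *absent* (`NA`) -- not an
#' error -- when the child is too young or any required predictor is
#' missing or unknown, since skipped entries must not be imputed.
#'
#' @inheritParams evaluate_danger_signs
#' @return admission-risk probability in `[0, 1]`, or `NA` if not applicable.
#' @export
compute_ipsi <- function(p, cfg) {
  validate_presentation(p, cfg)
  ip <- cfg$ipsi
  if (p$age < ip$min_age_months) return(NA_real_)
  numeric_preds <- c(age = "age", temperature = "temperature",
                     respiratory_rate = "respiratory_rate", spo2 = "spo2")
  binary_preds <- c("cough", "difficulty_breathing", "chest_indrawing",
                    "lethargy", "irritability", "diarrhea")
  need <- c(names(numeric_preds), binary_preds)
  have <- names(ip$coefficients)
  miss <- setdiff(need, have)
  if (length(miss))
    stop("ipsi configuration missing coefficient for: ",
         paste(miss, collapse = ", "))
  lp <- ip$intercept
  for (nm in names(numeric_preds)) {
    v <- p[[numeric_preds[[nm]]]]
    if (is.null(v)) return(NA_real_)
    lp <- lp + ip$coefficients[[nm]] * v
  }
  for (nm in binary_preds) {
    st <- feature_state(p, nm)
    if (st == "unknown") return(NA_real_)
    lp <- lp + ip$coefficients[[nm]] * (st == "present")
  }
  stats::plogis(lp)
}

#' Additive respiratory-severity score (RISC stage)
#'
#' An integer point sum over configured conditions (low SpO2, chest
#' indrawing, wheezing, inability to drink or eat, low weight for age, HIV
#' status), applied to children under the configured maximum age (24 months
#' in the shipped default) who show at least one configured indication of a
#' lower respiratory chest infection. Returns `NA` when not applicable, and
#' also -- with the reason attached as attribute `"reason"` -- when a datum
#' a configured condition needs (weight, SpO2) is missing.
#'
#' @inheritParams evaluate_danger_signs
#' @return integer points, or `NA` if not applicable/computable.
#' @export
compute_risc <- function(p, cfg) {
  validate_presentation(p, cfg)
  rs <- cfg$risc
  if (p$age >= rs$max_age_months) return(NA_integer_)
  indicated <- any(vapply(rs$applicability_any_of,
                          function(id) feature_state(p, id) == "present",
                          logical(1)))
  if (!indicated) return(NA_integer_)
  pts <- 0L
  pd <- rs$points
  if (!is.null(pd$spo2_below)) {
    if (is.null(p$spo2))
      return(structure(NA_integer_, reason = "spo2 missing"))
    if (p$spo2 < pd$spo2_below$threshold)
      pts <- pts + as.integer(pd$spo2_below$points)
  }
  for (nm in c("chest_indrawing", "wheezing", "inability_to_drink_or_eat"))
    if (!is.null(pd[[nm]]) && feature_state(p, nm) == "present")
      pts <- pts + as.integer(pd[[nm]])
  if (!is.null(pd$low_weight)) {
    if (is.null(p$weight))
      return(structure(NA_integer_, reason = "weight missing"))
    b <- find_band(pd$low_weight, p$age)
    if (!is.null(b) && p$weight < b$weight_below)
      pts <- pts + as.integer(b$points)
  }
  if (!is.null(pd$hiv))
    pts <- pts + as.integer(pd$hiv[[p$hiv_status]] %||% 0L)
  pts
}

#' Single-vital-sign threshold stage
#'
#' Every configured age-banded cut-off breached by a *present* vital sign
#' yields one flag (the most severe one per vital); missing vitals yield no
#' flag. Cut-offs may be upper bounds (`*_above`, breached when the value
#' exceeds them) or lower bounds (`*_below`).
#'
#' @inheritParams evaluate_danger_signs
#' @return data frame with columns `vital` and `category` (one row per
#'   flagged vital; zero rows when nothing is breached).
#' @export
evaluate_vital_thresholds <- function(p, cfg) {
  validate_presentation(p, cfg)
  out <- list()
  for (vital in names(cfg$vital_thresholds)) {
    v <- p[[vital]]
    if (is.null(v)) next
    b <- find_band(cfg$vital_thresholds[[vital]], p$age)
    if (is.null(b)) next
    breach <- function(above, below)
      (!is.null(above) && v > above) || (!is.null(below) && v < below)
    cat_hit <- if (breach(b$emergency_above, b$emergency_below)) "EMERGENCY"
               else if (breach(b$priority_above, b$priority_below)) "PRIORITY"
               else NA_character_
    if (!is.na(cat_hit))
      out[[length(out) + 1L]] <- data.frame(vital = vital,
                                            category = cat_hit,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(vital = character(), category = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

triage_result <- function(category, trigger, ipsi_risk, risc_score) {
  structure(list(category = category, trigger = trigger,
                 ipsi_risk = ipsi_risk, risc_score = risc_score,
                 evaluated_at = Sys.time()),
            class = "triage_result")
}

#' Classify one child through the full triage cascade
#'
#' The cascade runs: danger signs (emergency, short-circuit), then the
#' logistic admission-risk score against its two probability thresholds,
#' then the respiratory-severity points against its two point thresholds,
#' then the single-vital-sign flags. Absent scores contribute nothing. The
#' final category is the maximum severity attained over the non-short-
#' circuited stages (conservative triage); `trigger` names the first stage,
#' in cascade order, that attained it, or `"default"` for a non-urgent
#' child no stage flagged.
#'
#' @inheritParams evaluate_danger_signs
#' @return a `triage_result` with fields `category`, `trigger`, `ipsi_risk`,
#'   `risc_score` and `evaluated_at`.
#' @export
classify <- function(p, cfg) {
  ds <- evaluate_danger_signs(p, cfg)
  ipsi <- compute_ipsi(p, cfg)
  risc <- compute_risc(p, cfg)
  if (!is.null(ds)) {
    ds$ipsi_risk <- ipsi
    ds$risc_score <- as.integer(risc)
    return(ds)
  }
  stage_cat <- character()
  stage_trig <- character()
  if (!is.na(ipsi)) {
    ip <- cfg$ipsi
    c1 <- if (ipsi >= ip$emergency_threshold) "EMERGENCY"
          else if (ipsi >= ip$priority_threshold) "PRIORITY"
          else NA_character_
    if (!is.na(c1)) { stage_cat <- c(stage_cat, c1)
                      stage_trig <- c(stage_trig, "ipsi") }
  }
  if (!is.na(risc)) {
    rs <- cfg$risc
    c2 <- if (risc >= rs$emergency_threshold) "EMERGENCY"
          else if (risc >= rs$priority_threshold) "PRIORITY"
          else NA_character_
    if (!is.na(c2)) { stage_cat <- c(stage_cat, c2)
                      stage_trig <- c(stage_trig, "risc") }
  }
  flags <- evaluate_vital_thresholds(p, cfg)
  if (nrow(flags)) {
    stage_cat <- c(stage_cat, flags$category)
    stage_trig <- c(stage_trig, flags$vital)
  }
  if (!length(stage_cat))
    return(triage_result("NON_URGENT", "default", ipsi, as.integer(risc)))
  best <- max(severity_rank(stage_cat))
  first <- which(severity_rank(stage_cat) == best)[1]
  triage_result(CATEGORIES[best], stage_trig[first], ipsi, as.integer(risc))
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("%s (trigger: %s)", x$category, x$trigger))
  extra <- character()
  if (!is.na(x$ipsi_risk))
    extra <- c(extra, sprintf("admission risk %.3f", x$ipsi_risk))
  if (!is.na(x$risc_score))
    extra <- c(extra, sprintf("respiratory severity %d", x$risc_score))
  if (length(extra)) cat("  [", paste(extra, collapse = "; "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Triage a table of children
#'
#' Vectorised front end for CSV workflows: each row of `data` describes one
#' child with columns named after [triage_presentation()] fields. Danger
#' signs are given in a `danger_signs` column as a `;`-separated list;
#' symptom and sign identifiers appear as their own columns with values
#' `present`/`absent`/`unknown` (or `1`/`0`/`NA`).
#'
#' @param data a data frame of presentations.
#' @param cfg a [cascade_config()].
#' @return `data` with appended columns `category`, `trigger`, `ipsi_risk`
#'   and `risc_score`.
#' @export
triage_table <- function(data, cfg) {
  stopifnot(is.data.frame(data))
  known <- c(cfg$symptoms, cfg$signs)
  n <- nrow(data)
  category <- trigger <- character(n)
  ipsi_risk <- numeric(n)
  risc_score <- integer(n)
  to_tern <- function(v) {
    if (is.numeric(v)) return(ifelse(is.na(v), "unknown",
                                     ifelse(v > 0, "present", "absent")))
    v <- as.character(v)
    ifelse(is.na(v) | v == "" | v == "unknown", "unknown", v)
  }
  num_or_null <- function(v) if (is.null(v) || is.na(v)) NULL else as.numeric(v)
  for (i in seq_len(n)) {
    row <- data[i, , drop = FALSE]
    sy <- intersect(names(row), cfg$symptoms)
    sg <- intersect(names(row), cfg$signs)
    ds <- row$danger_signs %||% ""
    ds <- if (is.na(ds) || ds == "") character() else
      trimws(strsplit(as.character(ds), ";", fixed = TRUE)[[1]])
    p <- triage_presentation(
      age = as.numeric(row$age),
      sex = if (is.null(row$sex) || is.na(row$sex)) "unknown" else as.character(row$sex),
      weight = num_or_null(row$weight), height = num_or_null(row$height),
      temperature = num_or_null(row$temperature),
      heart_rate = num_or_null(row$heart_rate),
      respiratory_rate = num_or_null(row$respiratory_rate),
      spo2 = num_or_null(row$spo2),
      danger_signs = ds,
      symptoms = stats::setNames(to_tern(unlist(row[sy])), sy),
      signs = stats::setNames(to_tern(unlist(row[sg])), sg),
      hiv_status = if (is.null(row$hiv_status) || is.na(row$hiv_status))
        "unknown" else as.character(row$hiv_status))
    res <- classify(p, cfg)
    category[i] <- res$category
    trigger[i] <- res$trigger
    ipsi_risk[i] <- res$ipsi_risk
    risc_score[i] <- res$risc_score
  }
  data$category <- category
  data$trigger <- trigger
  data$ipsi_risk <- ipsi_risk
  data$risc_score <- risc_score
  data
}
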