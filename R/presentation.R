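#' One child's presentation at triage
#'
#' Bundles the demographics, anthropometrics, vital signs, danger signs and
#' the symptom/sign answers collected at the triage desk. Symptom and sign
#' answers are ternary (`"present"`, `"absent"`, `"unknown"`); identifiers
#' not mentioned default to `"unknown"`, reflecting that nurses may skip
#' questions. Vitals may be missing (`NULL`/`NA`).
#'
#' @param age age in months; fractional values allowed.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param weight,height optional weight (kg) and height (cm).
#' @param temperature optional axillary temperature, degrees C.
#' @param heart_rate,respiratory_rate optional rates per minute.
#' @param spo2 optional oxygen saturation, integer percent in `[0, 100]`.
#' @param danger_signs character vector of danger-sign identifiers present.
#' @param symptoms,signs named character vectors with values
#'   `"present"`/`"absent"`/`"unknown"`.
#' @param hiv_status `"positive"`, `"negative"` or `"unknown"`.
#' @return an object of class `triage_presentation`.
#' @export
triage_presentation <- function(age, sex = "unknown", weight = NULL,
                                height = NULL, temperature = NULL,
                                heart_rate = NULL, respiratory_rate = NULL,
                                spo2 = NULL, danger_signs = character(),
                                symptoms = character(), signs = character(),
                                hiv_status = "unknown") {
  num1 <- function(v, what, positive = TRUE) {
    if (is.null(v) || (length(v) == 1 && is.na(v))) return(NULL)
    if (!is.numeric(v) || length(v) != 1) stop(what, " must be one number")
    if (positive && v <= 0) stop(what, " must be positive")
    as.numeric(v)
  }
  if (!is.numeric(age) || length(age) != 1 || is.na(age) || age < 0)
    stop("age must be a non-negative number of months")
  sex <- match.arg(sex, c("male", "female", "unknown"))
  hiv_status <- match.arg(hiv_status, c("positive", "negative", "unknown"))
  spo2 <- num1(spo2, "spo2", positive = FALSE)
  if (!is.null(spo2) && (spo2 < 0 || spo2 > 100))
    stop("spo2 must lie in [0, 100]")
  tern <- function(v, what) {
    v <- unlist(v)
    if (!length(v)) return(stats::setNames(character(), character()))
    if (is.null(names(v)) || any(names(v) == ""))
      stop(what, " must be a named vector")
    if (!all(v %in% c("present", "absent", "unknown")))
      stop(what, " values must be present/absent/unknown")
    v
  }
  structure(list(
    age = as.numeric(age), sex = sex,
    weight = num1(weight, "weight"), height = num1(height, "height"),
    temperature = num1(temperature, "temperature"),
    heart_rate = num1(heart_rate, "heart_rate"),
    respiratory_rate = num1(respiratory_rate, "respiratory_rate"),
    spo2 = spo2,
    danger_signs = as.character(danger_signs),
    symptoms = tern(symptoms, "symptoms"),
    signs = tern(signs, "signs"),
    hiv_status = hiv_status
  ), class = "triage_presentation")
}

#' Validate a presentation against a cascade configuration
#'
#' Rejects danger-sign, symptom or sign identifiers not declared in the
#' configuration, naming the offender.
#'
#' @param p a [triage_presentation()].
#' @param cfg a [cascade_config()].
#' @return `p`, invisibly.
#' @export
validate_presentation <- function(p, cfg) {
  stopifnot(inherits(p, "triage_presentation"),
            inherits(cfg, "cascade_config"))
  bad <- setdiff(p$danger_signs, cfg$danger_signs)
  if (length(bad))
    stop("unknown danger-sign identifier: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(p$symptoms), cfg$symptoms)
  if (length(bad))
    stop("unknown symptom identifier: ", paste(bad, collapse = ", "))
  bad <- setdiff(names(p$signs), cfg$signs)
  if (length(bad))
    stop("unknown sign identifier: ", paste(bad, collapse = ", "))
  invisible(p)
}

# Ternary lookup over the symptom and sign maps; unmentioned ids: unknown.
feature_state <- function(p, id) {
  if (id %in% names(p$symptoms)) return(unname(p$symptoms[[id]]))
  if (id %in% names(p$signs)) return(unname(p$signs[[id]]))
  "unknown"
}

#' @export
print.triage_presentation <- function(x, ...) {
  cat(sprintf("Child at triage: %.1f months, %s\n", x$age, x$sex))
  vit <- c(temperature = x$temperature, heart_rate = x$heart_rate,
           respiratory_rate = x$respiratory_rate, spo2 = x$spo2)
  if (length(vit))
    cat("  vitals:", paste(names(vit), round(unlist(vit), 1), sep = "=",
                           collapse = ", "), "\n")
  if (length(x$danger_signs))
    cat("  danger signs:", paste(x$danger_signs, collapse = ", "), "\n")
  pres <- c(names(x$symptoms)[x$symptoms == "present"],
            names(x$signs)[x$signs == "present"])
  if (length(pres)) cat("  present:", paste(pres, collapse = ", "), "\n")
  invisible(x)
}
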