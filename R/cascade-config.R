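#' Triage cascade configuration
#'
#' A `cascade_config` object holds everything the triage cascade needs as
#' data: the ordered danger-sign list, the declared symptom and sign
#' vocabularies, the logistic admission-risk (IPSI) model coefficients and
#' its two probability thresholds, the additive respiratory-severity (RISC)
#' point table with its applicability rule and two point thresholds, and the
#' age-banded single-vital-sign cut-offs. Nothing numeric about the cascade
#' is hard-coded in the package: the shipped default is an explicitly
#' labelled *reconstructed* configuration in
#' `system.file("extdata", "cascade-default.yaml", package = "triageflow")`.
#'
#' @param x a list with the fields of the YAML schema (see the shipped
#'   default for the layout).
#' @return a validated object of class `cascade_config`.
#' @seealso [read_cascade_config()], [default_cascade_config()], [classify()]
#' @export
cascade_config <- function(x) {
  cfg <- structure(x, class = "cascade_config")
  validate_cascade_config(cfg)
  cfg
}

#' Read / write a cascade configuration
#'
#' Configurations are stored as YAML (or JSON, which YAML parsers accept)
#' with a `schema_version` field.
#'
#' @param path file path.
#' @return `read_cascade_config` returns a validated [cascade_config()];
#'   `write_cascade_config` writes `cfg` and returns `path` invisibly.
#' @export
read_cascade_config <- function(path) {
  if (!file.exists(path)) stop("cascade config not found: ", path)
  cascade_config(yaml::read_yaml(path))
}

#' @rdname read_cascade_config
#' @param cfg a [cascade_config()].
#' @export
write_cascade_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cascade_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname read_cascade_config
#' @export
default_cascade_config <- function() {
  read_cascade_config(system.file("extdata", "cascade-default.yaml",
                                  package = "triageflow", mustWork = TRUE))
}

#' Validate a cascade configuration
#'
#' Checks the structural invariants: emergency thresholds at least as high
#' as priority thresholds, thresholds inside the codomain of their score,
#' and vital-sign age bands that start at 0, are contiguous (closed below,
#' open above) and end unbounded. Overlapping or gapped bands are
#' configuration errors.
#'
#' @param cfg a `cascade_config`.
#' @return `cfg`, invisibly; errors describe the offending field.
#' @export
validate_cascade_config <- function(cfg) {
  need <- c("schema_version", "danger_signs", "symptoms", "signs",
            "ipsi", "risc", "vital_thresholds")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("cascade config missing fields: ",
                         paste(miss, collapse = ", "))
  ip <- cfg$ipsi
  if (!is.numeric(ip$min_age_months) || ip$min_age_months < 0)
    stop("ipsi$min_age_months must be a non-negative number")
  if (ip$priority_threshold < 0 || ip$emergency_threshold > 1)
    stop("ipsi thresholds must lie in [0, 1]")
  if (ip$emergency_threshold < ip$priority_threshold)
    stop("ipsi$emergency_threshold must be >= ipsi$priority_threshold")
  if (is.null(ip$intercept) || !is.numeric(ip$intercept))
    stop("ipsi$intercept is required")
  rs <- cfg$risc
  if (rs$emergency_threshold < rs$priority_threshold)
    stop("risc$emergency_threshold must be >= risc$priority_threshold")
  if (rs$priority_threshold < 0)
    stop("risc thresholds must be non-negative points")
  if (!is.numeric(rs$max_age_months) || rs$max_age_months <= 0)
    stop("risc$max_age_months must be a positive number")
  bad <- setdiff(rs$applicability_any_of, c(cfg$symptoms, cfg$signs))
  if (length(bad))
    stop("risc applicability refers to undeclared identifiers: ",
         paste(bad, collapse = ", "))
  for (vital in names(cfg$vital_thresholds))
    check_bands(cfg$vital_thresholds[[vital]], vital)
  lw <- rs$points$low_weight
  if (!is.null(lw)) check_bands(lw, "risc low_weight")
  invisible(cfg)
}

# Age bands must tile [0, Inf): closed below, open above, no overlap, no gap.
check_bands <- function(bands, what) {
  lo <- vapply(bands, function(b) as.numeric(b$age_min), numeric(1))
  hi <- vapply(bands, function(b) as.numeric(b$age_max), numeric(1))
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  if (lo[1] != 0)
    stop("age bands for ", what, " must start at 0")
  if (any(hi <= lo))
    stop("age bands for ", what, " must have age_max > age_min")
  if (length(lo) > 1 && any(abs(lo[-1] - hi[-length(hi)]) > 1e-9))
    stop("age bands for ", what, " overlap or leave a gap")
  invisible(TRUE)
}

# Locate the age band covering `age`; bands validated as contiguous.
find_band <- function(bands, age) {
  for (b in bands)
    if (age >= b$age_min && age < b$age_max) return(b)
  NULL
}

#' @export
print.cascade_config <- function(x, ...) {
  cat("Triage cascade configuration (schema", x$schema_version, ")\n")
  if (!is.null(x$provenance)) cat("  provenance:", x$provenance, "\n")
  cat("  danger signs (", length(x$danger_signs), "): ",
      paste(x$danger_signs, collapse = ", "), "\n", sep = "")
  cat(sprintf("  IPSI: age >= %s mo, priority >= %.2f, emergency >= %.2f\n",
              x$ipsi$min_age_months, x$ipsi$priority_threshold,
              x$ipsi$emergency_threshold))
  cat(sprintf("  RISC: age < %s mo, priority >= %d, emergency >= %d points\n",
              x$risc$max_age_months, as.integer(x$risc$priority_threshold),
              as.integer(x$risc$emergency_threshold)))
  cat("  vitals with thresholds:",
      paste(names(x$vital_thresholds), collapse = ", "), "\n")
  invisible(x)
}
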