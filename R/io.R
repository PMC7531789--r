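#' Column alias table for encounter-log CSVs
#'
#' Encounter logs arrive with varying headers; this table maps the
#' canonical field names to the spellings seen in exported data. Extend it
#' by passing a modified copy to [read_event_log()].
#'
#' @return named list: canonical field -> accepted header spellings.
#' @export
default_alias_table <- function() {
  list(
    patient_id = c("patient_id", "patient", "id", "study_id"),
    phase = c("phase", "period", "implementation_phase"),
    category = c("category", "triage_category", "triage", "priority_level"),
    registration_time = c("registration_time", "registration", "reg_time",
                          "arrival_time", "arrival"),
    triage_start = c("triage_start", "triage_start_time"),
    triage_end = c("triage_end", "triage_end_time", "triage_time",
                   "end_of_triage"),
    seen_time = c("seen_time", "seen", "consultation_start", "first_contact"),
    iv_fluids_time = c("iv_fluids_time", "ivf_time", "fluids_time"),
    iv_antibiotics_time = c("iv_antibiotics_time", "iva_time",
                            "antibiotics_time", "antibiotic_time"),
    age = c("age", "age_months", "age_mos"),
    weight = c("weight", "weight_kg"),
    height = c("height", "height_cm"),
    sex = c("sex", "gender"),
    district = c("district", "geographical_district"))
}

TIME_FIELDS <- c("registration_time", "triage_start", "triage_end",
                 "seen_time", "iv_fluids_time", "iv_antibiotics_time")

#' Read an encounter-log CSV
#'
#' Reads a comma-separated, headered event log and maps its columns onto
#' the canonical encounter-record fields through the alias table. Timestamp
#' columns may hold minutes from the study origin (numeric) or ISO-8601
#' local clock times, which are converted to minutes from `origin`
#' (defaulting to midnight before the earliest timestamp). Unparseable
#' timestamps become `NA` and are tallied per column in the parse report;
#' rows are never silently repaired -- in particular, antibiotic times
#' before triage times load verbatim, since filtering is the evaluation
#' pipeline's job. Unrecognised columns are preserved untouched.
#'
#' @param path CSV path.
#' @param aliases alias table as from [default_alias_table()].
#' @param origin optional `POSIXct` origin for ISO timestamps.
#' @return list with `records` (class `encounter_log`), `report` (class
#'   `parse_report`: per-column unparseable counts) and `origin`.
#' @export
read_event_log <- function(path, aliases = default_alias_table(),
                           origin = NULL) {
  if (!file.exists(path)) stop("event log not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  hdr <- names(raw)
  mapped <- character()
  for (canon in names(aliases)) {
    hit <- hdr[tolower(hdr) %in% tolower(aliases[[canon]])]
    if (length(hit)) {
      names(raw)[names(raw) == hit[1]] <- canon
      mapped <- c(mapped, canon)
    }
  }
  if (!"patient_id" %in% mapped)
    stop("mandatory identifier column missing: patient_id ",
         "(accepted spellings: ",
         paste(aliases$patient_id, collapse = ", "), ")")
  bad_counts <- stats::setNames(integer(length(TIME_FIELDS)), TIME_FIELDS)
  iso_vals <- list()
  for (f in intersect(TIME_FIELDS, names(raw))) {
    parsed <- parse_time_column(raw[[f]])
    bad_counts[f] <- parsed$n_bad
    iso_vals[[f]] <- parsed
  }
  needs_origin <- any(vapply(iso_vals, function(p) p$kind == "iso", logical(1)))
  if (needs_origin && is.null(origin)) {
    earliest <- suppressWarnings(min(do.call(
      c, lapply(iso_vals[vapply(iso_vals, function(p) p$kind == "iso",
                                logical(1))],
                function(p) p$posix)), na.rm = TRUE))
    origin <- as.POSIXct(trunc(earliest, "days"))
  }
  for (f in names(iso_vals)) {
    p <- iso_vals[[f]]
    raw[[f]] <- if (p$kind == "iso")
      as.numeric(difftime(p$posix, origin, units = "mins"))
    else p$minutes
  }
  class(raw) <- c("encounter_log", "data.frame")
  list(records = raw,
       report = structure(list(n_rows = nrow(raw),
                               n_unparseable = bad_counts,
                               mapped_fields = mapped),
                          class = "parse_report"),
       origin = origin)
}

parse_time_column <- function(x) {
  if (is.numeric(x))
    return(list(kind = "minutes", minutes = as.numeric(x), n_bad = 0L))
  x <- as.character(x)
  empty <- is.na(x) | trimws(x) == ""
  num <- suppressWarnings(as.numeric(x))
  if (all(empty | !is.na(num)))
    return(list(kind = "minutes", minutes = num, n_bad = 0L))
  # element-wise over the accepted layouts: one bad cell must not poison
  # the others
  posix <- as.POSIXct(rep(NA_character_, length(x)))
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M")) {
    todo <- is.na(posix) & !empty
    if (!any(todo)) break
    posix[todo] <- as.POSIXct(strptime(x[todo], fmt))
  }
  list(kind = "iso", posix = posix, n_bad = sum(is.na(posix) & !empty))
}

#' @export
print.parse_report <- function(x, ...) {
  cat("Parsed", x$n_rows, "rows; mapped fields:",
      paste(x$mapped_fields, collapse = ", "), "\n")
  bad <- x$n_unparseable[x$n_unparseable > 0]
  if (length(bad))
    cat("  unparseable timestamps:",
        paste(names(bad), bad, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @rdname read_event_log
#' @param records an encounter log.
#' @export
write_event_log <- function(records, path) {
  stopifnot(is.data.frame(records))
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline run records what produced its outputs: package version,
#' seed, input-file digests, configuration digests, and wall-clock times.
#'
#' @param path output JSON path.
#' @param inputs character vector of input file paths (digested with MD5).
#' @param configs named list of configuration objects (digested after YAML
#'   serialisation).
#' @param seed the seed used, if any.
#' @param started `POSIXct` start time.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, inputs = character(),
                               configs = list(), seed = NULL,
                               started = Sys.time()) {
  digest_cfg <- function(cfg) {
    f <- tempfile(fileext = ".yaml")
    on.exit(unlink(f))
    yaml::write_yaml(unclass(cfg), f)
    unname(tools::md5sum(f))
  }
  manifest <- list(
    package = "triageflow",
    version = as.character(utils::packageVersion("triageflow")),
    seed = seed,
    inputs = if (length(inputs))
      as.list(stats::setNames(unname(tools::md5sum(inputs)), inputs))
    else NULL,
    configs = if (length(configs)) lapply(configs, digest_cfg) else NULL,
    started = format(started, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
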