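#' Simulate the outpatient department
#'
#' Discrete-event simulation of one phase. Every child passes registration
#' (arrival), a registration-to-triage wait, a triage of random duration,
#' and then competes for the consultation rooms:
#'
#' * `discipline = "fcfs"` -- the pre-implementation department: whenever a
#'   room frees, the waiting child with the earliest triage completion is
#'   seen, whatever the category.
#' * `discipline = "triage_priority"` -- the dashboard department: whenever
#'   a room frees, staff consult the dashboard with probability
#'   `adherence[category]` of the child at the *top* of the
#'   severity-then-triage-time ordering. If the dashboard is followed and
#'   the top child is an emergency, that child bypasses consultation and is
#'   transferred straight to the treatment room (the freed room then takes
#'   the next decision); a followed priority child takes the room ahead of
#'   earlier arrivals. If the dashboard is ignored, the room reverts to
#'   first-come-first-served. Adherence is therefore drawn per service
#'   decision, which is what the downstream adherence metric can actually
#'   observe; with all adherence probabilities zero the two disciplines
#'   produce identical service orders.
#'
#' Rooms serve one child at a time and never idle while someone is waiting.
#' Consultation service times are drawn per child before queueing, so the
#' same population under the two disciplines differs only in ordering.
#'
#' @param pop a [generate_population()] result.
#' @param cfg the [simulation_config()] used to generate it.
#' @param discipline `"fcfs"` or `"triage_priority"`.
#' @return an encounter log `data.frame` (class `encounter_log`), one row
#'   per child, with the timestamp trail in minutes from the simulation
#'   origin: `registration_time`, `triage_start`, `triage_end`, `seen_time`,
#'   `consult_end` (`NA` for emergency bypasses), treatment columns left
#'   `NA` for [assign_treatments()], and a `bypassed` flag.
#' @export
simulate_department <- function(pop, cfg, discipline = c("fcfs", "triage_priority")) {
  stopifnot(inherits(pop, "triage_population"))
  validate_simulation_config(cfg)
  if (!is.character(discipline) ||
      !all(discipline %in% c("fcfs", "triage_priority")))
    stop("unknown queue discipline: ", paste(discipline, collapse = ", "))
  discipline <- match.arg(discipline)
  d <- pop$data
  n <- nrow(d)
  draws <- with_stream(cfg$seed, "service", list(
    wait = draw_duration(n, cfg$wait_to_triage),
    triage = draw_duration(n, cfg$triage_duration),
    consult = draw_duration(n, cfg$consultation_time),
    treat = draw_duration(n, cfg$treatment_time),
    delay = draw_duration(n, cfg$iva_delay)))
  triage_start <- d$arrival_min + draws$wait
  triage_end <- triage_start + draws$triage
  res <- with_stream(cfg$seed, "adherence",
    run_consultation(triage_end, severity_rank(d$category), draws$consult,
                     cfg$n_consult_rooms, discipline, cfg$adherence))
  out <- data.frame(
    patient_id = d$patient_id, phase = rep(pop$phase, length.out = n),
    category = d$category,
    registration_time = d$arrival_min, triage_start = triage_start,
    triage_end = triage_end, seen_time = res$seen,
    consult_end = res$consult_end,
    iv_fluids_time = rep(NA_real_, n), iv_antibiotics_time = rep(NA_real_, n),
    age = d$age, weight = d$weight, height = d$height, sex = d$sex,
    district = d$district, bypassed = res$bypassed,
    stringsAsFactors = FALSE)
  attr(out, "sim_draws") <- draws
  class(out) <- c("encounter_log", "data.frame")
  out
}

# Event loop for the consultation stage. Severity rank: 3 = emergency.
run_consultation <- function(ready, sev, service, n_servers, discipline,
                             adherence) {
  n <- length(ready)
  seen <- consult_end <- rep(NA_real_, n)
  bypassed <- rep(FALSE, n)
  if (n == 0)
    return(list(seen = seen, consult_end = consult_end, bypassed = bypassed))
  waiting <- rep(FALSE, n)   # triaged, not yet seen
  done <- rep(FALSE, n)
  free <- rep(0, n_servers)  # per-room next-free times
  arrival_order <- order(ready)
  next_arrival <- 1L
  adh <- adherence[CATEGORIES]  # index by severity rank
  repeat {
    s <- which.min(free)
    t <- free[s]
    # admit everyone triaged by t into the waiting set
    while (next_arrival <= n && ready[arrival_order[next_arrival]] <= t) {
      waiting[arrival_order[next_arrival]] <- TRUE
      next_arrival <- next_arrival + 1L
    }
    if (!any(waiting)) {
      if (next_arrival > n) break
      free[s] <- ready[arrival_order[next_arrival]]
      next
    }
    w <- which(waiting)
    follow_dashboard <- FALSE
    if (discipline == "triage_priority") {
      # transfer dashboard-followed emergencies before the room decision
      repeat {
        w <- which(waiting)
        if (!length(w)) break
        top <- w[order(-sev[w], ready[w], w)][1]
        if (sev[top] != 3L || stats::runif(1) > adh[3L]) break
        seen[top] <- t
        bypassed[top] <- TRUE
        waiting[top] <- FALSE
        done[top] <- TRUE
      }
      w <- which(waiting)
      if (!length(w)) next
      top <- w[order(-sev[w], ready[w], w)][1]
      follow_dashboard <- sev[top] == 3L ||
        stats::runif(1) <= adh[sev[top]]
      pick <- if (follow_dashboard && sev[top] != 3L) top
              else w[order(ready[w], w)][1]
    } else {
      pick <- w[order(ready[w], w)][1]
    }
    seen[pick] <- t
    consult_end[pick] <- t + service[pick]
    free[s] <- consult_end[pick]
    waiting[pick] <- FALSE
    done[pick] <- TRUE
  }
  list(seen = seen, consult_end = consult_end, bypassed = bypassed)
}

#' Assign treatments and simulate the treatment room
#'
#' Each child independently receives intravenous antibiotics with the
#' per-category, per-phase probability from the configuration. The
#' treatment room serves, one child at a time: every emergency bypass
#' (ready on transfer) and every antibiotic recipient from the consultation
#' stream (ready after consultation); both incur the order-to-administration
#' delay (cannulation, drug preparation) before treatment can start.
#' Emergencies take non-preemptive priority in the treatment queue. The
#' antibiotic timestamp is the treatment start; a configured fraction of
#' recipients also receives intravenous fluids at the same time. Bypassed
#' emergencies' `seen_time` is their transfer into the treatment room.
#'
#' @param records an `encounter_log` from [simulate_department()].
#' @param cfg the matching [simulation_config()].
#' @return the records with `iv_antibiotics_time`/`iv_fluids_time` filled.
#' @export
assign_treatments <- function(records, cfg) {
  stopifnot(inherits(records, "encounter_log"))
  n <- nrow(records)
  if (n == 0) return(records)
  draws <- attr(records, "sim_draws")
  if (is.null(draws))
    draws <- with_stream(cfg$seed, "service", list(
      treat = draw_duration(n, cfg$treatment_time),
      delay = draw_duration(n, cfg$iva_delay)))
  iva <- with_stream(cfg$seed, "treatment", {
    p <- cfg$iva_probability[records$category]
    gets_iva <- stats::runif(n) < p
    fluids <- stats::runif(n) < cfg$fluids_fraction
    list(gets_iva = gets_iva, fluids = fluids)
  })
  enters <- records$bypassed | iva$gets_iva
  # the order-to-administration delay (cannulation, drug preparation)
  # applies on arrival in the treatment room, bypassed or not
  ready <- ifelse(records$bypassed, records$seen_time,
                  records$consult_end) + draws$delay
  idx <- which(enters & !is.na(ready))
  if (length(idx)) {
    key_sev <- ifelse(records$category[idx] == "EMERGENCY", 3L, 1L)
    srv <- serve_fifo(ready[idx], key_sev, draws$treat[idx],
                      cfg$n_treatment_rooms)
    treat_start <- rep(NA_real_, n)
    treat_start[idx] <- srv$start
    got <- iva$gets_iva & !is.na(treat_start)
    records$iv_antibiotics_time[got] <- treat_start[got]
    records$iv_fluids_time[got & iva$fluids] <- treat_start[got & iva$fluids]
  }
  records
}

# Multi-server non-preemptive priority queue (higher key_sev first, then
# earlier ready time); returns service start times.
serve_fifo <- function(ready, key_sev, service, n_servers) {
  n <- length(ready)
  start <- rep(NA_real_, n)
  waiting <- rep(FALSE, n)
  free <- rep(0, n_servers)
  ao <- order(ready)
  nxt <- 1L
  served <- 0L
  while (served < n) {
    s <- which.min(free)
    t <- free[s]
    while (nxt <= n && ready[ao[nxt]] <= t) {
      waiting[ao[nxt]] <- TRUE
      nxt <- nxt + 1L
    }
    if (!any(waiting)) {
      free[s] <- ready[ao[nxt]]
      next
    }
    w <- which(waiting)
    pick <- w[order(-key_sev[w], ready[w], w)][1]
    start[pick] <- t
    free[s] <- t + service[pick]
    waiting[pick] <- FALSE
    served <- served + 1L
  }
  list(start = start)
}

#' Run one phase end to end
#'
#' Convenience wrapper: population, department, treatments.
#'
#' @inheritParams generate_population
#' @inheritParams simulate_department
#' @return an `encounter_log` with treatments assigned.
#' @export
simulate_phase <- function(cfg, discipline = if (cfg$phase == "pre") "fcfs"
                           else "triage_priority",
                           cascade = default_cascade_config()) {
  pop <- generate_population(cfg, cascade)
  rec <- simulate_department(pop, cfg, discipline)
  assign_treatments(rec, cfg)
}
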