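#' Generate a synthetic patient population
#'
#' Draws arrivals from a non-homogeneous Poisson process over the horizon
#' (hourly profile scaled to the configured expected volume), demographics
#' matching the observed cohort summaries (age median about 24 months with
#' IQR about 9--53, roughly 55% male, weight/height grown from age with
#' noise, district frequencies from the registration table), and a clinical
#' presentation *constructed per intended category* so that [classify()]
#' under the given cascade reproduces the configured category mix up to
#' sampling error: emergency children carry a danger sign, priority
#' children breach one priority-level vital threshold, non-urgent children
#' stay below every trigger. Each construction is verified by running the
#' cascade and redrawn on the rare mismatch.
#'
#' Everything is reproducible under `cfg$seed`; arrivals, demographics and
#' presentations consume independent RNG streams.
#'
#' @param cfg a [simulation_config()].
#' @param cascade a [cascade_config()]; the shipped default when omitted.
#' @return an object of class `triage_population`: a list with `data` (one
#'   row per child: `patient_id`, `arrival_min`, demographics, `category`,
#'   `trigger`) and `presentations` (list of [triage_presentation()]).
#' @export
generate_population <- function(cfg, cascade = default_cascade_config()) {
  validate_simulation_config(cfg)
  horizon_min <- cfg$horizon_weeks * MINUTES_PER_WEEK
  arrival_min <- with_stream(cfg$seed, "arrivals",
                             draw_arrivals(cfg, horizon_min))
  n <- length(arrival_min)
  if (n == 0) {
    return(structure(list(
      data = data.frame(patient_id = character(), arrival_min = numeric(),
                        age = numeric(), sex = character(),
                        weight = numeric(), height = numeric(),
                        district = character(), category = character(),
                        trigger = character(), stringsAsFactors = FALSE),
      presentations = list(), phase = cfg$phase), class = "triage_population"))
  }
  demo <- with_stream(cfg$seed, "demographics", draw_demographics(n))
  pres <- vector("list", n)
  trigger <- character(n)
  intended <- character(n)
  with_stream(cfg$seed, "presentation", {
    intended <- sample(names(cfg$category_mix), n, replace = TRUE,
                       prob = cfg$category_mix)
    for (i in seq_len(n)) {
      for (try in 1:25) {
        p <- construct_presentation(intended[i], demo$age[i], demo$sex[i],
                                    demo$weight[i], demo$height[i], cascade)
        res <- classify(p, cascade)
        if (res$category == intended[i]) break
      }
      if (res$category != intended[i])
        stop("could not construct a ", intended[i], " presentation (age ",
             round(demo$age[i], 1), " months)")
      pres[[i]] <- p
      trigger[i] <- res$trigger
    }
  })
  structure(list(
    data = data.frame(
      patient_id = sprintf("%s-%05d", cfg$phase, seq_len(n)),
      arrival_min = arrival_min, age = demo$age, sex = demo$sex,
      weight = demo$weight, height = demo$height, district = demo$district,
      category = intended, trigger = trigger, stringsAsFactors = FALSE),
    presentations = pres, phase = cfg$phase), class = "triage_population")
}

# Thinned non-homogeneous Poisson arrivals over the horizon.
draw_arrivals <- function(cfg, horizon_min) {
  if (horizon_min <= 0 || cfg$n_arrivals <= 0) return(numeric())
  w <- cfg$hourly_profile / mean(cfg$hourly_profile)
  rate_day <- cfg$n_arrivals / (cfg$horizon_weeks * 7)       # per day
  lambda_max <- rate_day / (24 * 60) * max(w)
  n_cand <- stats::rpois(1, lambda_max * horizon_min)
  t_cand <- sort(stats::runif(n_cand, 0, horizon_min))
  hour <- floor((t_cand %% (24 * 60)) / 60) + 1
  keep <- stats::runif(n_cand) < w[hour] / max(w)
  t_cand[keep]
}

draw_demographics <- function(n) {
  # Age: log-normal matched to median 24 months, IQR 9.4--53.
  ap <- lnorm_from_quantiles(24, 9.4, 53)
  age <- pmin(pmax(stats::rlnorm(n, ap$meanlog, ap$sdlog), 0.25), 192)
  sex <- ifelse(stats::runif(n) < 0.55, "male", "female")
  # Median growth curves with multiplicative noise.
  wmed <- ifelse(age < 12, 3.3 + 0.55 * age, 9.9 + 0.2 * (age - 12))
  weight <- pmax(wmed * exp(stats::rnorm(n, 0, 0.15)), 1.5)
  hmed <- 87 * (pmax(age, 1) / 24)^0.35
  height <- pmax(hmed * exp(stats::rnorm(n, 0, 0.05)), 35)
  districts <- c("Mbarara", "Isingiro", "Kiruhura", "Ntungamo", "Bushenyi",
                 "Missing", "Other")
  dprob <- c(0.59, 0.12, 0.08, 0.05, 0.035, 0.0125, 0.1125)
  district <- sample(districts, n, replace = TRUE, prob = dprob / sum(dprob))
  list(age = age, sex = sex, weight = weight, height = height,
       district = district)
}

# Build one presentation intended to classify as `category` under `cascade`.
construct_presentation <- function(category, age, sex, weight, height,
                                   cascade) {
  rr_band <- find_band(cascade$vital_thresholds$respiratory_rate, age)
  hr_band <- find_band(cascade$vital_thresholds$heart_rate, age)
  spo2_band <- find_band(cascade$vital_thresholds$spo2, age)
  benign <- list(
    temperature = min(stats::rnorm(1, 37.2, 0.5), 39.2),
    respiratory_rate = stats::runif(1, 0.55, 0.85) * rr_band$priority_above,
    heart_rate = stats::runif(1, 0.55, 0.85) * hr_band$priority_above,
    spo2 = round(stats::runif(1, spo2_band$priority_below + 2, 99)))
  symptoms <- stats::setNames(rep("absent", length(cascade$symptoms)),
                              cascade$symptoms)
  symptoms["cough"] <- ifelse(stats::runif(1) < 0.30, "present", "absent")
  symptoms["diarrhea"] <- ifelse(stats::runif(1) < 0.15, "present", "absent")
  symptoms["fever_history"] <- ifelse(stats::runif(1) < 0.35, "present", "absent")
  symptoms["vomiting"] <- ifelse(stats::runif(1) < 0.10, "present", "absent")
  signs <- stats::setNames(rep("absent", length(cascade$signs)),
                           cascade$signs)
  hiv <- sample(c("negative", "unknown", "positive"), 1,
                prob = c(0.90, 0.07, 0.03))
  danger <- character()
  if (category == "EMERGENCY") {
    danger <- sample(cascade$danger_signs, 1)
  } else if (category == "PRIORITY") {
    pick <- sample(c("temperature", "respiratory_rate", "spo2"), 1,
                   prob = c(0.5, 0.3, 0.2))
    if (pick == "temperature") {
      b <- find_band(cascade$vital_thresholds$temperature, age)
      benign$temperature <- stats::runif(1, b$priority_above + 0.1,
                                         b$priority_above + 1.0)
    } else if (pick == "respiratory_rate") {
      lo <- rr_band$priority_above
      hi <- (rr_band$emergency_above %||% (lo * 1.3))
      benign$respiratory_rate <- stats::runif(1, lo + 1, hi - 1)
    } else {
      benign$spo2 <- round(stats::runif(1, spo2_band$emergency_below + 0.5,
                                        spo2_band$priority_below - 0.5))
    }
  }
  triage_presentation(age = age, sex = sex, weight = weight, height = height,
                      temperature = benign$temperature,
                      heart_rate = benign$heart_rate,
                      respiratory_rate = benign$respiratory_rate,
                      spo2 = benign$spo2, danger_signs = danger,
                      symptoms = symptoms, signs = signs, hiv_status = hiv)
}

#' @export
print.triage_population <- function(x, ...) {
  cat(sprintf("Synthetic population (%s phase): %d children\n",
              x$phase, nrow(x$data)))
  if (nrow(x$data)) print(table(x$data$category))
  invisible(x)
}
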