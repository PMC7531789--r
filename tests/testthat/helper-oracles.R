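# Shared fixtures and independent oracles.

# A minimal cascade used where hand-computation must stay tractable.
tiny_cascade <- function(danger = c("unconscious", "convulsing", "shock")) {
  cascade_config(list(
    schema_version = 1,
    danger_signs = danger,
    symptoms = c("cough", "difficulty_breathing", "diarrhea",
                 "inability_to_drink_or_eat", "wheezing"),
    signs = c("chest_indrawing", "lethargy", "irritability"),
    ipsi = list(min_age_months = 3, priority_threshold = 0.3,
                emergency_threshold = 0.7, intercept = -3,
                coefficients = list(age = -0.01, temperature = 0.1,
                                    respiratory_rate = 0.02, spo2 = -0.03,
                                    cough = 0.5, difficulty_breathing = 0.6,
                                    chest_indrawing = 0.7, lethargy = 0.8,
                                    irritability = 0.4, diarrhea = 0.3)),
    risc = list(max_age_months = 24, priority_threshold = 2,
                emergency_threshold = 4,
                applicability_any_of = c("cough", "wheezing",
                                         "chest_indrawing"),
                points = list(
                  spo2_below = list(threshold = 90, points = 3),
                  chest_indrawing = 2, wheezing = 1,
                  inability_to_drink_or_eat = 1,
                  low_weight = list(
                    list(age_min = 0, age_max = 12, weight_below = 4,
                         points = 2),
                    list(age_min = 12, age_max = Inf, weight_below = 7,
                         points = 2)),
                  hiv = list(positive = 2, unknown = 1, negative = 0))),
    vital_thresholds = list(
      spo2 = list(list(age_min = 0, age_max = Inf,
                       emergency_below = 85, priority_below = 92)),
      respiratory_rate = list(
        list(age_min = 0, age_max = 12, emergency_above = 70,
             priority_above = 55),
        list(age_min = 12, age_max = Inf, emergency_above = 60,
             priority_above = 45)),
      temperature = list(list(age_min = 0, age_max = Inf,
                              emergency_below = 35, priority_above = 39.5)))))
}

# Random presentation drawn wide enough to hit every cascade stage,
# including missing vitals and unknown answers.
rand_presentation <- function(cfg) {
  maybe <- function(x, p_missing = 0.15) if (runif(1) < p_missing) NULL else x
  tern <- function(n) sample(c("present", "absent", "unknown"), n,
                             replace = TRUE, prob = c(0.25, 0.6, 0.15))
  ds <- if (runif(1) < 0.1)
    sample(cfg$danger_signs, sample(1:2, 1)) else character()
  triage_presentation(
    age = stats::rlnorm(1, log(20), 1),
    sex = sample(c("male", "female", "unknown"), 1),
    weight = maybe(runif(1, 2, 30)),
    temperature = maybe(runif(1, 34.5, 41)),
    heart_rate = maybe(runif(1, 80, 210)),
    respiratory_rate = maybe(runif(1, 15, 80)),
    spo2 = maybe(round(runif(1, 80, 100))),
    danger_signs = ds,
    symptoms = stats::setNames(tern(length(cfg$symptoms)), cfg$symptoms),
    signs = stats::setNames(tern(length(cfg$signs)), cfg$signs),
    hiv_status = sample(c("positive", "negative", "unknown"), 1))
}

# Stage-by-stage brute-force classifier, written flat and independently of
# the package's cascade walk: computes every stage on its own and takes the
# severity maximum, with the first stage (cascade order) attaining it as
# the trigger.
oracle_classify <- function(p, cfg) {
  sev <- c(NON_URGENT = 1, PRIORITY = 2, EMERGENCY = 3)
  hits <- cfg$danger_signs[cfg$danger_signs %in% p$danger_signs]
  if (length(hits) > 0)
    return(list(category = "EMERGENCY", trigger = hits[1]))
  stages <- list()
  risk <- oracle_ipsi(p, cfg)
  if (!is.na(risk)) {
    if (risk >= cfg$ipsi$emergency_threshold)
      stages[[length(stages) + 1]] <- c("EMERGENCY", "ipsi")
    else if (risk >= cfg$ipsi$priority_threshold)
      stages[[length(stages) + 1]] <- c("PRIORITY", "ipsi")
  }
  pts <- oracle_risc(p, cfg)
  if (!is.na(pts)) {
    if (pts >= cfg$risc$emergency_threshold)
      stages[[length(stages) + 1]] <- c("EMERGENCY", "risc")
    else if (pts >= cfg$risc$priority_threshold)
      stages[[length(stages) + 1]] <- c("PRIORITY", "risc")
  }
  for (vital in names(cfg$vital_thresholds)) {
    v <- p[[vital]]
    if (is.null(v)) next
    for (b in cfg$vital_thresholds[[vital]]) {
      if (p$age < b$age_min || p$age >= b$age_max) next
      ea <- b$emergency_above; eb <- b$emergency_below
      pa <- b$priority_above; pb <- b$priority_below
      if ((!is.null(ea) && v > ea) || (!is.null(eb) && v < eb))
        stages[[length(stages) + 1]] <- c("EMERGENCY", vital)
      else if ((!is.null(pa) && v > pa) || (!is.null(pb) && v < pb))
        stages[[length(stages) + 1]] <- c("PRIORITY", vital)
    }
  }
  if (length(stages) == 0)
    return(list(category = "NON_URGENT", trigger = "default"))
  cats <- vapply(stages, `[`, character(1), 1)
  trigs <- vapply(stages, `[`, character(1), 2)
  top <- max(sev[cats])
  list(category = names(sev)[top], trigger = trigs[sev[cats] == top][1])
}

state_of <- function(p, id) {
  if (id %in% names(p$symptoms)) unname(p$symptoms[[id]])
  else if (id %in% names(p$signs)) unname(p$signs[[id]])
  else "unknown"
}

oracle_ipsi <- function(p, cfg) {
  if (p$age < cfg$ipsi$min_age_months) return(NA_real_)
  co <- cfg$ipsi$coefficients
  if (is.null(p$temperature) || is.null(p$respiratory_rate) ||
      is.null(p$spo2)) return(NA_real_)
  lp <- cfg$ipsi$intercept + co$age * p$age +
    co$temperature * p$temperature +
    co$respiratory_rate * p$respiratory_rate + co$spo2 * p$spo2
  for (b in c("cough", "difficulty_breathing", "chest_indrawing",
              "lethargy", "irritability", "diarrhea")) {
    st <- state_of(p, b)
    if (st == "unknown") return(NA_real_)
    if (st == "present") lp <- lp + co[[b]]
  }
  1 / (1 + exp(-lp))
}

# Exhaustive condition-by-condition point sum.
oracle_risc <- function(p, cfg) {
  rs <- cfg$risc
  if (p$age >= rs$max_age_months) return(NA_integer_)
  if (!any(vapply(rs$applicability_any_of,
                  function(id) state_of(p, id) == "present", logical(1))))
    return(NA_integer_)
  if (!is.null(rs$points$spo2_below) && is.null(p$spo2))
    return(NA_integer_)
  if (!is.null(rs$points$low_weight) && is.null(p$weight))
    return(NA_integer_)
  total <- 0L
  if (!is.null(p$spo2) && p$spo2 < rs$points$spo2_below$threshold)
    total <- total + rs$points$spo2_below$points
  for (b in c("chest_indrawing", "wheezing", "inability_to_drink_or_eat"))
    if (!is.null(rs$points[[b]]) && state_of(p, b) == "present")
      total <- total + rs$points[[b]]
  for (band in rs$points$low_weight)
    if (p$age >= band$age_min && p$age < band$age_max &&
        p$weight < band$weight_below)
      total <- total + band$points
  total + rs$points$hiv[[p$hiv_status]]
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins.
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n, k), numeric(1))
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
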