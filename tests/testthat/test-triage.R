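cfg <- tiny_cascade()

benign <- function(...) {
  args <- list(...)
  base <- list(age = 30, sex = "male", weight = 12, temperature = 37,
               heart_rate = 110, respiratory_rate = 30, spo2 = 98,
               symptoms = c(cough = "absent", difficulty_breathing = "absent",
                            diarrhea = "absent",
                            inability_to_drink_or_eat = "absent",
                            wheezing = "absent"),
               signs = c(chest_indrawing = "absent", lethargy = "absent",
                         irritability = "absent"),
               hiv_status = "negative")
  do.call(triage_presentation, utils::modifyList(base, args))
}

test_that("a danger sign forces emergency and short-circuits the cascade", {
  p <- benign(danger_signs = "unconscious")
  r <- evaluate_danger_signs(p, cfg)
  expect_identical(r$category, "EMERGENCY")
  expect_identical(r$trigger, "unconscious")
  expect_null(evaluate_danger_signs(benign(), cfg))
  # regardless of how sick the scores say the child is
  p2 <- benign(danger_signs = "shock", spo2 = 80, respiratory_rate = 75,
               signs = c(chest_indrawing = "present", lethargy = "present",
                         irritability = "present"))
  expect_identical(classify(p2, cfg)$category, "EMERGENCY")
  expect_identical(classify(p2, cfg)$trigger, "shock")
})

test_that("with several danger signs the configured order picks the trigger", {
  signs3 <- c("unconscious", "convulsing", "shock")
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (perm in perms) {
    cfg_o <- tiny_cascade(danger = signs3[perm])
    p <- benign(danger_signs = c("shock", "convulsing"))
    r <- evaluate_danger_signs(p, cfg_o)
    # oracle: first of the permuted list that the child presents
    expected <- signs3[perm][signs3[perm] %in% c("shock", "convulsing")][1]
    expect_identical(r$trigger, expected)
  }
})

test_that("undeclared identifiers are rejected by name", {
  p <- benign(danger_signs = "levitating")
  expect_error(evaluate_danger_signs(p, cfg), "levitating")
  expect_error(
    validate_presentation(benign(symptoms = c(hiccups = "present")), cfg),
    "hiccups")
})

test_that("admission-risk score matches hand arithmetic and applicability rules", {
  # all-zero coefficients: inverse-logit of 0
  cfg0 <- unclass(cfg)
  cfg0$ipsi$intercept <- 0
  cfg0$ipsi$coefficients <- lapply(cfg0$ipsi$coefficients, function(x) 0)
  expect_equal(compute_ipsi(benign(), cascade_config(cfg0)), 0.5)
  # under the age bound: absent, not an error
  expect_true(is.na(compute_ipsi(benign(age = 2), cfg)))
  expect_false(is.na(compute_ipsi(benign(age = 3), cfg)))
  # hand-computed inverse-logit for a fixed child under tiny_cascade:
  # lp = -3 - 0.01*30 + 0.1*37 + 0.02*30 - 0.03*98 + 0.5 (cough)
  p <- benign(symptoms = c(cough = "present", difficulty_breathing = "absent",
                           diarrhea = "absent",
                           inability_to_drink_or_eat = "absent",
                           wheezing = "absent"))
  lp <- -3 - 0.3 + 3.7 + 0.6 - 2.94 + 0.5
  expect_equal(compute_ipsi(p, cfg), 1 / (1 + exp(-lp)), tolerance = 1e-12)
  # any missing required predictor makes the score absent
  expect_true(is.na(compute_ipsi(benign(spo2 = NA), cfg)))
  expect_true(is.na(compute_ipsi(
    benign(signs = c(lethargy = "unknown")), cfg)))
  # a configuration lacking a coefficient is an error naming it
  cfg_m <- unclass(cfg)
  cfg_m$ipsi$coefficients$lethargy <- NULL
  expect_error(compute_ipsi(benign(), cascade_config(cfg_m)), "lethargy")
})

test_that("respiratory-severity points match an exhaustive oracle", {
  appl <- function(...) benign(age = 10, weight = 6,
                               symptoms = c(cough = "present",
                                            wheezing = "absent",
                                            inability_to_drink_or_eat = "absent"),
                               ...)
  # applicable child meeting no condition scores zero
  expect_identical(compute_risc(appl(), cfg), 0L)
  # age bound and applicability predicate
  expect_true(is.na(compute_risc(benign(age = 30), cfg)))
  expect_true(is.na(compute_risc(benign(age = 10), cfg)))  # no indication
  # missing weight with a weight band configured: absent with a reason
  r <- compute_risc(benign(age = 10, weight = NA,
                           symptoms = c(cough = "present")), cfg)
  expect_true(is.na(r))
  expect_match(attr(r, "reason"), "weight")
  # 40 random applicable-aged presentations against the brute-force sum
  set.seed(41)
  for (i in 1:40) {
    p <- rand_presentation(cfg)
    expect_identical(as.integer(compute_risc(p, cfg)),
                     as.integer(oracle_risc(p, cfg)),
                     info = paste("presentation", i))
  }
})

test_that("vital-sign flags equal a flat band-by-band re-implementation", {
  expect_identical(nrow(evaluate_vital_thresholds(
    benign(temperature = NA, heart_rate = NA, respiratory_rate = NA,
           spo2 = NA), cfg)), 0L)
  f <- evaluate_vital_thresholds(benign(spo2 = 80), cfg)
  expect_identical(f$vital, "spo2")
  expect_identical(f$category, "EMERGENCY")
  set.seed(42)
  for (i in 1:60) {
    p <- rand_presentation(cfg)
    got <- evaluate_vital_thresholds(p, cfg)
    exp <- list()
    for (vital in names(cfg$vital_thresholds)) {
      v <- p[[vital]]
      if (is.null(v)) next
      for (b in cfg$vital_thresholds[[vital]]) {
        if (p$age < b$age_min || p$age >= b$age_max) next
        hit <- if ((!is.null(b$emergency_above) && v > b$emergency_above) ||
                   (!is.null(b$emergency_below) && v < b$emergency_below))
          "EMERGENCY"
        else if ((!is.null(b$priority_above) && v > b$priority_above) ||
                 (!is.null(b$priority_below) && v < b$priority_below))
          "PRIORITY"
        else NA_character_
        if (!is.na(hit)) exp[[vital]] <- hit
      }
    }
    expect_identical(nrow(got), length(exp))
    for (j in seq_len(nrow(got)))
      expect_identical(got$category[j], exp[[got$vital[j]]])
  }
})

test_that("full cascade equals the stage-by-stage severity-maximum oracle", {
  expect_identical(classify(benign(), cfg)$trigger, "default")
  expect_identical(classify(benign(), cfg)$category, "NON_URGENT")
  set.seed(7)
  for (i in 1:300) {
    p <- rand_presentation(cfg)
    got <- classify(p, cfg)
    want <- oracle_classify(p, cfg)
    expect_identical(got$category, want$category, info = paste("case", i))
    expect_identical(got$trigger, want$trigger, info = paste("case", i))
  }
})

test_that("cascade is deterministic and monotone in danger signs", {
  set.seed(8)
  sev <- function(cat_) match(cat_, c("NON_URGENT", "PRIORITY", "EMERGENCY"))
  for (i in 1:50) {
    p <- rand_presentation(cfg)
    a <- classify(p, cfg); b <- classify(p, cfg)
    expect_identical(a[c("category", "trigger", "ipsi_risk", "risc_score")],
                     b[c("category", "trigger", "ipsi_risk", "risc_score")])
    p_ds <- p
    p_ds$danger_signs <- unique(c(p$danger_signs, "convulsing"))
    expect_gte(sev(classify(p_ds, cfg)$category), sev(a$category))
  }
})

test_that("raising the admission-risk priority threshold never adds priority cases", {
  set.seed(9)
  pop <- replicate(150, rand_presentation(cfg), simplify = FALSE)
  count_priority_plus <- function(th) {
    c2 <- unclass(cfg)
    c2$ipsi$priority_threshold <- th
    c2$ipsi$emergency_threshold <- max(th, c2$ipsi$emergency_threshold)
    c2 <- cascade_config(c2)
    sum(vapply(pop, function(p) classify(p, c2)$category != "NON_URGENT",
               logical(1)))
  }
  counts <- vapply(c(0.05, 0.2, 0.4, 0.6, 0.9), count_priority_plus,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("score applicability bounds hold over random children", {
  set.seed(10)
  for (i in 1:80) {
    p <- rand_presentation(cfg)
    r <- classify(p, cfg)
    if (p$age < 3) expect_true(is.na(r$ipsi_risk))
    if (p$age >= 24) expect_true(is.na(r$risc_score))
  }
})

test_that("the table front end reproduces per-child classification", {
  df <- data.frame(
    age = c(24, 30, 5), sex = c("male", "female", "male"),
    weight = c(10, 12, 5.5), temperature = c(37, 40.2, 37.1),
    heart_rate = c(120, 130, 140), respiratory_rate = c(30, 33, 40),
    spo2 = c(98, 97, 96),
    danger_signs = c("", "", "unconscious"),
    cough = c(0, 0, 1), difficulty_breathing = c(0, 0, 0),
    diarrhea = c(0, 0, 0), inability_to_drink_or_eat = c(0, 0, 0),
    wheezing = c(0, 0, 0), chest_indrawing = c(0, 0, 0),
    lethargy = c(0, 0, 0), irritability = c(0, 0, 0),
    hiv_status = c("negative", "negative", "unknown"),
    stringsAsFactors = FALSE)
  out <- triage_table(df, cfg)
  expect_identical(out$category, c("NON_URGENT", "PRIORITY", "EMERGENCY"))
  expect_identical(out$trigger[2], "temperature")
  expect_identical(out$trigger[3], "unconscious")
})
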