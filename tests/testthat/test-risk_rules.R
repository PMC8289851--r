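test_that("medium-column items trigger exactly as printed", {
  expect_identical(medium_risk_items(risk_profile(chorioamnionitis = TRUE)),
                   "chorioamnionitis")
  expect_identical(medium_risk_items(risk_profile()), character(0))
  expect_identical(medium_risk_items(risk_profile(prior_vaginal_births = 4)),
                   character(0))
  expect_identical(medium_risk_items(risk_profile(prior_vaginal_births = 5)),
                   "grand_multiparity")
  # strict numeric boundaries
  expect_identical(medium_risk_items(risk_profile(bmi = 35)), character(0))
  expect_identical(medium_risk_items(risk_profile(bmi = 35.1)), "morbid_obesity")
  expect_identical(medium_risk_items(risk_profile(estimated_fetal_weight = 4)),
                   character(0))
  expect_identical(
    medium_risk_items(risk_profile(estimated_fetal_weight = 4.2)),
    "fetal_macrosomia")
  # one previous hemorrhage is medium; absent numerics never trigger
  expect_identical(medium_risk_items(risk_profile(prior_pph_count = 1)),
                   "prior_pph_once")
  expect_identical(medium_risk_items(risk_profile(bmi = NA_real_)), character(0))
})

test_that("high-column items trigger as printed, hematocrit rule conditional", {
  expect_identical(
    high_risk_items(risk_profile(placenta_previa_or_low_lying = TRUE)),
    "placenta_previa_low_lying")
  # hematocrit < 30 alone is not a high item ...
  expect_identical(high_risk_items(risk_profile(hematocrit = 28)), character(0))
  # ... but counts once any other item is triggered
  p <- risk_profile(hematocrit = 28, labor_induction = TRUE)
  expect_identical(high_risk_items(p), "low_hematocrit_with_risk_factors")
  expect_identical(medium_risk_items(p), "induction_of_labor")
  # bleeding disorder is synonymous with coagulopathy
  expect_identical(high_risk_items(risk_profile(known_bleeding_disorder = TRUE)),
                   "known_coagulopathy")
  expect_identical(high_risk_items(risk_profile(prior_pph_count = 2)),
                   "prior_pph_multiple")
  expect_identical(high_risk_items(risk_profile(platelets = 99999)),
                   "thrombocytopenia")
  expect_identical(high_risk_items(risk_profile(platelets = 1e5)), character(0))
})

test_that("classify applies precedence and the two-medium-item escalation", {
  esc <- classify(risk_profile(chorioamnionitis = TRUE, labor_induction = TRUE))
  expect_equal(as.character(esc$level), "high")
  expect_true(esc$escalated_from_medium)
  expect_length(esc$triggered_high_items, 0)

  expect_equal(as.character(classify(risk_profile())$level), "low")
  one <- classify(risk_profile(prior_uterine_incision_or_cesarean = TRUE))
  expect_equal(as.character(one$level), "medium")
  expect_false(one$escalated_from_medium)

  # an unconditional high item wins regardless of medium count
  hi <- classify(risk_profile(suspected_accreta_or_percreta = TRUE,
                              labor_induction = TRUE))
  expect_equal(as.character(hi$level), "high")
  expect_false(hi$escalated_from_medium)
})

test_that("classification matches the brute-force oracle on every medium-item combination", {
  # enumerate all 2^12 on/off patterns of the medium items
  items <- c("labor_induction", "prior_uterine_incision_or_cesarean",
             "large_uterine_fibroids", "chorioamnionitis", "fetal_demise",
             "family_history_pph_first_degree", "polyhydramnios",
             "multiple_gestation")
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(items) + 4))
  names(grid) <- c(items, "gm", "pph1", "mo", "fm")
  profiles <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    risk_profile(
      labor_induction = g$labor_induction,
      prior_uterine_incision_or_cesarean = g$prior_uterine_incision_or_cesarean,
      large_uterine_fibroids = g$large_uterine_fibroids,
      chorioamnionitis = g$chorioamnionitis,
      fetal_demise = g$fetal_demise,
      family_history_pph_first_degree = g$family_history_pph_first_degree,
      polyhydramnios = g$polyhydramnios,
      multiple_gestation = g$multiple_gestation,
      prior_vaginal_births = if (g$gm) 5L else 0L,
      prior_pph_count = if (g$pph1) 1L else 0L,
      bmi = if (g$mo) 40 else NA_real_,
      estimated_fetal_weight = if (g$fm) 4.5 else NA_real_)
  }))
  got <- as.character(classify_cohort(profiles)$level)
  want <- oracle_levels(profiles)
  expect_identical(got, want)
  # and the count-threshold rule directly
  nm <- classify_cohort(profiles)$n_medium_items
  expect_identical(got, ifelse(nm >= 2, "high", ifelse(nm == 1, "medium", "low")))
})

test_that("classification is a deterministic partition into exactly one tier", {
  set.seed(42)
  profiles <- random_profiles(500)
  a <- classify_cohort(profiles)
  b <- classify_cohort(profiles)
  expect_identical(a, b)
  expect_true(all(as.character(a$level) %in% risk_levels()))
  expect_false(any(is.na(a$level)))
  # tier predicates are mutually exclusive and exhaustive
  is_high <- a$n_high_items >= 1 | a$n_medium_items >= 2
  is_med <- a$n_high_items == 0 & a$n_medium_items == 1
  is_low <- a$n_high_items == 0 & a$n_medium_items == 0
  expect_true(all(is_high + is_med + is_low == 1))
  expect_identical(as.character(a$level),
                   ifelse(is_high, "high", ifelse(is_med, "medium", "low")))
})

test_that("turning any single item on never decreases the tier", {
  intensify <- list(
    function(p) {p$labor_induction <- TRUE; p},
    function(p) {p$prior_uterine_incision_or_cesarean <- TRUE; p},
    function(p) {p$chorioamnionitis <- TRUE; p},
    function(p) {p$multiple_gestation <- TRUE; p},
    function(p) {p$suspected_accreta_or_percreta <- TRUE; p},
    function(p) {p$placenta_previa_or_low_lying <- TRUE; p},
    function(p) {p$known_coagulopathy <- TRUE; p},
    function(p) {p$active_bleeding_more_than_show <- TRUE; p},
    function(p) {p$prior_vaginal_births <- 5L; p},
    function(p) {p$prior_pph_count <- pmax(1L, p$prior_pph_count + 1L); p},
    function(p) {p$bmi <- 40; p},
    function(p) {p$estimated_fetal_weight <- 4.5; p},
    function(p) {p$platelets <- 9e4; p},
    function(p) {p$hematocrit <- 28; p})
  set.seed(7)
  profiles <- random_profiles(200)
  base <- classify_cohort(profiles)$level
  for (mut in intensify) {
    mutated <- mut(profiles)
    expect_true(all(classify_cohort(mutated)$level >= base))
  }
})

test_that("profile invariants are enforced at construction", {
  expect_error(risk_profile(hematocrit = 65), "hematocrit")
  expect_error(risk_profile(bmi = -1), "bmi")
  expect_error(risk_profile(prior_vaginal_births = -1), "non-negative")
  expect_error(risk_profile(prior_pph_count = 1.5), "non-negative integers")
  expect_error(risk_profile(nonexistent_field = TRUE), "unknown profile field")
  df <- risk_profile()
  df$bmi <- NULL
  expect_error(classify_cohort(df), "missing assessment column")
})
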