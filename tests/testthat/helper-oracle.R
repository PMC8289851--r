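# Independent scalar re-implementation of the three-tier rules, used as a
# brute-force oracle: count triggered items with plain if/else, then apply
# the high-item / escalation precedence. Kept deliberately separate from the
# vectorised implementation under test.
oracle_level <- function(p) {
  nm <- 0
  if (isTRUE(p$labor_induction)) nm <- nm + 1
  if (!is.na(p$prior_vaginal_births) && p$prior_vaginal_births > 4) nm <- nm + 1
  if (isTRUE(p$prior_uterine_incision_or_cesarean)) nm <- nm + 1
  if (isTRUE(p$large_uterine_fibroids)) nm <- nm + 1
  if (!is.na(p$prior_pph_count) && p$prior_pph_count == 1) nm <- nm + 1
  if (isTRUE(p$chorioamnionitis)) nm <- nm + 1
  if (isTRUE(p$fetal_demise)) nm <- nm + 1
  if (!is.na(p$bmi) && p$bmi > 35) nm <- nm + 1
  if (!is.na(p$estimated_fetal_weight) && p$estimated_fetal_weight > 4) nm <- nm + 1
  if (isTRUE(p$family_history_pph_first_degree)) nm <- nm + 1
  if (isTRUE(p$polyhydramnios)) nm <- nm + 1
  if (isTRUE(p$multiple_gestation)) nm <- nm + 1
  nh <- 0
  if (isTRUE(p$active_bleeding_more_than_show)) nh <- nh + 1
  if (isTRUE(p$suspected_accreta_or_percreta)) nh <- nh + 1
  if (isTRUE(p$placenta_previa_or_low_lying)) nh <- nh + 1
  if (isTRUE(p$known_coagulopathy) || isTRUE(p$known_bleeding_disorder)) nh <- nh + 1
  if (!is.na(p$prior_pph_count) && p$prior_pph_count >= 2) nh <- nh + 1
  if (!is.na(p$platelets) && p$platelets < 1e5) nh <- nh + 1
  if (!is.na(p$hematocrit) && p$hematocrit < 30 && (nm + nh) >= 1) nh <- nh + 1
  if (nh >= 1 || nm >= 2) "high" else if (nm == 1) "medium" else "low"
}

# Random profiles spanning the whole invariant-respecting input space,
# including missing numerics. Independent of the package's own generator.
random_profiles <- function(n) {
  flip <- function(p) stats::runif(n) < p
  maybe <- function(x, p_na = 0.3) ifelse(flip(p_na), NA_real_, x)
  data.frame(
    prior_uterine_incision_or_cesarean = flip(0.3),
    known_bleeding_disorder = flip(0.1),
    multiple_gestation = flip(0.15),
    labor_induction = flip(0.4),
    large_uterine_fibroids = flip(0.1),
    chorioamnionitis = flip(0.15),
    fetal_demise = flip(0.05),
    family_history_pph_first_degree = flip(0.1),
    polyhydramnios = flip(0.1),
    active_bleeding_more_than_show = flip(0.1),
    suspected_accreta_or_percreta = flip(0.05),
    placenta_previa_or_low_lying = flip(0.1),
    known_coagulopathy = flip(0.05),
    prior_vaginal_births = sample(0:8, n, replace = TRUE),
    prior_pph_count = sample(0:3, n, replace = TRUE,
                             prob = c(0.7, 0.15, 0.1, 0.05)),
    bmi = maybe(stats::runif(n, 18, 55)),
    estimated_fetal_weight = maybe(stats::runif(n, 2, 5.5)),
    hematocrit = maybe(stats::runif(n, 20, 45)),
    platelets = maybe(stats::runif(n, 5e4, 4e5))
  )
}

oracle_levels <- function(profiles) {
  vapply(seq_len(nrow(profiles)),
         function(i) oracle_level(as.list(profiles[i, ])), character(1))
}

# Expand per-tier (event, non-event) counts into level / outcome vectors, so
# published count tables can be replayed through the evaluation stage.
counts_to_cohort <- function(events, sizes) {
  lv <- rep(names(sizes), sizes)
  out <- unlist(lapply(names(sizes), function(g)
    rep(c(TRUE, FALSE), c(events[[g]], sizes[[g]] - events[[g]]))))
  list(level = lv, outcome = out)
}

# Published per-tier sizes and composite counts used across tests.
published_sizes <- c(low = 14803, medium = 26163, high = 15937)
published_composite <- c(low = 330, medium = 2084, high = 1898)
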