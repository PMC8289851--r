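#' @title Three-tier hemorrhage risk rules
#' @description Internal item matrices behind the AWHONN-style classifier.
#'   Medium items each count once; two or more medium items escalate to high.
#'   High items classify as high unconditionally, except low hematocrit,
#'   which counts only in the presence of at least one other triggered item.
#' @name risk-rules
#' @keywords internal
NULL

# Fixed medium-item order: documented, stable across versions.
.medium_item_ids <- c(
  "induction_of_labor",
  "grand_multiparity",
  "prior_cesarean_or_uterine_incision",
  "large_uterine_fibroids",
  "prior_pph_once",
  "chorioamnionitis",
  "fetal_demise",
  "morbid_obesity",
  "fetal_macrosomia",
  "family_history_pph",
  "polyhydramnios",
  "multiple_gestation"
)

.high_item_ids <- c(
  "active_bleeding",
  "suspected_accreta_or_percreta",
  "placenta_previa_low_lying",
  "known_coagulopathy",
  "prior_pph_multiple",
  "thrombocytopenia",
  "low_hematocrit_with_risk_factors"
)

# n x 12 logical matrix of triggered medium items. Missing numerics never
# trigger: the comparison is wrapped so NA becomes FALSE.
.medium_matrix <- function(p) {
  gt <- function(x, cut) !is.na(x) & x > cut
  cbind(
    induction_of_labor = as.logical(p$labor_induction),
    grand_multiparity = gt(p$prior_vaginal_births, 4),
    prior_cesarean_or_uterine_incision =
      as.logical(p$prior_uterine_incision_or_cesarean),
    large_uterine_fibroids = as.logical(p$large_uterine_fibroids),
    prior_pph_once = !is.na(p$prior_pph_count) & p$prior_pph_count == 1,
    chorioamnionitis = as.logical(p$chorioamnionitis),
    fetal_demise = as.logical(p$fetal_demise),
    morbid_obesity = gt(p$bmi, 35),
    fetal_macrosomia = gt(p$estimated_fetal_weight, 4),
    family_history_pph = as.logical(p$family_history_pph_first_degree),
    polyhydramnios = as.logical(p$polyhydramnios),
    multiple_gestation = as.logical(p$multiple_gestation)
  )[, .medium_item_ids, drop = FALSE]
}

# n x 7 logical matrix of triggered high items. Low hematocrit (< 30) is
# conditional: it counts only when some other medium or high item fired.
.high_matrix <- function(p, medium = .medium_matrix(p)) {
  lt <- function(x, cut) !is.na(x) & x < cut
  uncond <- cbind(
    active_bleeding = as.logical(p$active_bleeding_more_than_show),
    suspected_accreta_or_percreta = as.logical(p$suspected_accreta_or_percreta),
    placenta_previa_low_lying = as.logical(p$placenta_previa_or_low_lying),
    known_coagulopathy = as.logical(p$known_coagulopathy) |
      as.logical(p$known_bleeding_disorder),
    prior_pph_multiple = !is.na(p$prior_pph_count) & p$prior_pph_count >= 2,
    thrombocytopenia = lt(p$platelets, 1e5)
  )
  other <- rowSums(medium) + rowSums(uncond) >= 1
  cbind(uncond,
        low_hematocrit_with_risk_factors = lt(p$hematocrit, 30) & other
  )[, .high_item_ids, drop = FALSE]
}

.coerce_bool_cols <- function(df) {
  for (f in intersect(.profile_bool_fields, names(df)))
    df[[f]] <- as.logical(df[[f]]) %in% TRUE
  df
}

#' Triggered medium-risk items
#'
#' Returns the identifiers of the medium-column items triggered by one
#' profile, in the fixed documented order: induction of labor, more than four
#' previous vaginal births, prior cesarean or uterine incision, large uterine
#' fibroids, exactly one previous postpartum hemorrhage, chorioamnionitis,
#' fetal demise, BMI > 35, estimated fetal weight > 4 kg, first-degree family
#' history of postpartum hemorrhage, polyhydramnios, and multiple gestation
#' (non-singleton pregnancy breaks the low tier and is counted as one medium
#' item). Absent numerics never trigger their item.
#'
#' @param profile One-row data frame (or named list) of assessment fields.
#' @return Character vector of item identifiers (possibly empty).
#' @seealso [high_risk_items()], [classify()]
#' @export
#' @examples
#' medium_risk_items(risk_profile(chorioamnionitis = TRUE))
medium_risk_items <- function(profile) {
  p <- .one_profile(profile)
  m <- .medium_matrix(p)
  colnames(m)[m[1, ]]
}

#' Triggered high-risk items
#'
#' Returns the identifiers of the triggered high-column items: active
#' bleeding greater than bloody show, suspected accreta or percreta, placenta
#' previa or low-lying placenta, known coagulopathy (a recorded bleeding
#' disorder counts), two or more previous postpartum hemorrhages, platelets
#' below 100,000/uL, and hematocrit below 30 provided at least one other
#' medium or high item is also triggered.
#'
#' @inheritParams medium_risk_items
#' @return Character vector of item identifiers (possibly empty).
#' @export
#' @examples
#' high_risk_items(risk_profile(placenta_previa_or_low_lying = TRUE))
#' high_risk_items(risk_profile(hematocrit = 28))          # empty: conditional
#' high_risk_items(risk_profile(hematocrit = 28, labor_induction = TRUE))
high_risk_items <- function(profile) {
  p <- .one_profile(profile)
  h <- .high_matrix(p)
  colnames(h)[h[1, ]]
}

.one_profile <- function(profile) {
  p <- as.data.frame(as.list(profile), stringsAsFactors = FALSE)
  if (nrow(p) != 1) stop("expected a single profile (one row)")
  validate_profiles(p)
  .coerce_bool_cols(p)
}

#' Classify one delivery into a hemorrhage-risk tier
#'
#' Applies the three-tier rules: any triggered high item classifies as high;
#' otherwise two or more medium items escalate to high; exactly one medium
#' item is medium; no items is low. The function is pure and deterministic.
#'
#' @inheritParams medium_risk_items
#' @return An object of class `risk_category`: list with `level` (ordered
#'   factor low < medium < high), `triggered_medium_items`,
#'   `triggered_high_items`, and `escalated_from_medium` (TRUE when high was
#'   reached via the two-medium-item escalation alone).
#' @export
#' @examples
#' classify(risk_profile())$level
#' classify(risk_profile(chorioamnionitis = TRUE, labor_induction = TRUE))
classify <- function(profile) {
  p <- .one_profile(profile)
  cls <- classify_cohort(p)
  structure(
    list(level = cls$level[1],
         triggered_medium_items = medium_risk_items(p),
         triggered_high_items = high_risk_items(p),
         escalated_from_medium = cls$escalated_from_medium[1]),
    class = "risk_category")
}

#' @export
print.risk_category <- function(x, ...) {
  cat("Hemorrhage risk:", as.character(x$level), "\n")
  if (length(x$triggered_medium_items))
    cat("  medium items:", paste(x$triggered_medium_items, collapse = ", "), "\n")
  if (length(x$triggered_high_items))
    cat("  high items:  ", paste(x$triggered_high_items, collapse = ", "), "\n")
  if (isTRUE(x$escalated_from_medium))
    cat("  escalated from medium (>= 2 medium items)\n")
  invisible(x)
}

#' Classify every delivery in a cohort table
#'
#' Vectorised classifier over a cohort data frame carrying the assessment
#' columns ([profile_fields()]).
#'
#' @param profiles Data frame with one row per delivery.
#' @return Data frame with one row per delivery: `level` (ordered factor
#'   low < medium < high), `n_medium_items`, `n_high_items`, and
#'   `escalated_from_medium`.
#' @export
#' @examples
#' cohort <- rbind(risk_profile(), risk_profile(labor_induction = TRUE))
#' classify_cohort(cohort)
classify_cohort <- function(profiles) {
  validate_profiles(profiles)
  p <- .coerce_bool_cols(profiles)
  m <- .medium_matrix(p)
  h <- .high_matrix(p, m)
  nm <- rowSums(m)
  nh <- rowSums(h)
  level <- ifelse(nh >= 1 | nm >= 2, "high", ifelse(nm == 1, "medium", "low"))
  data.frame(
    level = factor(level, levels = risk_levels(), ordered = TRUE),
    n_medium_items = nm,
    n_high_items = nh,
    escalated_from_medium = nh == 0 & nm >= 2
  )
}

#' Ordered risk levels
#'
#' @return `c("low", "medium", "high")`, the tier order used throughout.
#' @export
risk_levels <- function() c("low", "medium", "high")

#' Item identifier vocabulary
#'
#' @return Data frame mapping each stable item identifier to its tier
#'   (`medium` or `high`), in the fixed evaluation order.
#' @export
risk_item_vocabulary <- function() {
  data.frame(
    item = c(.medium_item_ids, .high_item_ids),
    tier = rep(c("medium", "high"),
               c(length(.medium_item_ids), length(.high_item_ids))),
    stringsAsFactors = FALSE)
}
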