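#' Risk-factor profile schema
#'
#' The cohort table carries one row per delivery. Risk-assessment columns
#' (the fields consulted by the classifier) are listed below; outcome columns
#' are documented in [composite_morbidity()].
#'
#' @name profile-schema
#' @keywords internal
NULL

# Assessment (risk-factor) columns, by storage type. Column names are the
# on-disk CSV header and are stable across versions.
.profile_bool_fields <- c(
  "prior_uterine_incision_or_cesarean",
  "known_bleeding_disorder",
  "multiple_gestation",
  "labor_induction",
  "large_uterine_fibroids",
  "chorioamnionitis",
  "fetal_demise",
  "family_history_pph_first_degree",
  "polyhydramnios",
  "active_bleeding_more_than_show",
  "suspected_accreta_or_percreta",
  "placenta_previa_or_low_lying",
  "known_coagulopathy"
)

.profile_count_fields <- c("prior_vaginal_births", "prior_pph_count")

.profile_numeric_fields <- c("bmi", "estimated_fetal_weight",
                             "hematocrit", "platelets")

.outcome_fields <- c("ebl_ml", "prbc_units", "icu_admission",
                     "hysterectomy", "dilation_and_curettage")

#' Column names of the risk-assessment fields
#'
#' @return Character vector of the 19 risk-factor column names, in canonical
#'   order (booleans, then counts, then nullable numerics).
#' @export
profile_fields <- function() {
  c(.profile_bool_fields, .profile_count_fields, .profile_numeric_fields)
}

#' Column names of the delivery-outcome fields
#'
#' @return Character vector of the 5 outcome column names.
#' @export
outcome_fields <- function() .outcome_fields

#' Machine-readable column dictionary for the cohort CSV
#'
#' One row per column of the ingest schema: name, type (`boolean` encoded
#' 0/1, `count`, `numeric` with empty cells for missing), role (`assessment`
#' or `outcome`), units, and a short description.
#'
#' @return A data frame with columns `column`, `type`, `role`, `units`,
#'   `description`.
#' @export
#' @examples
#' column_dictionary()
column_dictionary <- function() {
  d <- function(column, type, role, units, description)
    data.frame(column = column, type = type, role = role, units = units,
               description = description, stringsAsFactors = FALSE)
  rbind(
    d("prior_uterine_incision_or_cesarean", "boolean", "assessment", "",
      "Prior cesarean birth or other uterine incision"),
    d("known_bleeding_disorder", "boolean", "assessment", "",
      "Known bleeding disorder (treated as coagulopathy)"),
    d("multiple_gestation", "boolean", "assessment", "",
      "Non-singleton pregnancy"),
    d("labor_induction", "boolean", "assessment", "",
      "Induction of labor"),
    d("large_uterine_fibroids", "boolean", "assessment", "",
      "Large uterine fibroids"),
    d("chorioamnionitis", "boolean", "assessment", "",
      "Chorioamnionitis"),
    d("fetal_demise", "boolean", "assessment", "",
      "Fetal demise"),
    d("family_history_pph_first_degree", "boolean", "assessment", "",
      "First-degree relative with postpartum hemorrhage"),
    d("polyhydramnios", "boolean", "assessment", "",
      "Polyhydramnios"),
    d("active_bleeding_more_than_show", "boolean", "assessment", "",
      "Active bleeding greater than bloody show"),
    d("suspected_accreta_or_percreta", "boolean", "assessment", "",
      "Suspected placenta accreta or percreta"),
    d("placenta_previa_or_low_lying", "boolean", "assessment", "",
      "Placenta previa or low-lying placenta"),
    d("known_coagulopathy", "boolean", "assessment", "",
      "Known coagulopathy"),
    d("prior_vaginal_births", "count", "assessment", "",
      "Number of previous vaginal births"),
    d("prior_pph_count", "count", "assessment", "",
      "Number of previous postpartum hemorrhages"),
    d("bmi", "numeric", "assessment", "kg/m2",
      "Body mass index at delivery (empty if unknown)"),
    d("estimated_fetal_weight", "numeric", "assessment", "kg",
      "Estimated fetal weight (empty if unknown)"),
    d("hematocrit", "numeric", "assessment", "%",
      "Hematocrit (empty if unknown)"),
    d("platelets", "numeric", "assessment", "per uL",
      "Platelet count (empty if unknown)"),
    d("ebl_ml", "numeric", "outcome", "mL",
      "Estimated blood loss, gravimetric (empty if unknown)"),
    d("prbc_units", "count", "outcome", "units",
      "Packed red blood cell units transfused"),
    d("icu_admission", "boolean", "outcome", "",
      "Admitted to an intensive care unit"),
    d("hysterectomy", "boolean", "outcome", "",
      "Peripartum hysterectomy"),
    d("dilation_and_curettage", "boolean", "outcome", "",
      "Dilation and curettage")
  )
}

#' Construct a single risk-factor profile
#'
#' Convenience constructor for a one-row profile table with every boolean
#' FALSE, both counts 0, and every nullable numeric absent unless overridden.
#' Such a default profile classifies as low risk.
#'
#' @param ... Named profile fields to override (see [profile_fields()]).
#' @return A one-row data frame with the 19 assessment columns.
#' @export
#' @examples
#' risk_profile(chorioamnionitis = TRUE)
risk_profile <- function(...) {
  p <- c(
    stats::setNames(as.list(rep(FALSE, length(.profile_bool_fields))),
                    .profile_bool_fields),
    stats::setNames(as.list(rep(0L, length(.profile_count_fields))),
                    .profile_count_fields),
    stats::setNames(as.list(rep(NA_real_, length(.profile_numeric_fields))),
                    .profile_numeric_fields)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown profile field(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  out <- as.data.frame(p, stringsAsFactors = FALSE)
  validate_profiles(out)
  out
}

#' Validate risk-factor profile invariants
#'
#' Checks column presence and field-level invariants: counts are non-negative
#' integers, `bmi > 0`, `hematocrit` in (0, 60], and `platelets >= 0` where
#' present. Missing (`NA`) numerics are allowed and never trigger an item.
#'
#' @param profiles Data frame holding the assessment columns.
#' @return Invisibly, `profiles`. Errors on the first violated invariant.
#' @export
validate_profiles <- function(profiles) {
  miss <- setdiff(profile_fields(), names(profiles))
  if (length(miss))
    stop("missing assessment column(s): ", paste(miss, collapse = ", "))
  for (f in .profile_bool_fields) {
    v <- profiles[[f]]
    if (!(is.logical(v) || all(v %in% c(0, 1, NA))))
      stop("column '", f, "' must be logical or 0/1")
  }
  for (f in .profile_count_fields) {
    v <- profiles[[f]]
    if (any(!is.na(v) & (v < 0 | v != floor(v))))
      stop("column '", f, "' must hold non-negative integers")
  }
  chk <- function(f, ok, what) {
    v <- profiles[[f]]
    if (any(!is.na(v) & !ok(v))) stop("column '", f, "' must be ", what)
  }
  chk("bmi", function(v) v > 0, "positive where present")
  chk("hematocrit", function(v) v > 0 & v <= 60, "in (0, 60] where present")
  chk("platelets", function(v) v >= 0, "non-negative where present")
  invisible(profiles)
}
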