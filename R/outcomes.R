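#' Composite hemorrhage-related morbidity
#'
#' Derives the composite morbidity indicator and its component breakdown from
#' the delivery-outcome columns. The components are:
#'
#' * `hemorrhage` — estimated blood loss of at least 1000 mL (gravimetric;
#'   inclusive threshold). A missing `ebl_ml` contributes no hemorrhage
#'   component.
#' * `transfusion` — any packed red-blood-cell administration
#'   (`prbc_units >= 1`), regardless of timing.
#' * `icu` — ICU admission.
#' * `additional_complication` — hysterectomy or dilation and curettage.
#'
#' `composite` is the union (logical OR) of the four components. Components
#' overlap freely, so per-component cohort counts are not additive to the
#' composite count.
#'
#' @param outcomes Data frame with columns `ebl_ml` (mL, may be `NA`),
#'   `prbc_units` (non-negative count), `icu_admission`, `hysterectomy`,
#'   `dilation_and_curettage` (logical or 0/1).
#' @param ebl_threshold_ml Blood-loss cutoff defining hemorrhage, in mL.
#'   Default 1000 (inclusive); overriding it is logged by the pipeline.
#' @return Data frame with one row per input row and logical columns
#'   `hemorrhage`, `transfusion`, `icu`, `additional_complication`,
#'   `composite`. The number of rows with missing `ebl_ml` is attached as
#'   attribute `n_missing_ebl`.
#' @export
#' @examples
#' composite_morbidity(data.frame(
#'   ebl_ml = c(1000, 0, 500), prbc_units = c(0, 0, 1),
#'   icu_admission = FALSE, hysterectomy = FALSE,
#'   dilation_and_curettage = FALSE))
composite_morbidity <- function(outcomes, ebl_threshold_ml = 1000) {
  miss <- setdiff(.outcome_fields, names(outcomes))
  if (length(miss))
    stop("missing outcome column(s): ", paste(miss, collapse = ", "))
  ebl <- outcomes$ebl_ml
  units <- outcomes$prbc_units
  if (any(!is.na(ebl) & ebl < 0)) stop("ebl_ml must be non-negative")
  if (any(is.na(units) | units < 0)) stop("prbc_units must be a non-negative count")
  b <- function(x) as.logical(x) %in% TRUE
  res <- data.frame(
    hemorrhage = !is.na(ebl) & ebl >= ebl_threshold_ml,
    transfusion = units >= 1,
    icu = b(outcomes$icu_admission),
    additional_complication = b(outcomes$hysterectomy) |
      b(outcomes$dilation_and_curettage)
  )
  res$composite <- res$hemorrhage | res$transfusion | res$icu |
    res$additional_complication
  attr(res, "n_missing_ebl") <- sum(is.na(ebl))
  res
}

#' Per-group incidence of composite morbidity and its components
#'
#' Tabulates counts and percentages of the composite outcome and each
#' component by risk tier, with a pooled medium-plus-high column.
#'
#' @param level Vector of risk tiers (`low`/`medium`/`high`), one per record.
#' @param morbidity Data frame from [composite_morbidity()].
#' @return Data frame with one row per outcome (`composite`, `hemorrhage`,
#'   `transfusion`, `icu`, `additional_complication`) and, per group
#'   (`low`, `medium`, `high`, `medium_high`), a count column `<group>_n` and
#'   a percentage column `<group>_pct` (1 decimal place; full-precision
#'   percentages carried in `<group>_pct_full`).
#' @export
incidence_table <- function(level, morbidity) {
  level <- factor(as.character(level), levels = risk_levels())
  if (length(level) != nrow(morbidity))
    stop("level and morbidity must have one entry per record")
  outcomes <- c("composite", "hemorrhage", "transfusion", "icu",
                "additional_complication")
  groups <- list(low = level == "low", medium = level == "medium",
                 high = level == "high",
                 medium_high = level %in% c("medium", "high"))
  out <- data.frame(outcome = outcomes, stringsAsFactors = FALSE)
  for (g in names(groups)) {
    idx <- groups[[g]]
    n <- sum(idx)
    cnt <- vapply(outcomes, function(o) sum(morbidity[[o]][idx]), numeric(1))
    pct <- if (n > 0) 100 * cnt / n else rep(NA_real_, length(cnt))
    out[[paste0(g, "_n")]] <- cnt
    out[[paste0(g, "_pct")]] <- round(pct, 1)
    out[[paste0(g, "_pct_full")]] <- pct
  }
  attr(out, "group_sizes") <- vapply(groups, sum, numeric(1))
  out
}
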