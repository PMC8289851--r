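#' 2x2 screening contingency table
#'
#' Cell layout follows the screening convention: `tp` test-positive &
#' outcome-positive, `fp` test-positive & outcome-negative, `fn`
#' test-negative & outcome-positive, `tn` test-negative & outcome-negative.
#'
#' @param tp,fp,fn,tn Non-negative cell counts; the total must be positive.
#' @return An object of class `contingency_2x2` (named numeric vector).
#' @export
#' @examples
#' contingency_2x2(3982, 38118, 330, 14473)
contingency_2x2 <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0))
    stop("all four cells must be non-negative counts")
  if (sum(cells) <= 0) stop("empty 2x2 table: total count is zero")
  structure(cells, class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(unclass(x)[c("tp", "fp", "fn", "tn")], 2, byrow = TRUE,
              dimnames = list(c("test+", "test-"), c("outcome+", "outcome-")))
  print(m)
  invisible(x)
}

#' Build a 2x2 table for a risk contrast
#'
#' Records whose tier is in `positive_levels` form the test-positive margin;
#' low-tier records form the test-negative margin; records at any other tier
#' are excluded from the table (not pooled), mirroring how two-group
#' screening contrasts are computed against the low-risk referent.
#'
#' @param level Vector of risk tiers, one per record.
#' @param outcome Logical vector, one per record (e.g. the `composite`
#'   column of [composite_morbidity()]).
#' @param positive_levels Non-empty subset of `c("medium", "high")` defining
#'   the test-positive tiers.
#' @return A [contingency_2x2()] object. Errors if no records fall in the
#'   included tiers.
#' @export
#' @examples
#' lv <- c("low", "low", "medium", "high")
#' build_table(lv, c(FALSE, TRUE, TRUE, FALSE), c("medium", "high"))
build_table <- function(level, outcome, positive_levels = c("medium", "high")) {
  positive_levels <- match.arg(positive_levels, c("medium", "high"),
                               several.ok = TRUE)
  level <- as.character(level)
  if (length(level) != length(outcome))
    stop("level and outcome must have one entry per record")
  pos <- level %in% positive_levels
  ref <- level == "low"
  if (!any(pos | ref))
    stop("undefined table: no records at levels ",
         paste(c(positive_levels, "low"), collapse = "/"))
  outcome <- outcome %in% TRUE
  contingency_2x2(tp = sum(pos & outcome), fp = sum(pos & !outcome),
                  fn = sum(ref & outcome), tn = sum(ref & !outcome))
}

.denom <- function(x, what) {
  if (x <= 0) stop("undefined statistic: ", what, " has zero denominator")
  x
}

#' Screening-test accuracy statistics
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(fp+tn)`,
#' `ppv = tp/(tp+fp)`, `npv = tn/(fn+tn)`. Full precision is retained;
#' rounding happens only in reports.
#'
#' @param t A [contingency_2x2()] table.
#' @return A proportion in \[0, 1\]. Errors, naming the statistic, when its
#'   denominator is zero.
#' @name accuracy-statistics
#' @export
sensitivity <- function(t) unname(t["tp"] / .denom(t["tp"] + t["fn"], "sensitivity"))

#' @rdname accuracy-statistics
#' @export
specificity <- function(t) unname(t["tn"] / .denom(t["fp"] + t["tn"], "specificity"))

#' @rdname accuracy-statistics
#' @export
ppv <- function(t) unname(t["tp"] / .denom(t["tp"] + t["fp"], "PPV"))

#' @rdname accuracy-statistics
#' @export
npv <- function(t) unname(t["tn"] / .denom(t["fn"] + t["tn"], "NPV"))

# Haldane-Anscombe: add 0.5 to every cell when any cell is zero.
.corrected_cells <- function(t) {
  cells <- unclass(t)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  list(cells = cells, corrected = corrected)
}

#' Diagnostic odds ratio
#'
#' Cross-product odds ratio `(tp * tn) / (fp * fn)`. When any cell is zero
#' the Haldane-Anscombe correction (add 0.5 to all four cells) is applied
#' first and flagged via the `correction_applied` attribute.
#'
#' @param t A [contingency_2x2()] table.
#' @return The odds ratio (positive numeric) with logical attribute
#'   `correction_applied`.
#' @export
#' @examples
#' diagnostic_or(contingency_2x2(3982, 38118, 330, 14473))
diagnostic_or <- function(t) {
  cc <- .corrected_cells(t)
  cells <- cc$cells
  structure(unname((cells["tp"] * cells["tn"]) / (cells["fp"] * cells["fn"])),
            correction_applied = cc$corrected)
}

#' Woolf confidence interval for the diagnostic odds ratio
#'
#' Log-normal interval: `log(OR) +/- z * sqrt(1/tp + 1/fp + 1/fn + 1/tn)`,
#' exponentiated. Haldane-Anscombe-corrected cells are used when any cell is
#' zero, matching [diagnostic_or()].
#'
#' @param t A [contingency_2x2()] table.
#' @param alpha Two-sided significance level; default 0.05 gives
#'   `z = 1.959964`.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
#' @examples
#' woolf_ci(contingency_2x2(3982, 38118, 330, 14473))
woolf_ci <- function(t, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  cc <- .corrected_cells(t)
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(sum(1 / cc$cells))
  or <- (cc$cells["tp"] * cc$cells["tn"]) / (cc$cells["fp"] * cc$cells["fn"])
  unname(exp(log(or) + c(ci_low = -1, ci_high = 1) * z * se))
}

#' Full diagnostic summary for one 2x2 table
#'
#' @param t A [contingency_2x2()] table.
#' @param alpha Two-sided significance level for the Woolf interval.
#' @return A one-row data frame: `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `dor`, `ci_low`, `ci_high`, `alpha`,
#'   `correction_applied` — all at full precision.
#' @export
diagnostic_summary <- function(t, alpha = 0.05) {
  dor <- diagnostic_or(t)
  ci <- woolf_ci(t, alpha)
  data.frame(
    tp = unname(t["tp"]), fp = unname(t["fp"]),
    fn = unname(t["fn"]), tn = unname(t["tn"]),
    sensitivity = sensitivity(t), specificity = specificity(t),
    ppv = ppv(t), npv = npv(t),
    dor = as.numeric(dor), ci_low = ci[1], ci_high = ci[2],
    alpha = alpha, correction_applied = attr(dor, "correction_applied"))
}

#' Evaluate a classified, scored cohort
#'
#' Produces the incidence table (composite and each component by tier) and
#' the three screening contrasts against the low-risk referent: medium vs
#' low, high vs low, and medium-plus-high vs low.
#'
#' @param level Vector of risk tiers, one per record.
#' @param morbidity Data frame from [composite_morbidity()].
#' @param alpha Significance level for the Woolf intervals.
#' @param outcome Which outcome column of `morbidity` to contrast
#'   (default `"composite"`).
#' @return List with `incidence` (see [incidence_table()]) and `diagnostics`
#'   — one row per contrast with full-precision statistics plus display
#'   columns rounded to 2 decimal places.
#' @export
#' @examples
#' spec <- default_cohort_spec(group_sizes = c(300, 500, 300))
#' cohort <- generate_cohort(spec, seed = 7)
#' ev <- evaluate_cohort(cohort$assigned_level,
#'                       composite_morbidity(cohort[outcome_fields()]))
#' ev$diagnostics[, c("contrast", "dor_2dp")]
evaluate_cohort <- function(level, morbidity, alpha = 0.05,
                            outcome = "composite") {
  stopifnot(outcome %in% names(morbidity))
  contrasts <- list(
    medium_vs_low = "medium",
    high_vs_low = "high",
    medium_high_vs_low = c("medium", "high"))
  rows <- lapply(names(contrasts), function(nm) {
    t <- tryCatch(
      build_table(level, morbidity[[outcome]], contrasts[[nm]]),
      error = function(e) stop("contrast '", nm, "': ", conditionMessage(e),
                               call. = FALSE))
    s <- tryCatch(diagnostic_summary(t, alpha),
                  error = function(e) stop("contrast '", nm, "': ",
                                           conditionMessage(e), call. = FALSE))
    cbind(data.frame(contrast = nm, stringsAsFactors = FALSE), s)
  })
  diag <- do.call(rbind, rows)
  for (col in c("sensitivity", "specificity", "ppv", "npv", "dor",
                "ci_low", "ci_high"))
    diag[[paste0(col, "_2dp")]] <- round(diag[[col]], 2)
  list(incidence = incidence_table(level, morbidity), diagnostics = diag)
}
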