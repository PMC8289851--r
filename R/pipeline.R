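#' Read and validate a cohort CSV
#'
#' Reads a per-delivery cohort table in the ingest schema (see
#' [column_dictionary()]): UTF-8 CSV with a header row, booleans encoded
#' 0/1, missing numerics as empty cells. Rows with every assessment field
#' missing are excluded — such records carry no hemorrhage risk-assessment
#' data — and counted in the ingest log. Malformed cells are reported with
#' their row numbers.
#'
#' @param path Path to the cohort CSV.
#' @param require_outcomes Require the outcome columns too (default `TRUE`;
#'   set `FALSE` to ingest a classification-only table).
#' @return Data frame of typed records. Attributes: `n_read`, `n_excluded`
#'   (all-missing assessment rows), `excluded_rows` (1-based data row
#'   numbers), and `field_missingness` (per-column `NA` counts among kept
#'   rows).
#' @export
ingest_cohort <- function(path, require_outcomes = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  required <- profile_fields()
  if (require_outcomes) required <- c(required, outcome_fields())
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("cohort CSV is missing required column(s): ",
         paste(miss, collapse = ", "))
  bools <- intersect(c(.profile_bool_fields, "icu_admission", "hysterectomy",
                       "dilation_and_curettage"), names(raw))
  bad <- list()
  for (f in bools) {
    v <- raw[[f]]
    badrow <- which(!is.na(v) & !(v %in% c(0, 1, TRUE, FALSE)))
    if (length(badrow)) bad[[f]] <- badrow
    raw[[f]] <- !is.na(v) & v %in% c(1, TRUE)
  }
  nums <- intersect(c(.profile_count_fields, .profile_numeric_fields,
                      "ebl_ml", "prbc_units"), names(raw))
  for (f in nums) {
    v <- raw[[f]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      badrow <- which(!is.na(v) & is.na(conv))
      if (length(badrow)) bad[[f]] <- c(bad[[f]], badrow)
      raw[[f]] <- conv
    }
  }
  if (length(bad)) {
    msg <- vapply(names(bad), function(f)
      paste0(f, " (rows ", paste(utils::head(sort(unique(bad[[f]])), 10),
                                 collapse = ", "), ")"), character(1))
    stop("malformed cells in column(s): ", paste(msg, collapse = "; "))
  }
  # Exclusion rule: no assessment data at all. Booleans read as 0 when
  # blank do not count as data, so missingness is judged on the raw text.
  raw_txt <- utils::read.csv(path, colClasses = "character",
                             na.strings = c("", "NA"))
  assess_txt <- raw_txt[, profile_fields(), drop = FALSE]
  all_missing <- apply(is.na(assess_txt), 1, all)
  kept <- raw[!all_missing, , drop = FALSE]
  rownames(kept) <- NULL
  if ("prbc_units" %in% names(kept))
    kept$prbc_units[is.na(kept$prbc_units)] <- 0
  validate_profiles(kept)
  attr(kept, "n_read") <- nrow(raw)
  attr(kept, "n_excluded") <- sum(all_missing)
  attr(kept, "excluded_rows") <- which(all_missing)
  attr(kept, "field_missingness") <-
    vapply(kept[, intersect(required, names(kept)), drop = FALSE],
           function(v) sum(is.na(v)), numeric(1))
  kept
}

#' Run the full analysis pipeline
#'
#' Ingest, classify, score and evaluate a cohort CSV, writing an incidence
#' table, a diagnostics table, a JSON report, and a run log to the output
#' directory. All analytic thresholds (blood-loss cutoff 1000 mL, BMI 35,
#' platelets 100,000/uL, hematocrit 30, alpha 0.05) are the tool's published
#' defaults; only `alpha` and the blood-loss cutoff are exposed here, and
#' overrides are recorded prominently in the run log.
#'
#' @param input Path to the cohort CSV.
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance level for Woolf intervals. Default 0.05.
#' @param ebl_threshold_ml Blood-loss cutoff defining hemorrhage. Default
#'   1000.
#' @return Invisibly, a list with `incidence`, `diagnostics`, the ingest
#'   `log`, and the paths written. The JSON report is byte-stable across
#'   reruns apart from its single `timestamp` field.
#' @export
run_pipeline <- function(input, out_dir, alpha = 0.05,
                         ebl_threshold_ml = 1000) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- tryCatch(ingest_cohort(input),
                     error = function(e) stop("ingest: ", conditionMessage(e),
                                              call. = FALSE))
  cls <- tryCatch(classify_cohort(cohort),
                  error = function(e) stop("classify: ", conditionMessage(e),
                                           call. = FALSE))
  morb <- tryCatch(
    composite_morbidity(cohort[outcome_fields()], ebl_threshold_ml),
    error = function(e) stop("score: ", conditionMessage(e), call. = FALSE))
  ev <- evaluate_cohort(cls$level, morb, alpha = alpha)

  overrides <- character(0)
  if (alpha != 0.05) overrides <- c(overrides, paste0("alpha=", alpha))
  if (ebl_threshold_ml != 1000)
    overrides <- c(overrides, paste0("ebl_threshold_ml=", ebl_threshold_ml))
  log <- list(
    input = input,
    n_read = attr(cohort, "n_read"),
    n_excluded_no_assessment = attr(cohort, "n_excluded"),
    n_analyzed = nrow(cohort),
    n_missing_ebl = attr(morb, "n_missing_ebl"),
    field_missingness = as.list(attr(cohort, "field_missingness")),
    group_sizes = as.list(table(cls$level)),
    or_correction_applied = any(ev$diagnostics$correction_applied),
    overrides = if (length(overrides)) overrides else "none",
    package_version = as.character(utils::packageVersion("hemrisk")))

  paths <- list(
    incidence = file.path(out_dir, "incidence.csv"),
    diagnostics = file.path(out_dir, "diagnostics.csv"),
    report = file.path(out_dir, "report.json"),
    log = file.path(out_dir, "run_log.json"))
  utils::write.csv(ev$incidence, paths$incidence, row.names = FALSE)
  utils::write.csv(ev$diagnostics, paths$diagnostics, row.names = FALSE)
  report <- list(
    alpha = alpha,
    ebl_threshold_ml = ebl_threshold_ml,
    counts = log[c("n_read", "n_excluded_no_assessment", "n_analyzed")],
    group_sizes = log$group_sizes,
    incidence = ev$incidence,
    diagnostics = ev$diagnostics)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  jsonlite::write_json(c(list(timestamp = format(Sys.time(), tz = "UTC")),
                         log),
                       paths$log, auto_unbox = TRUE, digits = NA)
  invisible(list(incidence = ev$incidence, diagnostics = ev$diagnostics,
                 log = log, paths = paths))
}
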