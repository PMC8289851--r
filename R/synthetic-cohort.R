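#' Synthetic cohort specification
#'
#' Parameters of the synthetic delivery-cohort generator. Outcome rates are
#' parameterised per risk tier as: a hemorrhage Bernoulli probability, and
#' conditional probabilities of transfusion / ICU admission / additional
#' complication given hemorrhage status (the overlap model). The implied
#' composite (union) probability must equal `composite_prob` in each tier;
#' this is checked at construction to within `1e-9`.
#'
#' @param group_sizes Named integer vector `c(low=, medium=, high=)` of
#'   records per tier.
#' @param hemorrhage_prob Named per-tier probability of estimated blood loss
#'   >= 1000 mL.
#' @param composite_prob Named per-tier probability of the composite outcome.
#' @param cond_nh 3x3 matrix (tiers x components `transfusion`, `icu`,
#'   `additional`) of component probabilities given no hemorrhage.
#' @param cond_h Same shape, given hemorrhage.
#' @param misclassification_rate Probability that a record's recorded tier
#'   differs from the tier its risk-factor profile implies. Default 0.
#' @param ebl List of log-normal parameters for estimated blood loss:
#'   `nonhem_meanlog`, `nonhem_sdlog` (body truncated below 1000 mL) and
#'   `hem_meanlog`, `hem_sdlog` (excess over 1000 mL).
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_spec()] for the calibrated defaults,
#'   [generate_cohort()] to sample from a spec.
#' @export
cohort_spec <- function(group_sizes, hemorrhage_prob, composite_prob,
                        cond_nh, cond_h, misclassification_rate = 0,
                        ebl = list(nonhem_meanlog = log(350),
                                   nonhem_sdlog = 0.5,
                                   hem_meanlog = log(250),
                                   hem_sdlog = 0.8)) {
  lv <- risk_levels()
  group_sizes <- round(group_sizes[lv])
  hemorrhage_prob <- hemorrhage_prob[lv]
  composite_prob <- composite_prob[lv]
  cond_nh <- as.matrix(cond_nh)[lv, , drop = FALSE]
  cond_h <- as.matrix(cond_h)[lv, , drop = FALSE]
  problems <- character(0)
  if (any(is.na(group_sizes)) || any(group_sizes < 0))
    problems <- c(problems, "group_sizes must be named non-negative counts for low/medium/high")
  probs <- c(hemorrhage_prob, composite_prob, cond_nh, cond_h,
             misclassification_rate)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1))
    problems <- c(problems, "all probabilities must lie in [0, 1]")
  if (!length(problems)) {
    implied <- hemorrhage_prob +
      (1 - hemorrhage_prob) * (1 - apply(1 - cond_nh, 1, prod))
    off <- abs(implied - composite_prob) > 1e-9
    if (any(off))
      problems <- c(problems, paste0(
        "component model union does not match composite_prob for tier(s): ",
        paste(lv[off], collapse = ", ")))
  }
  if (length(problems))
    stop("invalid cohort spec:\n  - ", paste(problems, collapse = "\n  - "))
  structure(list(group_sizes = group_sizes,
                 hemorrhage_prob = hemorrhage_prob,
                 composite_prob = composite_prob,
                 cond_nh = cond_nh, cond_h = cond_h,
                 misclassification_rate = misclassification_rate,
                 ebl = ebl),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec\n")
  cat("  group sizes: ", paste(names(x$group_sizes), x$group_sizes,
                               sep = "=", collapse = ", "), "\n")
  cat("  hemorrhage prob: ", paste(signif(x$hemorrhage_prob, 4),
                                   collapse = ", "), "\n")
  cat("  composite prob:  ", paste(signif(x$composite_prob, 4),
                                   collapse = ", "), "\n")
  cat("  misclassification rate:", x$misclassification_rate, "\n")
  invisible(x)
}

# Canonical published per-tier counts the default spec is calibrated to.
.calibration_counts <- function() {
  list(n = c(low = 14803, medium = 26163, high = 15937),
       composite = c(low = 330, medium = 2084, high = 1898),
       hemorrhage = c(low = 304, medium = 1986, high = 1822),
       transfusion = c(low = 26, medium = 109, high = 123),
       icu = c(low = 13, medium = 45, high = 41),
       additional = c(low = 0, medium = 2, high = 23))
}

#' Default calibrated cohort spec
#'
#' Returns the generator spec calibrated so that expected per-tier counts of
#' the composite outcome and every component reproduce the published cohort
#' exactly (group sizes 14,803 / 26,163 / 15,937; composite 330 / 2,084 /
#' 1,898; hemorrhage 304 / 1,986 / 1,822; transfusion 26 / 109 / 123; ICU
#' 13 / 45 / 41; additional complications 0 / 2 / 23).
#'
#' The published tables give only marginal component counts, so the overlap
#' between hemorrhage and the other components is under-determined. The
#' default resolves it by taking, within each tier, the no-hemorrhage
#' conditional component probabilities proportional to the component
#' marginals, scaled (by one-dimensional root finding) so the expected
#' no-hemorrhage union equals the composite excess over hemorrhage; the
#' remaining component mass is assigned to hemorrhage records. The solved
#' conditionals are documented constants of the generator, not estimates of
#' the real cohort's joint distribution.
#'
#' @param group_sizes Optional override of the per-tier record counts (e.g.
#'   for small test cohorts); all probabilities stay at the published
#'   calibration.
#' @param misclassification_rate See [cohort_spec()]. Default 0.
#' @return A validated [cohort_spec()].
#' @export
#' @examples
#' spec <- default_cohort_spec()
#' sum(spec$group_sizes)  # 56903
default_cohort_spec <- function(group_sizes = NULL,
                                misclassification_rate = 0) {
  cal <- .calibration_counts()
  lv <- risk_levels()
  comps <- c("transfusion", "icu", "additional")
  p_h <- cal$hemorrhage / cal$n
  p_c <- cal$composite / cal$n
  cond_nh <- cond_h <- matrix(0, 3, 3, dimnames = list(lv, comps))
  for (g in lv) {
    m <- vapply(comps, function(k) cal[[k]][g], numeric(1)) / cal$n[g]
    excess <- p_c[g] - p_h[g]
    f <- function(lam) (1 - p_h[g]) * (1 - prod(1 - lam * m)) - excess
    lam <- stats::uniroot(f, c(0, 1 / (1 - p_h[g])), tol = 1e-14)$root
    t_nh <- lam * m
    cond_nh[g, ] <- t_nh
    cond_h[g, ] <- (m - (1 - p_h[g]) * t_nh) / p_h[g]
  }
  sizes <- if (is.null(group_sizes)) cal$n else {
    if (is.null(names(group_sizes)) && length(group_sizes) == 3)
      names(group_sizes) <- lv
    group_sizes
  }
  cohort_spec(group_sizes = sizes, hemorrhage_prob = p_h,
              composite_prob = p_c, cond_nh = cond_nh, cond_h = cond_h,
              misclassification_rate = misclassification_rate)
}

# Deterministic per-(tier, stage) seed streams: adding a stage or tier never
# perturbs draws in another stream.
.stream_seed <- function(master, level_index, stage) {
  (as.numeric(master) + 7919 * level_index + 104729 * stage) %% (2^31 - 1)
}

# Default sampling weights for which single item makes a profile medium, and
# which route makes it high. Roughly ordered by clinical frequency; any
# positive weights preserve the calibration since classification depends only
# on the tier, not the item.
.medium_item_weights <- c(
  induction_of_labor = 0.34, prior_cesarean_or_uterine_incision = 0.24,
  morbid_obesity = 0.15, grand_multiparity = 0.06, chorioamnionitis = 0.05,
  fetal_macrosomia = 0.05, prior_pph_once = 0.03, polyhydramnios = 0.03,
  multiple_gestation = 0.02, family_history_pph = 0.015,
  large_uterine_fibroids = 0.01, fetal_demise = 0.005)

.high_item_weights <- c(
  thrombocytopenia = 0.28, placenta_previa_low_lying = 0.22,
  prior_pph_multiple = 0.22, active_bleeding = 0.13,
  known_coagulopathy = 0.1, suspected_accreta_or_percreta = 0.05)

# Routes into the high tier: a single unconditional high item, escalation
# via two medium items, or low hematocrit plus one medium item.
.high_route_weights <- c(single_high = 0.55, escalation = 0.35,
                         low_hematocrit = 0.10)

# Base profiles with nothing triggering: numerics drawn in non-triggering
# ranges (hematocrit >= 30 so the conditional rule stays off), with a share
# of each nullable numeric left missing.
.base_profiles <- function(n, p_missing = 0.2) {
  maybe_na <- function(x) {
    x[stats::runif(n) < p_missing] <- NA_real_
    x
  }
  df <- stats::setNames(
    as.data.frame(matrix(FALSE, n, length(.profile_bool_fields))),
    .profile_bool_fields)
  df$prior_vaginal_births <- sample(0:4, n, replace = TRUE,
                                    prob = c(0.35, 0.35, 0.15, 0.1, 0.05))
  df$prior_pph_count <- rep(0L, n)
  df$bmi <- maybe_na(round(stats::runif(n, 19, 35), 1))
  df$estimated_fetal_weight <- maybe_na(round(stats::runif(n, 2.4, 4), 2))
  df$hematocrit <- maybe_na(round(stats::runif(n, 30, 44), 1))
  df$platelets <- maybe_na(round(stats::runif(n, 1.5e5, 4e5)))
  df[profile_fields()]
}

# Force one named item on, adjusting the underlying field.
.apply_item <- function(df, idx, item) {
  if (!length(idx)) return(df)
  switch(item,
    induction_of_labor = {df$labor_induction[idx] <- TRUE},
    grand_multiparity = {df$prior_vaginal_births[idx] <-
      sample(5:8, length(idx), replace = TRUE)},
    prior_cesarean_or_uterine_incision = {
      df$prior_uterine_incision_or_cesarean[idx] <- TRUE},
    large_uterine_fibroids = {df$large_uterine_fibroids[idx] <- TRUE},
    prior_pph_once = {df$prior_pph_count[idx] <- 1L},
    chorioamnionitis = {df$chorioamnionitis[idx] <- TRUE},
    fetal_demise = {df$fetal_demise[idx] <- TRUE},
    morbid_obesity = {df$bmi[idx] <- round(stats::runif(length(idx), 35.5, 52), 1)},
    fetal_macrosomia = {df$estimated_fetal_weight[idx] <-
      round(stats::runif(length(idx), 4.05, 5.2), 2)},
    family_history_pph = {df$family_history_pph_first_degree[idx] <- TRUE},
    polyhydramnios = {df$polyhydramnios[idx] <- TRUE},
    multiple_gestation = {df$multiple_gestation[idx] <- TRUE},
    active_bleeding = {df$active_bleeding_more_than_show[idx] <- TRUE},
    suspected_accreta_or_percreta = {df$suspected_accreta_or_percreta[idx] <- TRUE},
    placenta_previa_low_lying = {df$placenta_previa_or_low_lying[idx] <- TRUE},
    known_coagulopathy = {df$known_coagulopathy[idx] <- TRUE},
    prior_pph_multiple = {df$prior_pph_count[idx] <-
      sample(2:3, length(idx), replace = TRUE, prob = c(0.8, 0.2))},
    thrombocytopenia = {df$platelets[idx] <-
      round(stats::runif(length(idx), 3e4, 9.9e4))},
    stop("unknown item: ", item))
  df
}

.sample_items <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate risk-factor profiles at a target tier
#'
#' Draws `n` profiles whose rule-implied classification equals `level`:
#' low profiles trigger no items; medium profiles trigger exactly one medium
#' item (sampled from a weight table); high profiles take one of three
#' routes — a single unconditional high item, escalation via two distinct
#' medium items, or hematocrit below 30 plus one medium item.
#'
#' @param level Target tier, one of `"low"`, `"medium"`, `"high"`.
#' @param n Number of profiles.
#' @return Data frame of `n` assessment rows; `classify_cohort()` on the
#'   result returns `level` for every row.
#' @export
#' @examples
#' set.seed(1)
#' table(classify_cohort(generate_profiles("medium", 50))$level)
generate_profiles <- function(level, n) {
  level <- match.arg(level, risk_levels())
  df <- .base_profiles(n)
  if (n == 0 || level == "low") return(df)
  if (level == "medium") {
    items <- .sample_items(n, .medium_item_weights)
    for (it in unique(items)) df <- .apply_item(df, which(items == it), it)
    return(df)
  }
  route <- sample(names(.high_route_weights), n, replace = TRUE,
                  prob = .high_route_weights)
  i1 <- which(route == "single_high")
  if (length(i1)) {
    items <- .sample_items(length(i1), .high_item_weights)
    for (it in unique(items)) df <- .apply_item(df, i1[items == it], it)
  }
  i2 <- which(route == "escalation")
  for (k in i2) {
    pair <- sample(names(.medium_item_weights), 2, prob = .medium_item_weights)
    df <- .apply_item(.apply_item(df, k, pair[1]), k, pair[2])
  }
  i3 <- which(route == "low_hematocrit")
  if (length(i3)) {
    df$hematocrit[i3] <- round(stats::runif(length(i3), 22, 29.9), 1)
    items <- .sample_items(length(i3), .medium_item_weights)
    for (it in unique(items)) df <- .apply_item(df, i3[items == it], it)
  }
  df
}

#' Generate a synthetic delivery cohort
#'
#' Samples a full cohort from a [cohort_spec()]: per tier, risk-factor
#' profiles via [generate_profiles()], a hemorrhage Bernoulli draw, then
#' transfusion / ICU / additional-complication draws conditional on
#' hemorrhage status, and estimated blood loss from the spec's log-normal
#' models (below 1000 mL without hemorrhage via inverse-CDF truncation,
#' 1000 mL plus a log-normal excess with hemorrhage). All randomness flows
#' through per-tier, per-stage streams derived from `seed`, so output is
#' byte-reproducible and adding a stage does not perturb earlier draws.
#'
#' With a positive `misclassification_rate`, that share of records keeps its
#' recorded tier (and tier-calibrated outcomes) but receives a profile drawn
#' from a different tier, emulating scoring errors in recorded data.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return Data frame with the 19 assessment columns, `assigned_level`
#'   (ordered factor — the recorded tier), and the 5 outcome columns.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(c(200, 300, 200)), seed = 1)
#' table(cohort$assigned_level)
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  lv <- risk_levels()
  parts <- vector("list", 3)
  for (i in seq_along(lv)) {
    g <- lv[i]
    n <- spec$group_sizes[[g]]
    if (n == 0) next
    withseed <- function(stage, expr) {
      set.seed(.stream_seed(seed, i, stage))
      expr
    }
    prof <- withseed(1, {
      if (spec$misclassification_rate > 0 && n > 0) {
        flip <- stats::runif(n) < spec$misclassification_rate
        src <- rep(as.character(g), n)
        src[flip] <- sample(setdiff(lv, g), sum(flip), replace = TRUE)
        out <- stats::setNames(vector("list", 3), lv)
        for (s in lv) {
          k <- which(src == s)
          if (length(k)) {
            p <- generate_profiles(s, length(k))
            p$.row <- k
            out[[s]] <- p
          }
        }
        df <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
        df <- df[order(df$.row), ]
        df$.row <- NULL
        rownames(df) <- NULL
        df
      } else generate_profiles(g, n)
    })
    hem <- withseed(2, stats::runif(n) < spec$hemorrhage_prob[[g]])
    comps <- withseed(3, {
      u <- matrix(stats::runif(3 * n), n, 3)
      p <- matrix(spec$cond_nh[g, ], n, 3, byrow = TRUE)
      if (any(hem))
        p[hem, ] <- matrix(spec$cond_h[g, ], sum(hem), 3, byrow = TRUE)
      u < p
    })
    ebl <- withseed(4, {
      e <- numeric(n)
      nh <- !hem
      if (any(nh)) {
        pmax_u <- stats::plnorm(1000, spec$ebl$nonhem_meanlog,
                                spec$ebl$nonhem_sdlog)
        e[nh] <- stats::qlnorm(stats::runif(sum(nh)) * pmax_u,
                               spec$ebl$nonhem_meanlog, spec$ebl$nonhem_sdlog)
      }
      if (any(hem))
        e[hem] <- 1000 + stats::rlnorm(sum(hem), spec$ebl$hem_meanlog,
                                       spec$ebl$hem_sdlog)
      round(e)
    })
    units <- withseed(5, ifelse(comps[, 1], 1L + stats::rpois(n, 1), 0L))
    addl <- withseed(6, {
      hyst <- comps[, 3] & stats::runif(n) < 0.2
      list(hysterectomy = hyst, dnc = comps[, 3] & !hyst)
    })
    parts[[i]] <- cbind(
      prof,
      data.frame(assigned_level = rep(g, n),
                 ebl_ml = ebl, prbc_units = units,
                 icu_admission = comps[, 2],
                 hysterectomy = addl$hysterectomy,
                 dilation_and_curettage = addl$dnc,
                 stringsAsFactors = FALSE))
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) stop("cohort spec has no records (all group sizes 0)")
  cohort <- do.call(rbind, parts)
  cohort$assigned_level <- factor(cohort$assigned_level, levels = lv,
                                  ordered = TRUE)
  rownames(cohort) <- NULL
  cohort
}

#' Write a cohort to CSV in the ingest schema
#'
#' Booleans are encoded 0/1 and missing numerics as empty cells, matching
#' [ingest_cohort()] and the [column_dictionary()].
#'
#' @param cohort Data frame from [generate_cohort()] or of the same shape.
#' @param path Output file path.
#' @param include_assigned_level Keep the generator's recorded tier as an
#'   extra `assigned_level` column (ignored by ingest). Default `FALSE`.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path, include_assigned_level = FALSE) {
  cols <- c(profile_fields(), outcome_fields())
  out <- cohort[, cols, drop = FALSE]
  bools <- c(.profile_bool_fields, "icu_admission", "hysterectomy",
             "dilation_and_curettage")
  for (f in bools) out[[f]] <- as.integer(as.logical(out[[f]]))
  if (include_assigned_level)
    out$assigned_level <- as.character(cohort$assigned_level)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
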