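check_dialect <- function(dialect) {
  if (length(dialect) != 1L || !dialect %in% ANC_DIALECTS)
    stop("unknown dialect: must be one of ", paste(ANC_DIALECTS, collapse = ", "),
         call. = FALSE)
  dialect
}

#' Tetanus vaccination coverage
#'
#' Proportion of pregnancies vaccinated according to guidelines: immune at
#' entry, or — when immunity is unknown or absent — given a (booster) dose
#' during the pregnancy. Pregnancies with missing vaccination data count in
#' the denominator as unvaccinated (conservative rule), which is what makes
#' the paper-record dialect's higher missingness bite.
#'
#' @param cohort An `anc_cohort` or data frame with the cohort schema.
#' @param dialect `"paper"` or `"eregistry"` (validated; both dialects share
#'   the numerator rule and differ through their recorded missingness).
#' @return A single proportion.
#' @export
tetanus_coverage <- function(cohort, dialect = attr(cohort, "dialect")) {
  check_dialect(dialect)
  require_cols(cohort, c("pregnancy_id", "gestational_age", "tetanus_status",
                         "tetanus_dose_given"))
  ctx <- preg_context(cohort)
  status <- ctx$df$tetanus_status[ctx$first]
  dosed <- ctx_any(ctx, ctx$df$tetanus_dose_given %in% TRUE)
  covered <- (!is.na(status) & status == "immune") | dosed
  mean(covered)
}

#' Iron-folate supplementation coverage
#'
#' Paper dialect: the single given/not-given checkbox proportion. eRegistry
#' dialect: the proportion correctly supplemented given measured anemia
#' status — anemic women (any attended-visit hemoglobin below the anemia cut)
#' with a treatment dose recorded, non-anemic women with routine
#' supplementation recorded — pooled over the cohort. Missing supplementation
#' records count as not supplemented.
#'
#' @inheritParams tetanus_coverage
#' @param thresholds A [clinical_thresholds()] object (anemia cut for the
#'   eRegistry rule).
#' @return A single proportion.
#' @export
iron_folate_coverage <- function(cohort, dialect = attr(cohort, "dialect"),
                                 thresholds = clinical_thresholds()) {
  check_dialect(dialect)
  require_cols(cohort, c("pregnancy_id", "gestational_age", "iron_folate",
                         "hemoglobin"))
  ctx <- preg_context(cohort)
  if (dialect == "paper") {
    given <- ctx_any(ctx, ctx$df$iron_folate %in% TRUE)
    return(mean(given))
  }
  anemic <- ctx_any(ctx, !is.na(ctx$df$hemoglobin) &
                      ctx$df$hemoglobin < thresholds$anemia_cut)
  treated <- ctx_any(ctx, ctx$df$iron_folate %in% "treatment")
  routine <- ctx_any(ctx, ctx$df$iron_folate %in% "routine")
  mean(ifelse(anemic, treated, routine))
}

#' Health-status indicators: anemia, severe anemia, low BMI
#'
#' Anemia: any attended-visit hemoglobin strictly below the anemia cut
#' (11 g/dl default), at any point during the pregnancy. Severe anemia:
#' likewise against the severe cut (7 g/dl). Low BMI: booking-visit BMI
#' strictly below 18.5 kg/m^2. Pregnancies with the measurement entirely
#' missing do not count as cases (conservative denominator-complete rule).
#'
#' @inheritParams iron_folate_coverage
#' @return Named numeric vector `c(anemia, severe_anemia, low_bmi)`.
#' @export
health_status_indicators <- function(cohort, thresholds = clinical_thresholds()) {
  require_cols(cohort, c("pregnancy_id", "gestational_age", "hemoglobin", "bmi"))
  ctx <- preg_context(cohort)
  hb <- ctx$df$hemoglobin
  anemia <- ctx_any(ctx, !is.na(hb) & hb < thresholds$anemia_cut)
  severe <- ctx_any(ctx, !is.na(hb) & hb < thresholds$severe_anemia_cut)
  bmi0 <- ctx$df$bmi[ctx$first]
  low <- !is.na(bmi0) & bmi0 < thresholds$low_bmi_cut
  c(anemia = mean(anemia), severe_anemia = mean(severe), low_bmi = mean(low))
}

#' Assemble the full indicator set for one record-level source
#'
#' Runs the three cascades and the tetanus, iron-folate and health-status
#' indicators on a record-level cohort and packages them as the indicator
#' block for one data source and year. Record dialects supply all five
#' coverage and all three health-status indicators directly; availability
#' gaps belong to the aggregate-source estimators.
#'
#' @inheritParams iron_folate_coverage
#' @param year Calendar year the indicators describe.
#' @return An object of class `indicator_set`: source dialect, year, the five
#'   coverage proportions, the three health-status proportions, availability
#'   tags (all `"direct"`) and the underlying `cascade_result`s.
#' @export
indicator_set <- function(cohort, dialect = attr(cohort, "dialect"),
                          thresholds = clinical_thresholds(), year = 2017L) {
  check_dialect(dialect)
  dia <- diabetes_cascade(cohort, thresholds)
  htn <- hypertension_cascade(cohort, thresholds)
  pre <- preeclampsia_cascade(cohort, thresholds)
  cov <- c(diabetes_mgmt = dia$coverage,
           htn_mgmt = htn$coverage,
           preeclampsia_mgmt = pre$coverage,
           tetanus = tetanus_coverage(cohort, dialect),
           iron_folate = iron_folate_coverage(cohort, dialect, thresholds))
  hs <- health_status_indicators(cohort, thresholds)
  new_indicator_set(dialect, year, cov, hs,
                    availability = stats::setNames(rep("direct", 8L),
                                                   c(ANC_INTERVENTIONS, ANC_HEALTH_STATUS)),
                    cascades = list(diabetes = dia, hypertension = htn,
                                    preeclampsia = pre))
}

new_indicator_set <- function(source_dialect, year, coverage, health_status,
                              availability, cascades = NULL) {
  stopifnot(all(ANC_INTERVENTIONS %in% names(coverage)),
            all(ANC_HEALTH_STATUS %in% names(health_status)))
  ok <- !is.na(coverage)
  if (any(coverage[ok] < 0 | coverage[ok] > 1))
    stop("coverage proportions must lie in [0, 1]", call. = FALSE)
  structure(list(
    source_dialect = source_dialect,
    year = year,
    coverage = coverage[ANC_INTERVENTIONS],
    health_status = health_status[ANC_HEALTH_STATUS],
    availability = availability,
    cascades = cascades
  ), class = "indicator_set")
}

#' @export
print.indicator_set <- function(x, digits = 3, ...) {
  cat(sprintf("Antenatal indicator set — source: %s, year: %s\n",
              x$source_dialect, x$year))
  fmt <- function(v, avail) {
    ifelse(is.na(v), sprintf("unavailable (%s)", avail),
           formatC(v, digits = digits, format = "f"))
  }
  cat("  coverage:\n")
  for (k in ANC_INTERVENTIONS)
    cat(sprintf("    %-18s %s\n", k, fmt(x$coverage[[k]], x$availability[[k]])))
  cat("  health status:\n")
  for (k in ANC_HEALTH_STATUS)
    cat(sprintf("    %-18s %s\n", k,
                fmt(x$health_status[[k]], x$availability[[k]])))
  invisible(x)
}

#' @export
as.data.frame.indicator_set <- function(x, ...) {
  data.frame(
    source = x$source_dialect,
    year = x$year,
    indicator = c(names(x$coverage), names(x$health_status)),
    type = c(rep("coverage", length(x$coverage)),
             rep("health_status", length(x$health_status))),
    value = unname(c(x$coverage, x$health_status)),
    availability = unname(x$availability[c(names(x$coverage),
                                           names(x$health_status))]),
    row.names = NULL
  )
}
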