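require_cols <- function(cohort, cols) {
  miss <- setdiff(cols, names(cohort))
  if (length(miss))
    stop("cohort schema error: missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

## Per-pregnancy aggregation context: cohort rows ordered by pregnancy and
## gestational age, with a factor keyed in first-appearance (numeric) order.
preg_context <- function(cohort) {
  df <- as.data.frame(cohort)
  ord <- order(df$pregnancy_id, df$gestational_age)
  df <- df[ord, , drop = FALSE]
  pidf <- factor(df$pregnancy_id, levels = unique(df$pregnancy_id))
  list(df = df, pidf = pidf, first = !duplicated(pidf),
       n = nlevels(pidf))
}

ctx_any <- function(ctx, x) {
  as.vector(tapply(x, ctx$pidf, function(v) any(v, na.rm = TRUE)))
}
ctx_all <- function(ctx, x) {
  as.vector(tapply(x, ctx$pidf, function(v) all(v)))
}
## first gestational age at which `flag` holds, NA when never
ctx_min_ga <- function(ctx, flag) {
  g <- ifelse(flag %in% TRUE, ctx$df$gestational_age, NA_integer_)
  as.vector(tapply(g, ctx$pidf, function(v)
    if (all(is.na(v))) NA_integer_ else min(v, na.rm = TRUE)))
}

#' Construct a screening-and-management cascade result
#'
#' Holds the eligible -> correctly-screened -> screen-positive ->
#' correctly-managed counts and the resulting effective-coverage proportion,
#' decomposed as the product of the screening-stage proportion
#' (screened / eligible) and the management-stage proportion
#' (managed / positive). When no positives were detected the management stage
#' has an empty denominator: coverage is reported as 0 and flagged undefined.
#'
#' @param eligible_n,screened_correctly_n,positive_n,correctly_managed_n
#'   Monotone non-increasing counts.
#' @param label Cascade name.
#' @return An object of class `cascade_result`.
#' @export
cascade_result <- function(eligible_n, screened_correctly_n, positive_n,
                           correctly_managed_n, label = "cascade") {
  counts <- c(eligible_n, screened_correctly_n, positive_n, correctly_managed_n)
  if (any(counts < 0) || any(diff(counts) > 0))
    stop("cascade counts must satisfy eligible >= screened >= positive >= managed >= 0",
         call. = FALSE)
  screening_stage <- if (eligible_n > 0) screened_correctly_n / eligible_n else 0
  management_stage <- if (positive_n > 0) correctly_managed_n / positive_n else NA_real_
  undefined <- positive_n == 0 || eligible_n == 0
  coverage <- if (undefined) 0 else screening_stage * management_stage
  structure(list(
    label = label,
    eligible_n = eligible_n,
    screened_correctly_n = screened_correctly_n,
    positive_n = positive_n,
    correctly_managed_n = correctly_managed_n,
    screening_stage = screening_stage,
    management_stage = management_stage,
    coverage = coverage,
    undefined = undefined
  ), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("%s cascade\n", x$label))
  cat(sprintf("  eligible %d -> screened correctly %d -> positive %d -> managed %d\n",
              x$eligible_n, x$screened_correctly_n, x$positive_n,
              x$correctly_managed_n))
  if (x$undefined) {
    cat("  coverage: 0 (undefined: empty positive-case denominator)\n")
  } else {
    cat(sprintf("  coverage: %.4f (screening %.4f x management %.4f)\n",
                x$coverage, x$screening_stage, x$management_stage))
  }
  invisible(x)
}

#' Diabetes screening-and-management cascade
#'
#' Guideline pathway: urine sugar testing at the booking visit for every
#' woman; a blood sugar test within the 24-28 week window for women not
#' already urine-sugar positive; a glucose challenge test when either screen
#' is positive. A challenge result strictly above 140 mg/dl is a positive
#' case; correct management is referral, judged at the clinic regardless of
#' whether the woman followed through. A test outside its window does not
#' count as correct screening; missing required screening data counts as not
#' screened.
#'
#' @param cohort An `anc_cohort` (paper or eregistry dialect) or a data frame
#'   with the cohort schema.
#' @param thresholds A [clinical_thresholds()] object.
#' @return A [cascade_result()].
#' @export
diabetes_cascade <- function(cohort, thresholds = clinical_thresholds()) {
  require_cols(cohort, c("pregnancy_id", "gestational_age", "urine_sugar",
                         "blood_sugar", "glucose_challenge_mgdl", "referral"))
  ctx <- preg_context(cohort)
  df <- ctx$df
  w <- thresholds$blood_sugar_window

  us_booking <- df$urine_sugar[ctx$first]
  us_done <- !is.na(us_booking)
  us_pos <- !is.na(us_booking) & us_booking == "positive"

  in_window <- df$gestational_age >= w[1] & df$gestational_age <= w[2]
  bs_done <- ctx_any(ctx, in_window & !is.na(df$blood_sugar))
  bs_pos <- ctx_any(ctx, in_window & !is.na(df$blood_sugar) &
                      df$blood_sugar == "positive")
  gct_done <- ctx_any(ctx, !is.na(df$glucose_challenge_mgdl))
  gct_pos <- ctx_any(ctx, !is.na(df$glucose_challenge_mgdl) &
                       df$glucose_challenge_mgdl > thresholds$glucose_challenge_cut)
  referred <- ctx_any(ctx, df$referral != "none")

  indicated <- us_pos | bs_pos
  screened <- us_done & (us_pos | bs_done) & (!indicated | gct_done)
  positive <- screened & gct_pos
  managed <- positive & referred

  cascade_result(ctx$n, sum(screened), sum(positive), sum(managed),
                 label = "diabetes management")
}

#' Hypertensive-disorders screening-and-management cascade
#'
#' Correct screening is a blood pressure measurement at every attended visit.
#' A positive case is any observed hypertensive reading (systolic >= 140 or
#' diastolic >= 90 by default). Chronic hypertension (observed at or before 20
#' weeks) and moderate/severe readings (>= 160/110) are correctly managed by
#' referral; mild gestational hypertension is correctly managed by a urine
#' protein work-up at or after detection.
#'
#' @inheritParams diabetes_cascade
#' @return A [cascade_result()].
#' @export
hypertension_cascade <- function(cohort, thresholds = clinical_thresholds()) {
  require_cols(cohort, c("pregnancy_id", "gestational_age", "systolic_bp",
                         "diastolic_bp", "urine_protein", "referral"))
  ctx <- preg_context(cohort)
  df <- ctx$df

  bp_done_row <- !is.na(df$systolic_bp) & !is.na(df$diastolic_bp)
  elev_row <- bp_done_row & (df$systolic_bp >= thresholds$htn_sys_cut |
                               df$diastolic_bp >= thresholds$htn_dia_cut)
  sev_row <- bp_done_row & (df$systolic_bp >= thresholds$severe_sys_cut |
                              df$diastolic_bp >= thresholds$severe_dia_cut)

  screened <- ctx_all(ctx, bp_done_row)
  any_elev <- ctx_any(ctx, elev_row)
  chronic <- ctx_any(ctx, elev_row & df$gestational_age <= 20L)
  severe <- ctx_any(ctx, sev_row)
  first_elev <- ctx_min_ga(ctx, elev_row)
  nv <- as.vector(table(ctx$pidf))
  prot_after <- ctx_any(ctx, !is.na(df$urine_protein) &
                          df$gestational_age >= rep(first_elev, nv))
  referred <- ctx_any(ctx, df$referral != "none")

  positive <- screened & any_elev
  mild <- positive & !chronic & !severe
  managed <- (mild & prot_after) | (positive & (chronic | severe) & referred)

  cascade_result(ctx$n, sum(screened), sum(positive), sum(managed),
                 label = "hypertensive disorders management")
}

#' Pre-eclampsia screening-and-management cascade
#'
#' Correct screening requires blood pressure at every visit plus a urine
#' protein test following an observed hypertensive reading after 20 weeks
#' gestation. A positive case is hypertension after 20 weeks with positive
#' proteinuria (optionally, a recorded symptom flag). Correct management is
#' hospital referral; referral censoring is honored — a referred pregnancy is
#' managed even though her later clinic visits are absent.
#'
#' @inheritParams diabetes_cascade
#' @param include_symptoms If `TRUE` and the cohort carries a logical
#'   `pe_symptoms` column, a symptomatic hypertensive woman counts as positive
#'   without proteinuria. Default off.
#' @return A [cascade_result()].
#' @export
preeclampsia_cascade <- function(cohort, thresholds = clinical_thresholds(),
                                 include_symptoms = FALSE) {
  require_cols(cohort, c("pregnancy_id", "gestational_age", "systolic_bp",
                         "diastolic_bp", "urine_protein", "referral"))
  ctx <- preg_context(cohort)
  df <- ctx$df
  wk <- thresholds$proteinuria_min_week

  bp_done_row <- !is.na(df$systolic_bp) & !is.na(df$diastolic_bp)
  elev20_row <- bp_done_row & df$gestational_age > wk &
    (df$systolic_bp >= thresholds$htn_sys_cut |
       df$diastolic_bp >= thresholds$htn_dia_cut)

  screened_bp <- ctx_all(ctx, bp_done_row)
  htn20 <- ctx_any(ctx, elev20_row)
  first_elev20 <- ctx_min_ga(ctx, elev20_row)
  nv <- as.vector(table(ctx$pidf))
  prot_done_after <- ctx_any(ctx, !is.na(df$urine_protein) &
                               df$gestational_age >= rep(first_elev20, nv))
  prot_pos <- ctx_any(ctx, !is.na(df$urine_protein) &
                        df$urine_protein == "positive" &
                        df$gestational_age > wk)
  hosp <- ctx_any(ctx, df$referral == "hospital")

  screened <- screened_bp & (!htn20 | prot_done_after)
  positive <- screened & htn20 & prot_pos
  if (include_symptoms && "pe_symptoms" %in% names(df)) {
    sympt <- ctx_any(ctx, df$pe_symptoms %in% TRUE)
    positive <- positive | (screened & htn20 & sympt)
  }
  managed <- positive & hosp

  cascade_result(ctx$n, sum(screened), sum(positive), sum(managed),
                 label = "pre-eclampsia management")
}
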