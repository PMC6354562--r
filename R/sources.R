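#' Management coverage from routine-report aggregates
#'
#' Routine reports count referrals, not true cases, so coverage is estimated
#' as referred cases over an expected-case denominator: pregnancies registered
#' times an externally supplied incidence (in practice borrowed from a
#' record-level review). Because numerator and denominator come from different
#' reporting levels the ratio can exceed 1; it is then capped at 1 with a
#' warning rather than treated as an error.
#'
#' @param referred Count of cases referred.
#' @param registered Count of pregnancies registered (> 0).
#' @param incidence Condition incidence among registered pregnancies (> 0).
#' @return A single proportion in [0, 1].
#' @examples
#' routine_management_coverage(36, 1000, 0.05)  # 0.72
#' @export
routine_management_coverage <- function(referred, registered, incidence) {
  if (!is.numeric(referred) || referred < 0)
    stop("referred must be a non-negative count", call. = FALSE)
  if (!is.numeric(registered) || registered <= 0 ||
      !is.numeric(incidence) || incidence <= 0)
    stop("undefined indicator: registered and incidence must be positive",
         call. = FALSE)
  ratio <- referred / (registered * incidence)
  if (ratio > 1) {
    warning(sprintf(
      "routine indicator saturated: referred (%g) exceeds expected cases (%g); capping coverage at 1 (possible over-reporting)",
      referred, registered * incidence), call. = FALSE)
    ratio <- 1
  }
  ratio
}

#' Indirect effective coverage from survey inputs
#'
#' Household surveys report contact coverage (attendance), not effective
#' coverage. The default crosswalk multiplies contact coverage by a
#' readiness/quality fraction, so the estimate can never exceed contact
#' coverage. The estimator is a pluggable strategy: pass `method` to
#' substitute a published indirect formula that maps the same inputs to a
#' coverage proportion.
#'
#' @param contact_coverage Proportion of women attending antenatal care.
#' @param quality_fraction Readiness/quality adjustment in [0, 1].
#' @param method Optional `function(contact_coverage, quality_fraction)`
#'   returning a proportion; defaults to the product crosswalk.
#' @return A single proportion in [0, 1].
#' @examples
#' indirect_effective_coverage(0.8, 0.5)  # 0.40
#' @export
indirect_effective_coverage <- function(contact_coverage, quality_fraction,
                                        method = NULL) {
  check_prob(contact_coverage, "contact_coverage")
  check_prob(quality_fraction, "quality_fraction")
  if (is.null(method)) method <- function(cc, qf) cc * qf
  out <- method(contact_coverage, quality_fraction)
  check_prob(out, "indirect coverage estimate")
  out
}

#' Indicator availability by data source
#'
#' Which of the five coverage and three health-status indicators each data
#' source can populate, and whether directly or only through an indirect
#' survey-based estimator. Routine reports populate two coverage indicators
#' directly; the household survey populates three indirectly; record-level
#' sources (paper records, eRegistry) populate all eight directly.
#' Unavailable indicators are explicit `"unavailable"` markers, never zeros.
#'
#' @param source One of `"routine"`, `"mics"`, `"paper"`, `"eregistry"`.
#' @return Named character vector over the eight indicators with values
#'   `"direct"`, `"indirect"` or `"unavailable"`.
#' @export
available_indicators <- function(source) {
  if (length(source) != 1L || !source %in% ANC_SOURCES)
    stop("unknown source: must be one of ", paste(ANC_SOURCES, collapse = ", "),
         call. = FALSE)
  ind <- c(ANC_INTERVENTIONS, ANC_HEALTH_STATUS)
  out <- stats::setNames(rep("unavailable", length(ind)), ind)
  switch(source,
    routine = {
      out[c("diabetes_mgmt", "preeclampsia_mgmt")] <- "direct"
    },
    mics = {
      out[c("diabetes_mgmt", "htn_mgmt", "preeclampsia_mgmt")] <- "indirect"
    },
    paper = ,
    eregistry = {
      out[] <- "direct"
    })
  out
}

#' Indicator set from routine-report aggregates
#'
#' @param referred_diabetes,referred_preeclampsia Referral counts.
#' @param pregnancies_registered Registered pregnancies (> 0).
#' @param incidence_diabetes,incidence_preeclampsia Incidences borrowed from a
#'   record-level source.
#' @param year Calendar year.
#' @return An `indicator_set` with the two routine coverage indicators
#'   populated and the rest explicitly unavailable.
#' @export
routine_indicator_set <- function(referred_diabetes, referred_preeclampsia,
                                  pregnancies_registered,
                                  incidence_diabetes, incidence_preeclampsia,
                                  year = 2016L) {
  cov <- stats::setNames(rep(NA_real_, 5L), ANC_INTERVENTIONS)
  cov[["diabetes_mgmt"]] <- routine_management_coverage(
    referred_diabetes, pregnancies_registered, incidence_diabetes)
  cov[["preeclampsia_mgmt"]] <- routine_management_coverage(
    referred_preeclampsia, pregnancies_registered, incidence_preeclampsia)
  hs <- stats::setNames(rep(NA_real_, 3L), ANC_HEALTH_STATUS)
  new_indicator_set("routine", year, cov, hs, available_indicators("routine"))
}

#' Indicator set from survey contact coverage (indirect estimates)
#'
#' @param contact_coverage Antenatal care attendance proportion.
#' @param quality_fraction Named or scalar readiness/quality fraction; a named
#'   vector may give a different fraction per management indicator
#'   (`diabetes_mgmt`, `htn_mgmt`, `preeclampsia_mgmt`).
#' @param year Calendar year.
#' @param method Optional indirect estimator, see
#'   [indirect_effective_coverage()].
#' @return An `indicator_set` with the three management indicators populated
#'   indirectly and the rest explicitly unavailable.
#' @export
survey_indicator_set <- function(contact_coverage, quality_fraction,
                                 year = 2014L, method = NULL) {
  targets <- c("diabetes_mgmt", "htn_mgmt", "preeclampsia_mgmt")
  qf <- if (length(quality_fraction) == 1L && is.null(names(quality_fraction)))
    stats::setNames(rep(quality_fraction, 3L), targets) else quality_fraction
  cov <- stats::setNames(rep(NA_real_, 5L), ANC_INTERVENTIONS)
  for (k in targets)
    cov[[k]] <- indirect_effective_coverage(contact_coverage, qf[[k]], method)
  hs <- stats::setNames(rep(NA_real_, 3L), ANC_HEALTH_STATUS)
  new_indicator_set("mics", year, cov, hs, available_indicators("mics"))
}
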