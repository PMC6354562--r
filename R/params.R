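#' @keywords internal
"_PACKAGE"

## Canonical intervention and indicator names used across the package.
ANC_INTERVENTIONS <- c("diabetes_mgmt", "htn_mgmt", "preeclampsia_mgmt",
                       "tetanus", "iron_folate")
ANC_HEALTH_STATUS <- c("anemia", "severe_anemia", "low_bmi")
ANC_DIALECTS      <- c("paper", "eregistry")
ANC_SOURCES       <- c("routine", "mics", "paper", "eregistry")

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is_prob(x)) stop_config(field, "must be a single probability in [0, 1]")
  invisible(x)
}

check_prob_map <- function(x, field, required = NULL) {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop_config(field, "must be a named numeric vector of probabilities")
  if (any(is.na(x)) || any(x < 0) || any(x > 1))
    stop_config(field, "must contain probabilities in [0, 1]")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop_config(field, paste0("is missing entries: ", paste(missing, collapse = ", ")))
  invisible(x)
}

#' Parameters for the synthetic antenatal cohort generator
#'
#' Bundles and validates every knob of the synthetic longitudinal cohort:
#' latent condition frequencies, screening and management compliance by
#' clinical pathway, field-level missingness, the visit schedule and the
#' random seed. Defaults describe a West Bank-like antenatal population
#' attending public primary-care clinics.
#'
#' @param n_pregnancies Number of pregnancies to simulate (>= 1).
#' @param incidence_diabetes Latent gestational/pre-existing diabetes probability.
#' @param incidence_chronic_htn Latent chronic hypertension probability.
#' @param incidence_gest_htn_mild Latent mild gestational hypertension probability.
#' @param incidence_gest_htn_modsev Latent moderate/severe gestational
#'   hypertension probability.
#' @param incidence_preeclampsia Marginal pre-eclampsia probability; pre-eclampsia
#'   only arises among hypertensive pregnancies after 20 weeks, so it must not
#'   exceed the sum of the hypertension incidences.
#' @param anemia_hb_mean,anemia_hb_sd Mean and SD (g/dl) of the per-pregnancy
#'   hemoglobin level for the non-severe majority.
#' @param severe_anemia_floor Probability of drawing a severely anemic pregnancy
#'   (hemoglobin below 7 g/dl) regardless of the normal component.
#' @param low_bmi_prob Probability of booking BMI below 18.5 kg/m^2.
#' @param tetanus_immune_at_entry_prob Probability a woman enters pregnancy
#'   already fully vaccinated.
#' @param screening_compliance Named probabilities, one per screening pathway
#'   (`diabetes`, `hypertension`, `preeclampsia`): the chance the clinic runs
#'   that pathway completely and on time for a given pregnancy.
#' @param management_compliance Named probabilities (`diabetes`, `hypertension`,
#'   `preeclampsia`, `tetanus`, `iron_folate`): the chance a positive/eligible
#'   woman receives the guideline management (referral, proteinuria work-up,
#'   booster dose, correct supplement type).
#' @param iron_folate_given_prob Probability any iron-folate supplement is given.
#' @param missingness Named probabilities of a recorded value being absent:
#'   `tetanus` (per pregnancy), `tetanus_paper` (per-pregnancy rate after
#'   degradation to the paper dialect), `hemoglobin`, `bmi`, `iron_folate`.
#' @param visit_schedule Strictly increasing gestational weeks (<= 44) at which
#'   routine visits after booking occur; must include a week in the 24-28
#'   blood-sugar window for the diabetes pathway to be completable.
#' @param booking_week_range Integer range (length 2) the booking week is drawn
#'   uniformly from.
#' @param public_sector_prob Probability a pregnancy attends a public clinic.
#' @param seed Integer seed; identical parameters imply identical cohorts.
#'
#' @return An object of class `cohort_params` (a validated list).
#' @examples
#' p <- cohort_params(n_pregnancies = 50, seed = 1)
#' p$incidence_diabetes
#' @export
cohort_params <- function(n_pregnancies,
                          incidence_diabetes = 0.06,
                          incidence_chronic_htn = 0.01,
                          incidence_gest_htn_mild = 0.04,
                          incidence_gest_htn_modsev = 0.015,
                          incidence_preeclampsia = 0.02,
                          anemia_hb_mean = 11.4,
                          anemia_hb_sd = 1.25,
                          severe_anemia_floor = 0.002,
                          low_bmi_prob = 0.035,
                          tetanus_immune_at_entry_prob = 0.55,
                          screening_compliance = c(diabetes = 0.85,
                                                   hypertension = 0.8,
                                                   preeclampsia = 0.75),
                          management_compliance = c(diabetes = 0.5,
                                                    hypertension = 0.35,
                                                    preeclampsia = 0.7,
                                                    tetanus = 0.8,
                                                    iron_folate = 0.75),
                          iron_folate_given_prob = 0.9,
                          missingness = c(tetanus = 0.07,
                                          tetanus_paper = 0.42,
                                          hemoglobin = 0.03,
                                          bmi = 0.03,
                                          iron_folate = 0.02),
                          visit_schedule = c(12, 16, 20, 24, 28, 32, 36, 40),
                          booking_week_range = c(8, 16),
                          public_sector_prob = 1,
                          seed = 1L) {
  if (!is.numeric(n_pregnancies) || length(n_pregnancies) != 1L ||
      is.na(n_pregnancies) || n_pregnancies < 1)
    stop_config("n_pregnancies", "must be a count >= 1")
  n_pregnancies <- as.integer(n_pregnancies)

  for (f in c("incidence_diabetes", "incidence_chronic_htn",
              "incidence_gest_htn_mild", "incidence_gest_htn_modsev",
              "incidence_preeclampsia", "severe_anemia_floor", "low_bmi_prob",
              "tetanus_immune_at_entry_prob", "iron_folate_given_prob",
              "public_sector_prob"))
    check_prob(get(f), f)

  htn_total <- incidence_chronic_htn + incidence_gest_htn_mild +
    incidence_gest_htn_modsev
  if (incidence_preeclampsia > htn_total + 1e-12)
    stop_config("incidence_preeclampsia",
                "cannot exceed the summed hypertension incidences")

  check_prob_map(screening_compliance, "screening_compliance",
                 c("diabetes", "hypertension", "preeclampsia"))
  check_prob_map(management_compliance, "management_compliance",
                 c("diabetes", "hypertension", "preeclampsia", "tetanus",
                   "iron_folate"))
  check_prob_map(missingness, "missingness",
                 c("tetanus", "tetanus_paper", "hemoglobin", "bmi",
                   "iron_folate"))

  if (!is.numeric(anemia_hb_mean) || anemia_hb_mean <= 2 || anemia_hb_mean >= 20)
    stop_config("anemia_hb_mean", "must be a plausible g/dl value in (2, 20)")
  if (!is.numeric(anemia_hb_sd) || anemia_hb_sd <= 0)
    stop_config("anemia_hb_sd", "must be positive")

  if (length(visit_schedule) == 0L)
    stop_config("visit_schedule", "must be non-empty")
  if (any(diff(visit_schedule) <= 0) || any(visit_schedule > 44) ||
      any(visit_schedule < 4))
    stop_config("visit_schedule",
                "must be strictly increasing gestational weeks in [4, 44]")
  if (length(booking_week_range) != 2L ||
      booking_week_range[1] > booking_week_range[2] ||
      booking_week_range[1] < 4 || booking_week_range[2] > 44)
    stop_config("booking_week_range", "must be an increasing pair within [4, 44]")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_config("seed", "must be a single integer")

  structure(list(
    n_pregnancies = n_pregnancies,
    incidence_diabetes = incidence_diabetes,
    incidence_chronic_htn = incidence_chronic_htn,
    incidence_gest_htn_mild = incidence_gest_htn_mild,
    incidence_gest_htn_modsev = incidence_gest_htn_modsev,
    incidence_preeclampsia = incidence_preeclampsia,
    anemia_hb_mean = anemia_hb_mean,
    anemia_hb_sd = anemia_hb_sd,
    severe_anemia_floor = severe_anemia_floor,
    low_bmi_prob = low_bmi_prob,
    tetanus_immune_at_entry_prob = tetanus_immune_at_entry_prob,
    screening_compliance = screening_compliance,
    management_compliance = management_compliance,
    iron_folate_given_prob = iron_folate_given_prob,
    missingness = missingness,
    visit_schedule = as.integer(visit_schedule),
    booking_week_range = as.integer(booking_week_range),
    public_sector_prob = public_sector_prob,
    seed = as.integer(seed)
  ), class = "cohort_params")
}

#' Clinical decision thresholds for the cascade indicators
#'
#' @param glucose_challenge_cut Glucose challenge positivity cut, mg/dl
#'   (results strictly greater are positive).
#' @param blood_sugar_window Closed gestational-week interval for the routine
#'   blood sugar test.
#' @param proteinuria_min_week Earliest gestational week at which hypertension
#'   plus proteinuria counts as pre-eclampsia (strictly greater).
#' @param anemia_cut,severe_anemia_cut Hemoglobin cuts in g/dl; values strictly
#'   below count as (severe) anemia.
#' @param low_bmi_cut Booking BMI cut, kg/m^2 (strictly below counts).
#' @param htn_sys_cut,htn_dia_cut Systolic/diastolic mmHg at or above which a
#'   reading counts as hypertensive (conventional 140/90).
#' @param severe_sys_cut,severe_dia_cut Cuts for moderate/severe hypertension
#'   (conventional 160/110).
#'
#' @return An object of class `clinical_thresholds`.
#' @export
clinical_thresholds <- function(glucose_challenge_cut = 140,
                                blood_sugar_window = c(24, 28),
                                proteinuria_min_week = 20,
                                anemia_cut = 11,
                                severe_anemia_cut = 7,
                                low_bmi_cut = 18.5,
                                htn_sys_cut = 140,
                                htn_dia_cut = 90,
                                severe_sys_cut = 160,
                                severe_dia_cut = 110) {
  if (length(blood_sugar_window) != 2L ||
      blood_sugar_window[1] > blood_sugar_window[2])
    stop_config("blood_sugar_window", "bounds must be increasing")
  if (severe_anemia_cut >= anemia_cut)
    stop_config("severe_anemia_cut", "must be below anemia_cut")
  structure(list(
    glucose_challenge_cut = glucose_challenge_cut,
    blood_sugar_window = blood_sugar_window,
    proteinuria_min_week = proteinuria_min_week,
    anemia_cut = anemia_cut,
    severe_anemia_cut = severe_anemia_cut,
    low_bmi_cut = low_bmi_cut,
    htn_sys_cut = htn_sys_cut,
    htn_dia_cut = htn_dia_cut,
    severe_sys_cut = severe_sys_cut,
    severe_dia_cut = severe_dia_cut
  ), class = "clinical_thresholds")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat("Synthetic antenatal cohort parameters\n")
  cat(sprintf("  pregnancies: %d   seed: %d\n", x$n_pregnancies, x$seed))
  cat(sprintf("  incidences: diabetes %.3f, chronic htn %.3f, gest htn %.3f/%.3f, pre-eclampsia %.3f\n",
              x$incidence_diabetes, x$incidence_chronic_htn,
              x$incidence_gest_htn_mild, x$incidence_gest_htn_modsev,
              x$incidence_preeclampsia))
  cat(sprintf("  hemoglobin: N(%.1f, %.2f) g/dl, severe-anemia floor %.3f\n",
              x$anemia_hb_mean, x$anemia_hb_sd, x$severe_anemia_floor))
  cat("  visit schedule (weeks):", paste(x$visit_schedule, collapse = " "), "\n")
  invisible(x)
}
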