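# Hand-built visit-level fixtures. Expected cascade values below each
# builder were enumerated by hand from the guideline rules before the
# cascade implementations existed; tests freeze those numbers.

visit_row <- function(pid, ga, booking_week = 10L, sector = "public",
                      urine_sugar = NA_character_, blood_sugar = NA_character_,
                      glucose_challenge_mgdl = NA_real_,
                      systolic_bp = NA_real_, diastolic_bp = NA_real_,
                      urine_protein = NA_character_, hemoglobin = NA_real_,
                      bmi = NA_real_, tetanus_status = NA_character_,
                      tetanus_dose_given = NA, iron_folate = NA_character_,
                      referral = "none") {
  data.frame(pregnancy_id = pid, sector = sector, booking_week = booking_week,
             gestational_age = as.integer(ga), urine_sugar = urine_sugar,
             blood_sugar = blood_sugar,
             glucose_challenge_mgdl = glucose_challenge_mgdl,
             systolic_bp = systolic_bp, diastolic_bp = diastolic_bp,
             urine_protein = urine_protein, hemoglobin = hemoglobin,
             bmi = bmi, tetanus_status = tetanus_status,
             tetanus_dose_given = tetanus_dose_given,
             iron_folate = iron_folate, referral = referral,
             stringsAsFactors = FALSE)
}

## 12 pregnancies, 3 latent diabetics: one fully managed, one screened late
## (blood sugar at 30 weeks, outside 24-28), one positive but unreferred.
## Hand count: eligible 12, screened 11, positive 2, managed 1
## coverage = (11/12) * (1/2) = 11/24
diabetes_fixture <- function() {
  rows <- list()
  for (i in 1:9) {
    rows[[length(rows) + 1L]] <- visit_row(i, 10, urine_sugar = "negative")
    rows[[length(rows) + 1L]] <- visit_row(i, 24, blood_sugar = "negative")
  }
  rows[[length(rows) + 1L]] <- visit_row(10, 10, urine_sugar = "negative")
  rows[[length(rows) + 1L]] <- visit_row(10, 24, blood_sugar = "positive",
                                         glucose_challenge_mgdl = 180,
                                         referral = "high_risk_clinic")
  rows[[length(rows) + 1L]] <- visit_row(11, 10, urine_sugar = "negative")
  rows[[length(rows) + 1L]] <- visit_row(11, 30, blood_sugar = "positive",
                                         glucose_challenge_mgdl = 175)
  rows[[length(rows) + 1L]] <- visit_row(12, 10, urine_sugar = "positive",
                                         glucose_challenge_mgdl = 166)
  do.call(rbind, rows)
}

## 10 pregnancies, 3 hypertensives: chronic referred, moderate/severe
## hospital-referred, mild without the proteinuria work-up; one normotensive
## pregnancy misses a blood pressure measurement.
## Hand count: eligible 10, screened 9, positive 3, managed 2
## coverage = (9/10) * (2/3) = 0.6
hypertension_fixture <- function() {
  rows <- list()
  for (i in 1:6) {
    rows[[length(rows) + 1L]] <- visit_row(i, 10, systolic_bp = 120, diastolic_bp = 75)
    rows[[length(rows) + 1L]] <- visit_row(i, 30, systolic_bp = 118, diastolic_bp = 76)
  }
  rows[[length(rows) + 1L]] <- visit_row(7, 10, systolic_bp = 150, diastolic_bp = 95,
                                         referral = "high_risk_clinic")
  rows[[length(rows) + 1L]] <- visit_row(7, 30, systolic_bp = 152, diastolic_bp = 96)
  rows[[length(rows) + 1L]] <- visit_row(8, 10, systolic_bp = 120, diastolic_bp = 75)
  rows[[length(rows) + 1L]] <- visit_row(8, 30, systolic_bp = 170, diastolic_bp = 115,
                                         referral = "hospital")
  rows[[length(rows) + 1L]] <- visit_row(9, 10, systolic_bp = 121, diastolic_bp = 74)
  rows[[length(rows) + 1L]] <- visit_row(9, 30, systolic_bp = 145, diastolic_bp = 92)
  rows[[length(rows) + 1L]] <- visit_row(10, 10, systolic_bp = 119, diastolic_bp = 72)
  rows[[length(rows) + 1L]] <- visit_row(10, 30)  # missing BP
  do.call(rbind, rows)
}

## 6 pregnancies, 2 with hypertension + proteinuria after 20 weeks; one
## hospital-referred, one kept at the clinic.
## Hand count: eligible 6, screened 6, positive 2, managed 1, coverage 0.5
preeclampsia_fixture <- function() {
  rows <- list()
  for (i in 1:4) {
    rows[[length(rows) + 1L]] <- visit_row(i, 10, systolic_bp = 115, diastolic_bp = 70)
    rows[[length(rows) + 1L]] <- visit_row(i, 28, systolic_bp = 117, diastolic_bp = 72)
  }
  rows[[length(rows) + 1L]] <- visit_row(5, 10, systolic_bp = 116, diastolic_bp = 71)
  rows[[length(rows) + 1L]] <- visit_row(5, 28, systolic_bp = 146, diastolic_bp = 96,
                                         urine_protein = "positive",
                                         referral = "hospital")
  rows[[length(rows) + 1L]] <- visit_row(6, 10, systolic_bp = 114, diastolic_bp = 69)
  rows[[length(rows) + 1L]] <- visit_row(6, 28, systolic_bp = 147, diastolic_bp = 95,
                                         urine_protein = "positive")
  do.call(rbind, rows)
}

## 8 pregnancies: 3 anemic (hemoglobin 9.5; one untreated), 5 non-anemic
## (hemoglobin 12.5; two unsupplemented). Pooled correct supplementation 5/8.
iron_folate_fixture <- function() {
  rows <- list()
  an_type <- c("treatment", "treatment", "none")
  for (i in 1:3)
    rows[[length(rows) + 1L]] <- visit_row(i, 10, hemoglobin = 9.5,
                                           iron_folate = an_type[i])
  non_type <- c("routine", "routine", "routine", "none", "none")
  for (i in 1:5)
    rows[[length(rows) + 1L]] <- visit_row(3L + i, 10, hemoglobin = 12.5,
                                           iron_folate = non_type[i])
  do.call(rbind, rows)
}

full_compliance_params <- function(n, seed, ...) {
  cohort_params(
    n_pregnancies = n, seed = seed,
    screening_compliance = c(diabetes = 1, hypertension = 1, preeclampsia = 1),
    management_compliance = c(diabetes = 1, hypertension = 1, preeclampsia = 1,
                              tetanus = 1, iron_folate = 1),
    iron_folate_given_prob = 1,
    missingness = c(tetanus = 0, tetanus_paper = 0, hemoglobin = 0,
                    bmi = 0, iron_folate = 0),
    ...
  )
}

## Expected health-status prevalences implied by cohort parameters
## (normal hemoglobin component clipped to (2.1, 19.9); the clip mass is
## negligible at the default mean/sd, so the plain normal CDF is used).
expected_health_status <- function(p) {
  fl <- p$severe_anemia_floor
  c(anemia = fl + (1 - fl) * pnorm(11, p$anemia_hb_mean, p$anemia_hb_sd),
    severe_anemia = fl + (1 - fl) * pnorm(7, p$anemia_hb_mean, p$anemia_hb_sd),
    low_bmi = p$low_bmi_prob)
}

binom_se <- function(p, n) sqrt(p * (1 - p) / n)

## delta-method SE of the product of two independent stage proportions
product_se <- function(p_screen, n_elig, p_manage, n_pos) {
  sqrt(p_manage^2 * p_screen * (1 - p_screen) / n_elig +
         p_screen^2 * p_manage * (1 - p_manage) / max(n_pos, 1))
}
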