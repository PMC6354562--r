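test_that("diabetes cascade matches the hand-enumerated fixture", {
  res <- diabetes_cascade(diabetes_fixture())
  expect_equal(res$eligible_n, 12L)
  expect_equal(res$screened_correctly_n, 11L)
  expect_equal(res$positive_n, 2L)
  expect_equal(res$correctly_managed_n, 1L)
  expect_equal(res$coverage, (11 / 12) * (1 / 2))
  expect_false(res$undefined)
})

test_that("hypertension cascade matches the hand-enumerated fixture", {
  res <- hypertension_cascade(hypertension_fixture())
  expect_equal(res$eligible_n, 10L)
  expect_equal(res$screened_correctly_n, 9L)
  expect_equal(res$positive_n, 3L)
  expect_equal(res$correctly_managed_n, 2L)
  expect_equal(res$coverage, 0.9 * (2 / 3))
})

test_that("a single missing blood pressure fails hypertension screening for everyone", {
  df <- hypertension_fixture()
  df$systolic_bp[df$gestational_age == 10] <- NA
  res <- hypertension_cascade(df)
  expect_equal(res$screened_correctly_n, 0L)
  expect_equal(res$coverage, 0)
})

test_that("pre-eclampsia cascade matches the fixture and flags empty denominators", {
  res <- preeclampsia_cascade(preeclampsia_fixture())
  expect_equal(res$screened_correctly_n, 6L)
  expect_equal(res$positive_n, 2L)
  expect_equal(res$correctly_managed_n, 1L)
  expect_equal(res$coverage, 0.5)

  ## no hypertensive pregnancies: positive empty, coverage 0 and undefined
  normo <- preeclampsia_fixture()
  normo <- normo[normo$pregnancy_id <= 4, ]
  res0 <- preeclampsia_cascade(normo)
  expect_equal(res0$positive_n, 0L)
  expect_equal(res0$coverage, 0)
  expect_true(res0$undefined)
})

test_that("a referral-censored positive still counts as managed", {
  df <- preeclampsia_fixture()
  coh <- anccover:::new_anc_cohort(df, cohort_params(6, seed = 1), "eregistry",
                                   NULL)
  cen <- apply_referral_censoring(coh)
  res <- preeclampsia_cascade(cen)
  expect_equal(res$correctly_managed_n, 1L)
  expect_equal(res$coverage, 0.5)
})

test_that("missing schema columns raise a schema error naming the column", {
  df <- diabetes_fixture()
  df$glucose_challenge_mgdl <- NULL
  expect_error(diabetes_cascade(df), "glucose_challenge_mgdl")
})

test_that("iron-folate coverage: checkbox rule vs dose-specific rule", {
  fx <- iron_folate_fixture()
  expect_equal(iron_folate_coverage(fx, "eregistry"), 5 / 8)
  fx_paper <- fx
  ## checkbox view: 2 treated + 3 routine = 5 of 8 given anything
  fx_paper$iron_folate <- fx$iron_folate %in% c("routine", "treatment")
  expect_equal(iron_folate_coverage(fx_paper, "paper"), 5 / 8)
})

test_that("tetanus coverage composes guideline compliance with missingness", {
  p <- cohort_params(
    n_pregnancies = 10000, seed = 17,
    tetanus_immune_at_entry_prob = 0,
    management_compliance = c(diabetes = 0.5, hypertension = 0.35,
                              preeclampsia = 0.7, tetanus = 0.9,
                              iron_folate = 0.75),
    missingness = c(tetanus = 0.07, tetanus_paper = 0.42, hemoglobin = 0.03,
                    bmi = 0.03, iron_folate = 0.02))
  coh <- generate_cohort(p)
  cov <- tetanus_coverage(coh, "eregistry")
  expect_lt(abs(cov - 0.9 * 0.93), 3 * binom_se(0.9 * 0.93, 10000))
  ## all vaccination data missing counts as unvaccinated
  blank <- coh
  blank$tetanus_status <- NA_character_
  blank$tetanus_dose_given <- NA
  expect_equal(tetanus_coverage(blank, "eregistry"), 0)
})

test_that("health-status indicators follow the strict-below convention at any point", {
  rows <- rbind(
    visit_row(1, 10, hemoglobin = 6.8), visit_row(2, 10, hemoglobin = 10.9),
    visit_row(3, 10, hemoglobin = 11.0), visit_row(4, 10, hemoglobin = 13.0))
  hs <- health_status_indicators(rows)
  expect_equal(hs[["anemia"]], 2 / 4)
  expect_equal(hs[["severe_anemia"]], 1 / 4)

  ## one anemic reading among several visits is enough
  rows2 <- do.call(rbind, lapply(1:10, function(i)
    rbind(visit_row(i, 10, hemoglobin = if (i == 1) 10.2 else 12.5),
          visit_row(i, 30, hemoglobin = if (i == 1) 11.4 else 12.6))))
  expect_equal(health_status_indicators(rows2)[["anemia"]], 0.1)
  ## severe anemia never exceeds anemia
  hs2 <- health_status_indicators(rows2)
  expect_lte(hs2[["severe_anemia"]], hs2[["anemia"]])
})

test_that("full-compliance cohorts score exactly 1.0 on all five coverage indicators", {
  for (dialect in c("eregistry", "paper")) {
    coh <- apply_referral_censoring(
      generate_cohort(full_compliance_params(800, seed = 31)))
    coh <- degrade_to_dialect(coh, dialect)
    iset <- indicator_set(coh, dialect)
    expect_identical(unname(iset$coverage), rep(1, 5))
  }
})

test_that("zero screening yields zero coverage and no detected positives", {
  p <- cohort_params(
    n_pregnancies = 400, seed = 9, incidence_diabetes = 0.2,
    screening_compliance = c(diabetes = 0, hypertension = 1, preeclampsia = 1))
  res <- diabetes_cascade(generate_cohort(p))
  expect_equal(res$screened_correctly_n, 0L)
  expect_equal(res$positive_n, 0L)
  expect_equal(res$coverage, 0)
})

test_that("cascade monotonicity holds across random-parameter cohorts", {
  set.seed(404)
  for (rep in 1:60) {
    inc_c <- runif(1, 0, 0.1)
    inc_m <- runif(1, 0, 0.15)
    inc_s <- runif(1, 0, 0.1)
    p <- cohort_params(
      n_pregnancies = 60, seed = sample.int(1e6, 1),
      incidence_diabetes = runif(1, 0, 0.3),
      incidence_chronic_htn = inc_c,
      incidence_gest_htn_mild = inc_m,
      incidence_gest_htn_modsev = inc_s,
      incidence_preeclampsia = runif(1) * min(0.05, inc_c + inc_m + inc_s),
      screening_compliance = c(diabetes = runif(1), hypertension = runif(1),
                               preeclampsia = runif(1)),
      management_compliance = c(diabetes = runif(1), hypertension = runif(1),
                                preeclampsia = runif(1), tetanus = runif(1),
                                iron_folate = runif(1)),
      iron_folate_given_prob = runif(1),
      missingness = c(tetanus = runif(1, 0, 0.5), tetanus_paper = 0.42,
                      hemoglobin = runif(1, 0, 0.3), bmi = runif(1, 0, 0.3),
                      iron_folate = runif(1, 0, 0.3)))
    coh <- apply_referral_censoring(generate_cohort(p))
    for (cascade in list(diabetes_cascade, hypertension_cascade,
                         preeclampsia_cascade)) {
      r <- cascade(coh)
      counts <- c(r$eligible_n, r$screened_correctly_n, r$positive_n,
                  r$correctly_managed_n)
      expect_true(all(diff(counts) <= 0) && all(counts >= 0))
      expect_gte(r$coverage, 0); expect_lte(r$coverage, 1)
    }
  }
})

test_that("cascade coverage recovers the product of stage compliances", {
  p <- cohort_params(
    n_pregnancies = 20000, seed = 101, incidence_diabetes = 0.08,
    incidence_chronic_htn = 0, incidence_gest_htn_mild = 0,
    incidence_gest_htn_modsev = 0, incidence_preeclampsia = 0,
    screening_compliance = c(diabetes = 0.7, hypertension = 0.7,
                             preeclampsia = 0.7),
    management_compliance = c(diabetes = 0.8, hypertension = 0.8,
                              preeclampsia = 0.8, tetanus = 0.8,
                              iron_folate = 0.8))
  res <- diabetes_cascade(generate_cohort(p))
  se <- product_se(0.7, 20000, 0.8, res$positive_n)
  expect_lt(abs(res$coverage - 0.56), 3 * se)
  pos_frac <- res$positive_n / res$screened_correctly_n
  expect_lt(abs(pos_frac - 0.08), 3 * binom_se(0.08, res$screened_correctly_n))
})

test_that("latent-truth data are provably unused by the indicators", {
  coh <- apply_referral_censoring(generate_cohort(cohort_params(500, seed = 55)))
  with_truth <- indicator_set(coh, "eregistry")
  shuffled <- coh
  tr <- attr(coh, "truth")
  attr(shuffled, "truth") <- tr[sample.int(nrow(tr)), ]
  stripped <- as.data.frame(coh)  # plain data frame, no attributes at all
  expect_equal(indicator_set(shuffled, "eregistry")$coverage, with_truth$coverage)
  expect_equal(indicator_set(stripped, "eregistry")$coverage, with_truth$coverage)
  expect_equal(indicator_set(stripped, "eregistry")$health_status,
               with_truth$health_status)
})

test_that("indicator_set equals the element-wise individual operations", {
  coh <- apply_referral_censoring(generate_cohort(cohort_params(400, seed = 77)))
  iset <- indicator_set(coh, "eregistry")
  expect_equal(iset$coverage[["diabetes_mgmt"]], diabetes_cascade(coh)$coverage)
  expect_equal(iset$coverage[["htn_mgmt"]], hypertension_cascade(coh)$coverage)
  expect_equal(iset$coverage[["preeclampsia_mgmt"]],
               preeclampsia_cascade(coh)$coverage)
  expect_equal(iset$coverage[["tetanus"]], tetanus_coverage(coh, "eregistry"))
  expect_equal(iset$coverage[["iron_folate"]],
               iron_folate_coverage(coh, "eregistry"))
  expect_equal(iset$health_status, health_status_indicators(coh))
})
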