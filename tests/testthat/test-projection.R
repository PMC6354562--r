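test_that("national coverage is the sector mixture", {
  expect_equal(national_coverage(0.9, 0.9, 0.3), 0.9)
  expect_equal(national_coverage(0.9, 0.2, 1.0), 0.9)
  expect_equal(national_coverage(0.9, 0.2, 0.6), 0.62)
})

test_that("scenario builder holds the comparator flat and scales the public sector", {
  base <- c(diabetes_mgmt = 0.35, htn_mgmt = 0.35, preeclampsia_mgmt = 0.5,
            tetanus = NA, iron_folate = 0.9)
  sc <- build_scenarios(base, p_public = 0.6, target_public = 0.9)
  expect_s3_class(sc$comparator, "scenario_spec")
  ## comparator constant across all years
  expect_true(all(sc$comparator$coverage == sc$comparator$coverage[, 1]))
  ## mixture arithmetic: 0.6*0.9 + 0.4*0.35 = 0.68 from the second year on
  expect_equal(unname(sc$intervention$coverage["diabetes_mgmt", "2018"]), 0.68)
  expect_equal(unname(sc$intervention$coverage["diabetes_mgmt", "2025"]), 0.68)
  expect_equal(unname(sc$intervention$coverage["diabetes_mgmt", "2017"]), 0.35)
  ## a baseline already at target is a no-op
  expect_equal(unname(sc$intervention$coverage["iron_folate", "2018"]), 0.9)
  ## unavailable indicators: identical held trajectories in both scenarios
  expect_true(sc$comparator$held[["tetanus"]])
  expect_equal(sc$comparator$coverage["tetanus", ],
               sc$intervention$coverage["tetanus", ])
})

test_that("calibration identities hold in closed form and round-trip", {
  epi <- default_epi_inputs()
  ivs <- anccover:::ANC_INTERVENTIONS
  ## zero baseline coverage: the latent envelope is the input envelope
  env0 <- calibrate_envelope(epi, setNames(rep(0, 5), ivs))
  expect_equal(env0$deaths_star$maternal, epi$deaths$maternal)
  expect_equal(env0$anemia_star, epi$anemia_prevalence)

  ## single intervention, Eff*AF = 0.5, cov = 0.5 -> D* = D / 0.75
  one <- epi
  one$effectiveness$maternal[, ] <- 0
  one$effectiveness$maternal["htn_mgmt", "hypertensive"] <- 0.5
  one$affected_fraction$maternal[, ] <- 0
  one$affected_fraction$maternal["htn_mgmt", "hypertensive"] <- 1
  cov <- setNames(c(0, 0.5, 0, 0, 0), ivs)
  env1 <- calibrate_envelope(one, cov)
  expect_equal(unname(env1$deaths_star$maternal[["hypertensive"]]),
               unname(one$deaths$maternal[["hypertensive"]]) / 0.75)

  ## round-trip: projecting at baseline coverage reproduces the envelope
  base <- setNames(c(0.3, 0.2, 0.5, 0.8, 0.6), ivs)
  env <- calibrate_envelope(epi, base)
  cov_mat <- matrix(rep(base, 4), nrow = 5,
                    dimnames = list(ivs, 2017:2020))
  proj <- project_outcomes(make_scenario(cov_mat, 2017:2020), epi, env)
  for (o in c("maternal", "neonatal", "stillbirth"))
    expect_lt(max(abs(proj$deaths[[o]] -
                        matrix(rep(epi$deaths[[o]], 4), ncol = 4))), 1e-10)
  expect_lt(max(abs(proj$anemia_prevalence - epi$anemia_prevalence)), 1e-10)
})

test_that("infeasible residual-risk factors are rejected", {
  epi <- default_epi_inputs()
  epi$effectiveness$neonatal["tetanus", "neonatal_tetanus"] <- 1
  epi$affected_fraction$neonatal["tetanus", "neonatal_tetanus"] <- 1
  cov <- setNames(c(0, 0, 0, 1, 0), anccover:::ANC_INTERVENTIONS)
  expect_error(calibrate_envelope(epi, cov), "infeasible")
})

test_that("projection equals the independent brute-force oracle on random instances", {
  set.seed(2024)
  for (rep in 1:100) {
    inst <- random_epi_instance()
    scen <- make_scenario(inst$cov_mat, inst$years)
    proj <- project_outcomes(scen, inst$epi)
    for (o in c("maternal", "neonatal", "stillbirth")) {
      expected <- oracle_project_deaths(
        inst$epi$deaths[[o]], inst$epi$effectiveness[[o]],
        inst$epi$affected_fraction[[o]], inst$cov0, inst$cov_mat)
      expect_lt(max(abs(proj$deaths[[o]] - expected)), 1e-10)
    }
    ## anemia: scalar residual-risk oracle
    p_star <- inst$epi$anemia_prevalence /
      (1 - inst$epi$anemia_effectiveness * inst$epi$anemia_affected_fraction *
         inst$cov0[["iron_folate"]])
    exp_prev <- p_star * (1 - inst$epi$anemia_effectiveness *
                            inst$epi$anemia_affected_fraction *
                            inst$cov_mat["iron_folate", ])
    expect_lt(max(abs(proj$anemia_prevalence - exp_prev)), 1e-10)
  }
})

test_that("elimination limit: full coverage of a fully effective sole intervention removes the cause", {
  epi <- default_epi_inputs()
  epi$effectiveness$neonatal["tetanus", "neonatal_tetanus"] <- 1
  epi$affected_fraction$neonatal["tetanus", "neonatal_tetanus"] <- 1
  ivs <- anccover:::ANC_INTERVENTIONS
  cov_mat <- matrix(0, 5, 2, dimnames = list(ivs, 2017:2018))
  cov_mat["tetanus", 2] <- 1
  proj <- project_outcomes(make_scenario(cov_mat, 2017:2018), epi)
  expect_equal(unname(proj$deaths$neonatal["neonatal_tetanus", "2018"]), 0)
  ## constant coverage gives constant yearly deaths
  flat <- matrix(0.4, 5, 3, dimnames = list(ivs, 2017:2019))
  pf <- project_outcomes(make_scenario(flat, 2017:2019), epi)
  expect_true(all(abs(pf$totals - pf$totals[, 1]) < 1e-12))
})

test_that("identical scenarios avert nothing and leave attribution flagged undefined", {
  base <- c(diabetes_mgmt = 0.4, htn_mgmt = 0.3, preeclampsia_mgmt = 0.5,
            tetanus = 0.8, iron_folate = 0.7)
  sc <- build_scenarios(base, p_public = 0.6, target_public = 0.9)
  sc$intervention <- sc$comparator
  s <- compare_scenarios(sc, default_epi_inputs())
  expect_equal(unname(s$averted), rep(0, 4))
  expect_false(any(s$attribution_defined))
})

test_that("attribution shares sum to one, lie in [0,1], and match one-at-a-time ratios", {
  base <- c(diabetes_mgmt = 0.3, htn_mgmt = 0.25, preeclampsia_mgmt = 0.4,
            tetanus = 0.7, iron_folate = 0.6)
  sc <- build_scenarios(base, p_public = 0.6, target_public = 0.9)
  s <- compare_scenarios(sc, default_epi_inputs())
  expect_true(all(s$averted >= 0))
  for (o in rownames(s$attribution)) {
    if (!s$attribution_defined[[o]]) next
    sh <- s$attribution[o, ]
    expect_equal(sum(sh, na.rm = TRUE), 1, tolerance = 1e-9)
    expect_true(all(sh[!is.na(sh)] >= 0 & sh[!is.na(sh)] <= 1))
    expect_equal(unname(sh), unname(s$one_at_a_time[o, ] /
                                      sum(s$one_at_a_time[o, ])))
  }
  ## a single contributing intervention takes a 100% share
  expect_equal(unname(s$attribution["neonatal", "tetanus"]), 1)
  expect_equal(unname(s$attribution["anemia_cases", "iron_folate"]), 1)
})

test_that("cumulative averted is nondecreasing in the public-sector target", {
  base <- c(diabetes_mgmt = 0.3, htn_mgmt = 0.25, preeclampsia_mgmt = 0.4,
            tetanus = 0.7, iron_folate = 0.6)
  epi <- default_epi_inputs()
  targets <- seq(0.5, 0.95, by = 0.05)
  prev <- NULL
  for (tg in targets) {
    s <- compare_scenarios(build_scenarios(base, 0.6, target_public = tg), epi)
    if (!is.null(prev)) expect_true(all(s$averted >= prev - 1e-9))
    prev <- s$averted
  }
})

test_that("rates are reported on the conventional scales", {
  base <- c(diabetes_mgmt = 0.3, htn_mgmt = 0.25, preeclampsia_mgmt = 0.4,
            tetanus = 0.7, iron_folate = 0.6)
  epi <- default_epi_inputs()
  s <- compare_scenarios(build_scenarios(base, 0.6), epi)
  expect_equal(unname(s$rates["comparator_first", "mmr"]),
               sum(epi$deaths$maternal) / epi$live_births_per_year * 1e5,
               tolerance = 1e-8)
  expect_lt(s$rates["intervention_last", "mmr"],
            s$rates["comparator_last", "mmr"])
  expect_true(all(s$pct_change["vs_own_first", ] >= 0))
})
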