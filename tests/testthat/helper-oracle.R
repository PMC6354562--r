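# Independent brute-force oracle for the multiplicative residual-risk
# projection: plain scalar loops, no shared code with the package engine.

oracle_residual_factor <- function(eff_col, af_col, cov) {
  f <- 1
  for (i in seq_along(cov)) f <- f * (1 - eff_col[i] * af_col[i] * cov[i])
  f
}

## deaths by cause and year from baseline deaths, baseline coverage and a
## coverage trajectory (interventions x years)
oracle_project_deaths <- function(deaths0, eff, af, cov0, cov_mat) {
  causes <- names(deaths0)
  ny <- ncol(cov_mat)
  out <- matrix(NA_real_, nrow = length(causes), ncol = ny,
                dimnames = list(causes, colnames(cov_mat)))
  for (c_ix in seq_along(causes)) {
    f0 <- oracle_residual_factor(eff[, c_ix], af[, c_ix], cov0)
    d_star <- deaths0[[c_ix]] / f0
    for (t in seq_len(ny)) {
      out[c_ix, t] <- d_star *
        oracle_residual_factor(eff[, c_ix], af[, c_ix], cov_mat[, t])
    }
  }
  out
}

## random small projection instance within the engine's five-intervention
## frame: at most `max_active` interventions carry nonzero effects and at
## most `max_causes` causes per outcome
random_epi_instance <- function(max_causes = 3, max_active = 4) {
  ivs <- anccover:::ANC_INTERVENTIONS
  mk <- function(prefix) {
    k <- sample.int(max_causes, 1L)
    causes <- paste0(prefix, seq_len(k))
    active <- sample(ivs, sample.int(max_active, 1L))
    eff <- matrix(0, 5L, k, dimnames = list(ivs, causes))
    af <- matrix(0, 5L, k, dimnames = list(ivs, causes))
    eff[active, ] <- round(runif(length(active) * k, 0, 0.9), 3)
    af[active, ] <- round(runif(length(active) * k, 0, 1), 3)
    list(eff = eff, af = af,
         deaths = setNames(round(runif(k, 10, 500)), causes))
  }
  m <- mk("mc"); n <- mk("nc"); s <- mk("sc")
  epi <- epi_inputs(
    pregnancies_per_year = 100000, live_births_per_year = 90000,
    maternal_deaths = m$deaths, neonatal_deaths = n$deaths,
    stillbirths = s$deaths,
    anemia_prevalence = round(runif(1, 0.1, 0.5), 3),
    effectiveness = list(maternal = m$eff, neonatal = n$eff, stillbirth = s$eff),
    affected_fraction = list(maternal = m$af, neonatal = n$af, stillbirth = s$af),
    anemia_effectiveness = round(runif(1, 0, 0.9), 3),
    anemia_affected_fraction = round(runif(1, 0, 1), 3)
  )
  years <- 2017:2020
  cov0 <- setNames(round(runif(5L, 0, 0.8), 3), anccover:::ANC_INTERVENTIONS)
  cov_mat <- matrix(round(runif(5L * length(years), 0, 0.95), 3), nrow = 5L,
                    dimnames = list(anccover:::ANC_INTERVENTIONS, years))
  cov_mat[, 1L] <- cov0
  list(epi = epi, years = years, cov0 = cov0, cov_mat = cov_mat)
}

make_scenario <- function(cov_mat, years, label = "test") {
  anccover:::new_scenario_spec(label, years, cov_mat,
                               setNames(rep(FALSE, 5L),
                                        anccover:::ANC_INTERVENTIONS))
}
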