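ANC_OUTCOMES <- c("maternal", "neonatal", "stillbirth")

#' Epidemiological inputs for the lives-saved projection
#'
#' Holds the demographic envelope, cause-partitioned baseline deaths, anemia
#' prevalence, and the effectiveness and affected-fraction matrices linking
#' the five antenatal interventions to causes of death. The engine combines
#' interventions within a cause by multiplicative residual risk:
#' `deaths = D_star * prod_i(1 - Eff_i * AF_i * cov_i)`.
#'
#' @param pregnancies_per_year Pregnancies per year (constant across years).
#' @param live_births_per_year Live births per year.
#' @param maternal_deaths,neonatal_deaths,stillbirths Named numeric vectors of
#'   baseline (first-year) deaths by cause.
#' @param anemia_prevalence Baseline anemia prevalence among pregnant women.
#' @param effectiveness,affected_fraction Lists with one matrix per outcome
#'   (`maternal`, `neonatal`, `stillbirth`); rows are the five interventions,
#'   columns the outcome's causes; entries in [0, 1].
#' @param anemia_effectiveness,anemia_affected_fraction Iron-folate effect on
#'   anemia prevalence.
#' @return An object of class `epi_inputs`.
#' @seealso [default_epi_inputs()] for an illustrative filled-in set.
#' @export
epi_inputs <- function(pregnancies_per_year, live_births_per_year,
                       maternal_deaths, neonatal_deaths, stillbirths,
                       anemia_prevalence,
                       effectiveness, affected_fraction,
                       anemia_effectiveness = 0, anemia_affected_fraction = 0) {
  deaths <- list(maternal = maternal_deaths, neonatal = neonatal_deaths,
                 stillbirth = stillbirths)
  for (o in ANC_OUTCOMES) {
    d <- deaths[[o]]
    if (!is.numeric(d) || is.null(names(d)) || any(d < 0))
      stop_config(paste0(o, " deaths"), "must be a named non-negative vector")
    for (nm in c("effectiveness", "affected_fraction")) {
      M <- get(nm)[[o]]
      if (!is.matrix(M) || !identical(rownames(M), ANC_INTERVENTIONS) ||
          !identical(colnames(M), names(d)))
        stop_config(nm, sprintf(
          "for outcome '%s' must be a matrix with the 5 interventions as rows and the outcome's causes as columns", o))
      if (any(M < 0 | M > 1)) stop_config(nm, "entries must lie in [0, 1]")
    }
  }
  check_prob(anemia_prevalence, "anemia_prevalence")
  check_prob(anemia_effectiveness, "anemia_effectiveness")
  check_prob(anemia_affected_fraction, "anemia_affected_fraction")
  structure(list(
    pregnancies_per_year = pregnancies_per_year,
    live_births_per_year = live_births_per_year,
    deaths = deaths,
    anemia_prevalence = anemia_prevalence,
    effectiveness = effectiveness,
    affected_fraction = affected_fraction,
    anemia_effectiveness = anemia_effectiveness,
    anemia_affected_fraction = anemia_affected_fraction
  ), class = "epi_inputs")
}

#' Illustrative epidemiological inputs
#'
#' A filled-in [epi_inputs()] for a West Bank-like population: roughly 46
#' maternal deaths per 100,000 live births, a neonatal mortality rate near 11
#' per 1,000 and a stillbirth rate near 7 per 1,000 births. The intervention
#' -> cause structure follows the standard antenatal linkage: hypertension
#' and pre-eclampsia management act on maternal hypertensive deaths,
#' pre-eclampsia and diabetes management on antepartum stillbirths, tetanus
#' vaccination on neonatal tetanus, and iron-folate on anemia. Effectiveness
#' and affected-fraction values are illustrative defaults, not an
#' authoritative effectiveness database; analyses that matter should set them
#' explicitly.
#'
#' @return An `epi_inputs` object.
#' @export
default_epi_inputs <- function() {
  zero <- function(causes) {
    matrix(0, nrow = 5L, ncol = length(causes),
           dimnames = list(ANC_INTERVENTIONS, causes))
  }
  mat_causes <- c("hypertensive", "other_maternal")
  neo_causes <- c("neonatal_tetanus", "other_neonatal")
  sb_causes  <- c("antepartum", "other_stillbirth")

  eff <- list(maternal = zero(mat_causes), neonatal = zero(neo_causes),
              stillbirth = zero(sb_causes))
  af <- list(maternal = zero(mat_causes), neonatal = zero(neo_causes),
             stillbirth = zero(sb_causes))
  eff$maternal["htn_mgmt", "hypertensive"] <- 0.35
  af$maternal["htn_mgmt", "hypertensive"] <- 0.60
  eff$maternal["preeclampsia_mgmt", "hypertensive"] <- 0.59
  af$maternal["preeclampsia_mgmt", "hypertensive"] <- 0.70
  eff$neonatal["tetanus", "neonatal_tetanus"] <- 0.94
  af$neonatal["tetanus", "neonatal_tetanus"] <- 1.00
  eff$stillbirth["preeclampsia_mgmt", "antepartum"] <- 0.20
  af$stillbirth["preeclampsia_mgmt", "antepartum"] <- 0.50
  eff$stillbirth["diabetes_mgmt", "antepartum"] <- 0.10
  af$stillbirth["diabetes_mgmt", "antepartum"] <- 0.30

  epi_inputs(
    pregnancies_per_year = 130000,
    live_births_per_year = 120000,
    maternal_deaths = c(hypertensive = 15, other_maternal = 40),
    neonatal_deaths = c(neonatal_tetanus = 25, other_neonatal = 1295),
    stillbirths = c(antepartum = 350, other_stillbirth = 500),
    anemia_prevalence = 0.37,
    effectiveness = eff,
    affected_fraction = af,
    anemia_effectiveness = 0.67,
    anemia_affected_fraction = 1.0
  )
}

#' National coverage from a public/other sector mix
#'
#' @param public_cov Coverage in public facilities.
#' @param other_cov Coverage in other (private/NGO) facilities.
#' @param p_public Proportion of women attending public facilities.
#' @return `p_public * public_cov + (1 - p_public) * other_cov`.
#' @examples
#' national_coverage(0.9, 0.2, 0.6)  # 0.62
#' @export
national_coverage <- function(public_cov, other_cov, p_public) {
  check_prob(p_public, "p_public")
  p_public * public_cov + (1 - p_public) * other_cov
}

new_scenario_spec <- function(label, years, coverage, held) {
  stopifnot(is.matrix(coverage),
            identical(rownames(coverage), ANC_INTERVENTIONS),
            ncol(coverage) == length(years))
  colnames(coverage) <- as.character(years)
  structure(list(label = label, years = years, coverage = coverage,
                 held = held), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%d-%d)\n", x$label, min(x$years), max(x$years)))
  print(round(x$coverage, 3))
  if (any(x$held))
    cat("  held at reference (indicator unavailable):",
        paste(names(x$held)[x$held], collapse = ", "), "\n")
  invisible(x)
}

#' Build comparator and public-sector scale-up scenarios
#'
#' The comparator holds the national baseline coverage flat across all years.
#' The scale-up scenario raises public-sector coverage to `target_public`
#' (never below its baseline) from the second year onward, leaving
#' other-sector coverage and the public-attendance share unchanged.
#' Interventions whose indicator is unavailable in the source are held at a
#' reference coverage in both scenarios and flagged, so their scenario delta
#' is structurally zero.
#'
#' @param baseline An `indicator_set` (public-sector coverage, NA when
#'   unavailable) or a named coverage vector over the five interventions.
#' @param p_public Proportion of women attending public facilities.
#' @param target_public Public-sector coverage target (default 0.9).
#' @param other_cov Either `"public_baseline"` (other-sector coverage assumed
#'   equal to the public baseline, the default imputation) or a named numeric
#'   vector of other-sector coverages.
#' @param years Projection years (default 2017-2025).
#' @param fallback_coverage Reference coverage for unavailable indicators
#'   (default 0; it cancels between scenarios).
#' @return A list of class `scenario_pair` with elements `comparator` and
#'   `intervention`, both `scenario_spec` objects.
#' @export
build_scenarios <- function(baseline, p_public, target_public = 0.9,
                            other_cov = "public_baseline",
                            years = 2017:2025, fallback_coverage = 0) {
  check_prob(p_public, "p_public")
  check_prob(target_public, "target_public")
  pub <- if (inherits(baseline, "indicator_set")) baseline$coverage else baseline
  if (is.null(names(pub)) || !all(ANC_INTERVENTIONS %in% names(pub)))
    stop_config("baseline", "must name all five intervention coverages")
  pub <- pub[ANC_INTERVENTIONS]
  avail <- !is.na(pub)

  oth <- if (identical(other_cov, "public_baseline")) pub
         else other_cov[ANC_INTERVENTIONS]
  nat_base <- ifelse(avail, national_coverage(pub, oth, p_public)[ANC_INTERVENTIONS],
                     fallback_coverage)
  nat_base <- stats::setNames(as.numeric(nat_base), ANC_INTERVENTIONS)
  if (any(nat_base[avail] > 1 + 1e-12))
    stop_config("baseline", "implies national coverage above 1")

  pub_target <- pmax(target_public, pub)
  nat_target <- ifelse(avail,
                       p_public * pub_target + (1 - p_public) * oth,
                       fallback_coverage)
  nat_target <- stats::setNames(as.numeric(nat_target), ANC_INTERVENTIONS)

  ny <- length(years)
  comp <- matrix(rep(nat_base, ny), nrow = 5L,
                 dimnames = list(ANC_INTERVENTIONS, years))
  intv <- comp
  if (ny > 1L) intv[, -1L] <- matrix(rep(nat_target, ny - 1L), nrow = 5L)

  held <- stats::setNames(!avail, ANC_INTERVENTIONS)
  structure(list(
    comparator = new_scenario_spec("steady state", years, comp, held),
    intervention = new_scenario_spec(
      sprintf("public-sector scale-up to %.0f%%", 100 * target_public),
      years, intv, held)
  ), class = "scenario_pair")
}

## residual-risk factor per cause: prod_i (1 - Eff * AF * cov_i)
impact_factor <- function(eff, af, cov) {
  apply(1 - eff * af * cov, 2L, prod)
}

#' Calibrate the latent zero-coverage envelope
#'
#' Back-calculates, for each cause, the deaths that would occur with no
#' intervention coverage: `D_star = D_baseline / prod_i(1 - Eff*AF*cov_i)`.
#' Projecting the calibrated envelope at the baseline coverage reproduces the
#' input envelope exactly. Anemia prevalence is calibrated analogously
#' against iron-folate coverage.
#'
#' @param epi An [epi_inputs()] object.
#' @param baseline_cov Named coverage vector over the five interventions
#'   (NA treated as 0).
#' @return An object of class `latent_envelope`.
#' @export
calibrate_envelope <- function(epi, baseline_cov) {
  stopifnot(inherits(epi, "epi_inputs"))
  cov <- stats::setNames(rep(0, 5L), ANC_INTERVENTIONS)
  cov[names(baseline_cov)] <- ifelse(is.na(baseline_cov), 0, baseline_cov)
  deaths_star <- list()
  for (o in ANC_OUTCOMES) {
    f <- impact_factor(epi$effectiveness[[o]], epi$affected_fraction[[o]], cov)
    if (any(f <= 0))
      stop("infeasible parameters: residual-risk factor <= 0 for outcome ", o,
           call. = FALSE)
    deaths_star[[o]] <- epi$deaths[[o]] / f
  }
  f_an <- 1 - epi$anemia_effectiveness * epi$anemia_affected_fraction *
    cov[["iron_folate"]]
  if (f_an <= 0)
    stop("infeasible parameters: anemia residual-risk factor <= 0", call. = FALSE)
  structure(list(deaths_star = deaths_star,
                 anemia_star = epi$anemia_prevalence / f_an,
                 baseline_cov = cov),
            class = "latent_envelope")
}

#' Project yearly outcomes under a coverage scenario
#'
#' Deterministic projection: for each cause and year,
#' `deaths = D_star * prod_i(1 - Eff*AF*cov_i_year)`; anemia prevalence is
#' `p_star * (1 - Eff_IFA * AF_IFA * cov_IFA_year)` and anemia cases apply
#' that prevalence to the yearly pregnancies.
#'
#' @param scenario A `scenario_spec`.
#' @param epi An [epi_inputs()] object.
#' @param envelope A [calibrate_envelope()] result; by default calibrated at
#'   the scenario's first-year coverage.
#' @return An object of class `anc_projection`: per-outcome cause-by-year
#'   death matrices, per-outcome yearly totals, anemia prevalence and cases.
#' @export
project_outcomes <- function(scenario, epi,
                             envelope = calibrate_envelope(
                               epi, scenario$coverage[, 1L])) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(epi, "epi_inputs"))
  years <- scenario$years
  ny <- length(years)
  deaths <- list()
  totals <- matrix(0, nrow = length(ANC_OUTCOMES), ncol = ny,
                   dimnames = list(ANC_OUTCOMES, years))
  for (o in ANC_OUTCOMES) {
    D <- matrix(0, nrow = length(envelope$deaths_star[[o]]), ncol = ny,
                dimnames = list(names(envelope$deaths_star[[o]]), years))
    for (t in seq_len(ny)) {
      f <- impact_factor(epi$effectiveness[[o]], epi$affected_fraction[[o]],
                         scenario$coverage[, t])
      D[, t] <- envelope$deaths_star[[o]] * f
    }
    deaths[[o]] <- D
    totals[o, ] <- colSums(D)
  }
  cov_ifa <- scenario$coverage["iron_folate", ]
  prev <- envelope$anemia_star *
    (1 - epi$anemia_effectiveness * epi$anemia_affected_fraction * cov_ifa)
  cases <- epi$pregnancies_per_year * prev
  structure(list(label = scenario$label, years = years, deaths = deaths,
                 totals = totals, anemia_prevalence = prev,
                 anemia_cases = cases),
            class = "anc_projection")
}

#' @export
print.anc_projection <- function(x, ...) {
  cat(sprintf("Projection '%s' (%d-%d)\n", x$label, min(x$years), max(x$years)))
  cat("  yearly deaths (totals):\n")
  print(round(x$totals, 1))
  cat("  anemia prevalence:\n")
  print(round(x$anemia_prevalence, 4))
  invisible(x)
}
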