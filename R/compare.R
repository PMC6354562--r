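#' Compare two projected scenarios: averted outcomes and attribution
#'
#' Projects comparator and intervention scenarios from a common envelope
#' calibrated at the shared first-year coverage, accumulates the difference
#' in deaths and anemia cases over the scale-up years (all years after the
#' first), and attributes the averted totals to interventions by
#' one-at-a-time scaling: each intervention's trajectory is raised alone
#' while the rest stay at comparator levels, and the resulting averted
#' amounts are normalized to shares. Mortality rates (maternal mortality
#' ratio per 100,000 live births, neonatal mortality and stillbirth rates
#' per 1,000) are reported for the first and last year under both scenarios
#' with two percent-change readings: the intervention scenario's last year
#' against its own first year, and against the comparator's last year.
#'
#' @param scenarios A `scenario_pair` from [build_scenarios()], or a list
#'   with `comparator` and `intervention` `scenario_spec`s sharing years and
#'   first-year coverage.
#' @param epi An [epi_inputs()] object.
#' @return An object of class `averted_summary`.
#' @export
compare_scenarios <- function(scenarios, epi) {
  comp <- scenarios$comparator
  intv <- scenarios$intervention
  stopifnot(inherits(comp, "scenario_spec"), inherits(intv, "scenario_spec"),
            identical(comp$years, intv$years))
  if (max(abs(comp$coverage[, 1L] - intv$coverage[, 1L])) > 1e-12)
    stop("scenarios must share their first-year (baseline) coverage",
         call. = FALSE)
  env <- calibrate_envelope(epi, comp$coverage[, 1L])
  pc <- project_outcomes(comp, epi, env)
  pi_ <- project_outcomes(intv, epi, env)
  post <- seq_along(comp$years)[-1L]

  averted <- c(
    maternal = sum(pc$totals["maternal", post] - pi_$totals["maternal", post]),
    neonatal = sum(pc$totals["neonatal", post] - pi_$totals["neonatal", post]),
    stillbirth = sum(pc$totals["stillbirth", post] - pi_$totals["stillbirth", post]),
    anemia_cases = sum(pc$anemia_cases[post] - pi_$anemia_cases[post])
  )

  ## one-at-a-time attribution
  outcomes <- names(averted)
  one_at_a_time <- matrix(0, nrow = length(outcomes), ncol = 5L,
                          dimnames = list(outcomes, ANC_INTERVENTIONS))
  for (i in ANC_INTERVENTIONS) {
    s_i <- comp
    s_i$coverage[i, ] <- intv$coverage[i, ]
    p_i <- project_outcomes(s_i, epi, env)
    one_at_a_time[, i] <- c(
      sum(pc$totals["maternal", post] - p_i$totals["maternal", post]),
      sum(pc$totals["neonatal", post] - p_i$totals["neonatal", post]),
      sum(pc$totals["stillbirth", post] - p_i$totals["stillbirth", post]),
      sum(pc$anemia_cases[post] - p_i$anemia_cases[post])
    )
  }
  tot <- rowSums(one_at_a_time)
  attribution <- one_at_a_time / ifelse(tot == 0, NA_real_, tot)
  attribution_defined <- tot != 0

  rates <- function(proj, t) {
    lb <- epi$live_births_per_year
    sb <- proj$totals["stillbirth", t]
    c(mmr = proj$totals["maternal", t] / lb * 1e5,
      nmr = proj$totals["neonatal", t] / lb * 1e3,
      sbr = sb / (lb + sb) * 1e3,
      anemia_pct = unname(proj$anemia_prevalence[t]) * 100)
  }
  ny <- length(comp$years)
  rate_tab <- rbind(
    comparator_first = rates(pc, 1L),
    comparator_last = rates(pc, ny),
    intervention_first = rates(pi_, 1L),
    intervention_last = rates(pi_, ny)
  )
  pct <- function(from, to) ifelse(from == 0, NA_real_, 100 * (from - to) / from)
  pct_change <- rbind(
    vs_own_first = pct(rate_tab["intervention_first", ],
                       rate_tab["intervention_last", ]),
    vs_comparator_last = pct(rate_tab["comparator_last", ],
                             rate_tab["intervention_last", ])
  )

  structure(list(
    years = comp$years,
    averted = averted,
    attribution = attribution,
    attribution_defined = attribution_defined,
    one_at_a_time = one_at_a_time,
    rates = rate_tab,
    pct_change = pct_change,
    comparator = pc,
    intervention = pi_
  ), class = "averted_summary")
}

#' @export
print.averted_summary <- function(x, digits = 1, ...) {
  cat(sprintf("Averted outcomes, cumulative %d-%d\n",
              x$years[2], max(x$years)))
  for (o in names(x$averted)) {
    cat(sprintf("  %-13s %10.1f", o, x$averted[[o]]))
    if (x$attribution_defined[[o]]) {
      sh <- x$attribution[o, ]
      sh <- sh[!is.na(sh) & sh > 1e-9]
      cat("   (", paste(sprintf("%s %.0f%%", names(sh), 100 * sh),
                        collapse = "; "), ")", sep = "")
    } else {
      cat("   (no intervention contributes; attribution undefined)")
    }
    cat("\n")
  }
  cat("\nRates (first/last year):\n")
  print(round(x$rates, 2))
  cat("\nPercent change in rates:\n")
  print(round(x$pct_change, 2))
  invisible(x)
}

#' @export
summary.averted_summary <- function(object, ...) object

#' Bar chart of averted outcomes by intervention
#'
#' @param x An `averted_summary`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.averted_summary <- function(x, ...) {
  m <- t(x$one_at_a_time)
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    main = "Averted outcomes by intervention (one-at-a-time)",
                    ylab = "cumulative averted", las = 1, ...)
  invisible(x)
}
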