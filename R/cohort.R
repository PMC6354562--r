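## Generator-side guideline constants. The cascades take their own
## clinical_thresholds(); these fix how the simulated clinics behave.
URINE_SUGAR_SENS <- 0.3   # chance a latent diabetic already shows glycosuria at booking
BLOOD_SUGAR_FPR  <- 0.02  # chance a non-diabetic blood sugar test triggers a challenge test
GEN_BS_WINDOW    <- c(24L, 28L)
GEN_GCT_CUT      <- 140

first_of <- function(flag, pid) {
  idx <- which(flag)
  keep <- idx[!duplicated(pid[idx])]
  out <- logical(length(flag))
  out[keep] <- TRUE
  out
}

new_anc_cohort <- function(visits, params, dialect, truth, censored = FALSE) {
  structure(visits,
            params = params, dialect = dialect, truth = truth,
            censored = censored,
            class = c("anc_cohort", "data.frame"))
}

#' Generate a synthetic longitudinal antenatal cohort
#'
#' Simulates one pregnancy record per woman: a booking visit followed by the
#' routine visit schedule, with gestational-age-stamped screenings (urine
#' sugar, blood sugar, glucose challenge, blood pressure, urine protein,
#' hemoglobin, booking BMI), tetanus vaccination status, iron-folate
#' supplementation and referral events. Latent conditions (diabetes,
#' hypertensive disorders, pre-eclampsia) manifest in the observations only
#' through the guideline screening pathway: a latent diabetic shows a glucose
#' challenge above 140 mg/dl only when the challenge test was actually
#' performed.
#'
#' The simulated clinic follows West Bank antenatal guidelines: urine sugar at
#' booking, blood sugar at 24-28 weeks for women not already positive, a
#' glucose challenge when indicated, blood pressure at every visit, urine
#' protein after observed hypertension beyond 20 weeks, and referral (high-risk
#' clinic or hospital) as management. Screening compliance acts per pregnancy
#' and pathway: a non-compliant pregnancy misses the whole pathway (diabetes)
#' or one blood-pressure measurement (hypertension), so the correctly-screened
#' fraction recovers the configured compliance exactly.
#'
#' Random draws occur in a fixed, documented order (pregnancy-level vectors
#' first, then visit-level vectors), so a seed identifies a cohort across
#' versions.
#'
#' @param params A [cohort_params()] object.
#' @return An `anc_cohort`: a data frame with one row per visit observation,
#'   ordered by pregnancy and gestational age, carrying the generating
#'   parameters, the dialect (`"eregistry"`, the full-structure canonical
#'   form) and a pregnancy-level latent-truth table as attributes. The truth
#'   table is never consumed by any indicator operation.
#' @seealso [degrade_to_dialect()], [apply_referral_censoring()],
#'   [write_cohort()]
#' @examples
#' coh <- generate_cohort(cohort_params(n_pregnancies = 25, seed = 3))
#' head(coh)
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params"))
    params <- do.call(cohort_params, as.list(params))
  n <- params$n_pregnancies
  set.seed(params$seed)

  ## --- pregnancy-level draws, fixed order ---------------------------------
  sector <- ifelse(stats::runif(n) < params$public_sector_prob, "public", "other")
  lo <- params$booking_week_range[1]; hi <- params$booking_week_range[2]
  booking <- as.integer(floor(stats::runif(n) * (hi - lo + 1L))) + lo

  p_c <- params$incidence_chronic_htn
  p_m <- params$incidence_gest_htn_mild
  p_s <- params$incidence_gest_htn_modsev
  u_htn <- stats::runif(n)
  htn_cat <- rep("none", n)
  htn_cat[u_htn < p_c + p_m + p_s] <- "gest_modsev"
  htn_cat[u_htn < p_c + p_m] <- "gest_mild"
  htn_cat[u_htn < p_c] <- "chronic"

  htn_total <- p_c + p_m + p_s
  p_pe_given_htn <- if (htn_total > 0) params$incidence_preeclampsia / htn_total else 0
  pe <- htn_cat != "none" & stats::runif(n) < p_pe_given_htn

  diabetes <- stats::runif(n) < params$incidence_diabetes

  onset_gest <- as.integer(floor(stats::runif(n) * 14)) + 21L   # 21..34
  pe_draw    <- as.integer(floor(stats::runif(n) * 16)) + 21L   # 21..36
  pe_onset <- ifelse(htn_cat %in% c("gest_mild", "gest_modsev"),
                     pmax(onset_gest, pe_draw), pe_draw)
  pe_onset[!pe] <- NA_integer_

  tet_immune <- stats::runif(n) < params$tetanus_immune_at_entry_prob
  severe_an  <- stats::runif(n) < params$severe_anemia_floor
  hb_norm <- pmin(pmax(stats::rnorm(n, params$anemia_hb_mean, params$anemia_hb_sd),
                       2.1), 19.9)
  hb_sev  <- stats::runif(n, 4, 6.9)
  hb_true <- round(ifelse(severe_an, hb_sev, hb_norm), 1)

  low_bmi  <- stats::runif(n) < params$low_bmi_prob
  bmi_low  <- stats::runif(n, 15, 18.4)
  bmi_norm <- stats::runif(n, 19, 34)
  bmi_val  <- round(ifelse(low_bmi, bmi_low, bmi_norm), 1)

  sc <- params$screening_compliance
  mc <- params$management_compliance
  scr_diab <- stats::runif(n) < sc[["diabetes"]]
  scr_htn  <- stats::runif(n) < sc[["hypertension"]]
  scr_pe   <- stats::runif(n) < sc[["preeclampsia"]]
  mg_diab  <- stats::runif(n) < mc[["diabetes"]]
  mg_htn   <- stats::runif(n) < mc[["hypertension"]]
  mg_pe    <- stats::runif(n) < mc[["preeclampsia"]]
  mg_tet   <- stats::runif(n) < mc[["tetanus"]]
  if_given   <- stats::runif(n) < params$iron_folate_given_prob
  if_correct <- stats::runif(n) < mc[["iron_folate"]]

  us_pos_draw <- stats::runif(n) < URINE_SUGAR_SENS
  bs_fp       <- stats::runif(n) < BLOOD_SUGAR_FPR
  gct_pos_val <- round(stats::runif(n, GEN_GCT_CUT + 1, 200))
  gct_neg_val <- round(stats::runif(n, 95, GEN_GCT_CUT - 1))

  miss_tet <- stats::runif(n) < params$missingness[["tetanus"]]
  htn_miss_u <- stats::runif(n)   # picks the skipped BP measurement

  ## --- visit skeleton ------------------------------------------------------
  sched <- params$visit_schedule
  ga_list <- lapply(seq_len(n), function(i) c(booking[i], sched[sched > booking[i]]))
  nv <- lengths(ga_list)
  ga <- unlist(ga_list, use.names = FALSE)
  pid <- rep(seq_len(n), times = nv)
  vix <- sequence(nv)
  m <- length(ga)

  ## --- visit-level draws, fixed order --------------------------------------
  sys_n <- round(stats::runif(m, 100, 135)); dia_n <- round(stats::runif(m, 62, 85))
  sys_e <- round(stats::runif(m, 142, 158)); dia_e <- round(stats::runif(m, 92, 105))
  sys_s <- round(stats::runif(m, 162, 190)); dia_s <- round(stats::runif(m, 112, 125))
  miss_hb_u  <- stats::runif(m)
  miss_bmi_u <- stats::runif(m)
  miss_if_u  <- stats::runif(m)

  rl <- function(x) rep(x, times = nv)  # pregnancy-level -> row-level

  is_booking <- vix == 1L

  ## blood pressure
  cat_r <- rl(htn_cat)
  elevated <- (cat_r == "chronic") |
    (cat_r %in% c("gest_mild", "gest_modsev") & ga >= rl(onset_gest))
  severe_row <- cat_r == "gest_modsev" & ga >= rl(onset_gest)
  sys <- ifelse(severe_row, sys_s, ifelse(elevated, sys_e, sys_n))
  dia <- ifelse(severe_row, dia_s, ifelse(elevated, dia_e, dia_n))
  skip_bp <- !rl(scr_htn) & vix == (1L + floor(rl(htn_miss_u) * nv[pid]))
  sys[skip_bp] <- NA_real_; dia[skip_bp] <- NA_real_
  bp_recorded <- !is.na(sys)

  ## diabetes pathway
  us_already <- rl(diabetes & us_pos_draw)           # glycosuria-positive at booking
  urine_sugar <- rep(NA_character_, m)
  do_us <- is_booking & rl(scr_diab)
  urine_sugar[do_us] <- ifelse(us_already[do_us], "positive", "negative")

  in_window <- ga >= GEN_BS_WINDOW[1] & ga <= GEN_BS_WINDOW[2]
  first_window <- first_of(in_window, pid)
  blood_sugar <- rep(NA_character_, m)
  do_bs <- first_window & rl(scr_diab) & !us_already
  bs_pos_p <- rl(diabetes | bs_fp)
  blood_sugar[do_bs] <- ifelse(bs_pos_p[do_bs], "positive", "negative")

  gct <- rep(NA_real_, m)
  gct_at_booking <- is_booking & rl(scr_diab) & us_already
  gct_at_window  <- do_bs & bs_pos_p
  do_gct <- gct_at_booking | gct_at_window
  gct[do_gct] <- ifelse(rl(diabetes)[do_gct], rl(gct_pos_val)[do_gct],
                        rl(gct_neg_val)[do_gct])

  ## urine protein: tested after observed hypertension beyond 20 weeks
  protein <- rep(NA_character_, m)
  do_prot <- bp_recorded & elevated & ga > 20L & rl(scr_pe)
  prot_pos <- rl(pe) & !is.na(rl(pe_onset)) & ga >= rl(pe_onset)
  protein[do_prot] <- ifelse(prot_pos[do_prot], "positive", "negative")

  ## referrals
  diab_pos_row <- do_gct & rl(diabetes)
  ref_hr <- (diab_pos_row & rl(mg_diab)) |
    (first_of(bp_recorded & elevated & cat_r == "chronic", pid) & rl(mg_htn))
  ref_hosp <- (first_of(bp_recorded & severe_row, pid) & rl(mg_htn)) |
    (first_of(do_prot & prot_pos, pid) & rl(mg_pe))
  referral <- ifelse(ref_hosp, "hospital", ifelse(ref_hr, "high_risk_clinic", "none"))

  ## tetanus: status and booster documented at booking
  tet_status <- rep(NA_character_, m)
  tet_dose <- rep(NA, m)
  bk <- is_booking & !rl(miss_tet)
  tet_status[bk] <- ifelse(rl(tet_immune)[bk], "immune", "unknown")
  tet_dose[bk] <- !rl(tet_immune)[bk] & rl(mg_tet)[bk]

  ## iron-folate: dose-specific record at booking (canonical eRegistry form)
  anemic_true <- rl(hb_true) < 11
  if_type <- ifelse(rl(if_correct),
                    ifelse(anemic_true, "treatment", "routine"),
                    ifelse(anemic_true, "routine", "treatment"))
  iron_folate <- rep(NA_character_, m)
  if_rows <- is_booking & miss_if_u >= params$missingness[["iron_folate"]]
  iron_folate[if_rows] <- ifelse(rl(if_given)[if_rows], if_type[if_rows], "none")

  ## hemoglobin at every visit, BMI at booking
  hb <- rl(hb_true)
  hb[miss_hb_u < params$missingness[["hemoglobin"]]] <- NA_real_
  bmi <- rep(NA_real_, m)
  bmi_rows <- is_booking & miss_bmi_u >= params$missingness[["bmi"]]
  bmi[bmi_rows] <- rl(bmi_val)[bmi_rows]

  visits <- data.frame(
    pregnancy_id = pid,
    sector = rl(sector),
    booking_week = rl(booking),
    gestational_age = as.integer(ga),
    urine_sugar = urine_sugar,
    blood_sugar = blood_sugar,
    glucose_challenge_mgdl = gct,
    systolic_bp = sys,
    diastolic_bp = dia,
    urine_protein = protein,
    hemoglobin = hb,
    bmi = bmi,
    tetanus_status = tet_status,
    tetanus_dose_given = tet_dose,
    iron_folate = iron_folate,
    referral = referral,
    stringsAsFactors = FALSE
  )

  truth <- data.frame(
    pregnancy_id = seq_len(n),
    diabetes = diabetes,
    htn_category = htn_cat,
    preeclampsia = pe,
    pe_onset = pe_onset,
    tetanus_immune = tet_immune,
    hb_true = hb_true,
    low_bmi = low_bmi,
    stringsAsFactors = FALSE
  )

  new_anc_cohort(visits, params, "eregistry", truth)
}

#' Degrade a cohort to a data-source dialect
#'
#' The canonical generated cohort has the electronic-registry structure:
#' dose-specific iron-folate documentation (routine supplementation vs anemia
#' treatment) and well-captured tetanus status. The paper-record dialect
#' collapses iron-folate to a single given/not-given checkbox and raises
#' tetanus missingness to the configured paper-record rate; all other fields
#' are unchanged (pregnancy count and gestational ages are always conserved).
#'
#' @param cohort An `anc_cohort`.
#' @param dialect `"paper"` or `"eregistry"`.
#' @return The cohort in the requested dialect.
#' @export
degrade_to_dialect <- function(cohort, dialect) {
  stopifnot(inherits(cohort, "anc_cohort"))
  if (length(dialect) != 1L || !dialect %in% ANC_DIALECTS)
    stop("unknown dialect: must be one of ", paste(ANC_DIALECTS, collapse = ", "),
         call. = FALSE)
  if (dialect == "eregistry") {
    if (attr(cohort, "dialect") == "paper")
      stop("cannot restore the eregistry dialect from a paper-dialect cohort",
           call. = FALSE)
    attr(cohort, "dialect") <- "eregistry"
    return(cohort)
  }
  if (attr(cohort, "dialect") == "paper") return(cohort)

  params <- attr(cohort, "params")
  ## single checkbox: any supplementation counts as given
  ifc <- cohort$iron_folate
  cohort$iron_folate <- ifelse(is.na(ifc), NA, ifc %in% c("routine", "treatment"))

  ## extra tetanus missingness, applied per pregnancy on top of the base rate
  base <- params$missingness[["tetanus"]]
  target <- params$missingness[["tetanus_paper"]]
  p_extra <- max(0, (target - base) / (1 - base))
  if (p_extra > 0) {
    set.seed(params$seed + 9901L)  # documented derivation; independent of generation
    pids <- unique(cohort$pregnancy_id)
    drop <- pids[stats::runif(length(pids)) < p_extra]
    hit <- cohort$pregnancy_id %in% drop
    cohort$tetanus_status[hit] <- NA_character_
    cohort$tetanus_dose_given[hit] <- NA
  }
  attr(cohort, "dialect") <- "paper"
  cohort
}

#' Censor visits after the first hospital referral
#'
#' Women referred to hospital (moderate/severe hypertension, potential
#' pre-eclampsia) do not return to the primary-care clinics, so their
#' later clinic visits never happen. Removes every visit strictly after a
#' pregnancy's first hospital referral; the referral visit itself is kept,
#' and pregnancies without a hospital referral are unchanged. Idempotent.
#'
#' @param cohort An `anc_cohort`.
#' @return The censored cohort.
#' @export
apply_referral_censoring <- function(cohort) {
  stopifnot(inherits(cohort, "anc_cohort"))
  hosp <- cohort$referral == "hospital"
  if (!any(hosp, na.rm = TRUE)) {
    attr(cohort, "censored") <- TRUE
    return(cohort)
  }
  first_ga <- tapply(ifelse(hosp, cohort$gestational_age, NA_integer_),
                     cohort$pregnancy_id, function(x) suppressWarnings(min(x, na.rm = TRUE)))
  cutoff <- first_ga[as.character(cohort$pregnancy_id)]
  keep <- is.infinite(cutoff) | cohort$gestational_age <= cutoff
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_anc_cohort(as.data.frame(out), attr(cohort, "params"),
                 attr(cohort, "dialect"), attr(cohort, "truth"),
                 censored = TRUE)
}

#' @export
print.anc_cohort <- function(x, ...) {
  n <- length(unique(x$pregnancy_id))
  cat(sprintf("Antenatal cohort: %d pregnancies, %d visit observations (%s dialect%s)\n",
              n, nrow(x), attr(x, "dialect"),
              if (isTRUE(attr(x, "censored"))) ", referral-censored" else ""))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
summary.anc_cohort <- function(object, ...) {
  n <- length(unique(object$pregnancy_id))
  out <- list(
    pregnancies = n,
    visits = nrow(object),
    dialect = attr(object, "dialect"),
    mean_visits = nrow(object) / n,
    hospital_referrals = sum(tapply(object$referral == "hospital",
                                    object$pregnancy_id, any, default = FALSE))
  )
  class(out) <- "summary.anc_cohort"
  out
}

#' @export
print.summary.anc_cohort <- function(x, ...) {
  cat(sprintf("Antenatal cohort (%s dialect)\n", x$dialect))
  cat(sprintf("  pregnancies: %d, visits: %d (mean %.1f per pregnancy)\n",
              x$pregnancies, x$visits, x$mean_visits))
  cat(sprintf("  pregnancies with a hospital referral: %d\n", x$hospital_referrals))
  invisible(x)
}
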