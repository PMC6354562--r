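COHORT_SCHEMA_VERSION <- "1.0"

COHORT_COLUMNS <- c(
  pregnancy_id = "integer", sector = "character", booking_week = "integer",
  gestational_age = "integer", urine_sugar = "character",
  blood_sugar = "character", glucose_challenge_mgdl = "numeric",
  systolic_bp = "numeric", diastolic_bp = "numeric",
  urine_protein = "character", hemoglobin = "numeric", bmi = "numeric",
  tetanus_status = "character", tetanus_dose_given = "logical",
  iron_folate = "character", referral = "character"
)

#' Write a cohort to CSV with a JSON sidecar
#'
#' One row per visit observation, empty fields for missing values, and a
#' sidecar `<path>.json` carrying the generating parameters, dialect,
#' censoring state and schema version. `read_cohort(write_cohort(x))` is
#' bit-exact on the schema fields: continuous measurements are generated at
#' fixed decimal precision so the decimal text round-trips to identical
#' doubles.
#'
#' @param cohort An `anc_cohort`.
#' @param path CSV file path; the sidecar is written next to it.
#' @param with_truth If `TRUE`, append the pregnancy-level latent-truth
#'   columns (prefixed `truth_`). Off by default so indicator inputs stay
#'   honest.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, with_truth = FALSE) {
  stopifnot(inherits(cohort, "anc_cohort"))
  df <- as.data.frame(cohort)
  if (with_truth) {
    truth <- attr(cohort, "truth")
    names(truth)[-1] <- paste0("truth_", names(truth)[-1])
    df <- merge(df, truth, by = "pregnancy_id", sort = FALSE)
    df <- df[order(df$pregnancy_id, df$gestational_age), , drop = FALSE]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  params <- unclass(attr(cohort, "params"))
  ## named vectors must become JSON objects, not arrays, to keep their names
  for (f in c("screening_compliance", "management_compliance", "missingness"))
    params[[f]] <- as.list(params[[f]])
  meta <- list(
    schema_version = COHORT_SCHEMA_VERSION,
    dialect = attr(cohort, "dialect"),
    censored = isTRUE(attr(cohort, "censored")),
    with_truth = with_truth,
    params = params
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path CSV file path with its `<path>.json` sidecar alongside.
#' @return An `anc_cohort`.
#' @export
read_cohort <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("cohort sidecar not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  cls <- COHORT_COLUMNS
  if (identical(meta$dialect, "paper")) cls[["iron_folate"]] <- "logical"

  header <- names(utils::read.csv(path, nrows = 1L, check.names = FALSE))
  truth_cols <- grep("^truth_", header, value = TRUE)
  col_classes <- c(cls, stats::setNames(rep("character", length(truth_cols)),
                                        truth_cols))
  df <- utils::read.csv(path, colClasses = col_classes[header],
                        na.strings = "", stringsAsFactors = FALSE)

  p <- meta$params
  ## JSON integers (e.g. a probability written as 1) must come back as doubles
  for (f in c("incidence_diabetes", "incidence_chronic_htn",
              "incidence_gest_htn_mild", "incidence_gest_htn_modsev",
              "incidence_preeclampsia", "anemia_hb_mean", "anemia_hb_sd",
              "severe_anemia_floor", "low_bmi_prob",
              "tetanus_immune_at_entry_prob", "iron_folate_given_prob",
              "public_sector_prob"))
    p[[f]] <- as.numeric(p[[f]])
  params <- cohort_params(
    n_pregnancies = p$n_pregnancies,
    incidence_diabetes = p$incidence_diabetes,
    incidence_chronic_htn = p$incidence_chronic_htn,
    incidence_gest_htn_mild = p$incidence_gest_htn_mild,
    incidence_gest_htn_modsev = p$incidence_gest_htn_modsev,
    incidence_preeclampsia = p$incidence_preeclampsia,
    anemia_hb_mean = p$anemia_hb_mean,
    anemia_hb_sd = p$anemia_hb_sd,
    severe_anemia_floor = p$severe_anemia_floor,
    low_bmi_prob = p$low_bmi_prob,
    tetanus_immune_at_entry_prob = p$tetanus_immune_at_entry_prob,
    screening_compliance = vapply(as.list(p$screening_compliance), as.numeric, 0),
    management_compliance = vapply(as.list(p$management_compliance), as.numeric, 0),
    iron_folate_given_prob = p$iron_folate_given_prob,
    missingness = vapply(as.list(p$missingness), as.numeric, 0),
    visit_schedule = p$visit_schedule,
    booking_week_range = p$booking_week_range,
    public_sector_prob = p$public_sector_prob,
    seed = p$seed
  )

  truth <- NULL
  if (length(truth_cols)) {
    tr <- df[!duplicated(df$pregnancy_id),
             c("pregnancy_id", truth_cols), drop = FALSE]
    names(tr) <- sub("^truth_", "", names(tr))
    tr$diabetes <- as.logical(tr$diabetes)
    tr$preeclampsia <- as.logical(tr$preeclampsia)
    tr$pe_onset <- as.integer(tr$pe_onset)
    tr$tetanus_immune <- as.logical(tr$tetanus_immune)
    tr$hb_true <- as.numeric(tr$hb_true)
    tr$low_bmi <- as.logical(tr$low_bmi)
    rownames(tr) <- NULL
    truth <- tr
    df <- df[, setdiff(names(df), truth_cols), drop = FALSE]
  }
  new_anc_cohort(df, params, meta$dialect, truth,
                 censored = isTRUE(meta$censored))
}
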