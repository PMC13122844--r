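CONDITIONS <- c("LH", "RH", "LF", "RF", "TONGUE")
ONSET_CODES <- c("UL", "LL", "B")

# Onset site -> first-affected somatotopic fields. Laterality of limb onset
# is not recorded in the clinical table, so limb onsets are mapped
# bilaterally, mirroring the convention that bulbar onset is bilateral.
ONSET_ROI_MAP <- list(UL = c("LH", "RH"),
                      LL = c("LF", "RF"),
                      B  = "TONGUE")

#' Read a clinical table of ALS patient records
#'
#' Parses a comma-separated UTF-8 table with one row per patient and the
#' columns `patient_id`, `age_years`, `sex` (F/M), `onset_type` (UL =
#' upper limb, LL = lower limb, B = bulbar), `alsfrs_total` (revised ALS
#' Functional Rating Scale, 0-48, lower = more impaired), `kings_stage`
#' (King's staging, 1-3) and `pumns` (Penn Upper Motor Neuron Scale,
#' 0-32, higher = more impaired). Additional columns (e.g.
#' `matched_control`) are carried through unchanged.
#'
#' The first-affected somatotopic fields are derived from the onset type
#' (UL -> LH+RH, LL -> LF+RF, B -> TONGUE) and returned as the
#' list-column `first_affected_rois`.
#'
#' A packaged fixture reproducing the study's patient table verbatim is at
#' `system.file("extdata", "clinical_table1.csv", package = "funcphen")`.
#'
#' @param path CSV file path.
#' @return a `data.frame` with one row per patient and the columns above;
#'   empty input yields a zero-row frame with a warning.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path))
    fp_stop("funcphen_file_not_found", "clinical table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        colClasses = c(patient_id = "character",
                                       sex = "character",
                                       onset_type = "character"))
  required <- c("patient_id", "age_years", "sex", "onset_type",
                "alsfrs_total", "kings_stage", "pumns")
  missing <- setdiff(required, names(df))
  if (length(missing))
    fp_stop("funcphen_bad_clinical", "missing column(s): %s",
            paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    fp_warn("funcphen_empty_clinical", "clinical table %s has no rows", path)
    df$first_affected_rois <- list()
    return(df)
  }
  for (i in seq_len(nrow(df))) {
    row_id <- df$patient_id[i]
    if (!df$onset_type[i] %in% ONSET_CODES)
      fp_stop("funcphen_bad_onset",
              "row '%s': unknown onset code '%s'", row_id, df$onset_type[i])
    if (!df$sex[i] %in% c("F", "M"))
      fp_stop("funcphen_bad_clinical", "row '%s': sex must be F or M", row_id)
    if (is.na(df$age_years[i]) || df$age_years[i] <= 0)
      fp_stop("funcphen_score_out_of_range",
              "row '%s': age must be positive", row_id)
    if (is.na(df$alsfrs_total[i]) ||
        df$alsfrs_total[i] < 0 || df$alsfrs_total[i] > 48)
      fp_stop("funcphen_score_out_of_range",
              "row '%s': ALSFRS-R total outside 0-48", row_id)
    if (!df$kings_stage[i] %in% 1:3)
      fp_stop("funcphen_score_out_of_range",
              "row '%s': King's stage must be 1, 2 or 3", row_id)
    if (is.na(df$pumns[i]) || df$pumns[i] < 0 || df$pumns[i] > 32)
      fp_stop("funcphen_score_out_of_range",
              "row '%s': PUMNS outside 0-32", row_id)
  }
  df$first_affected_rois <- unname(ONSET_ROI_MAP[df$onset_type])
  df
}

#' Summary statistics of a patient cohort
#'
#' Convenience recomputation of the headline cohort descriptives: mean and
#' population standard deviation of age, PUMNS range, and onset-type
#' counts.
#'
#' @param records a clinical `data.frame` from [read_clinical_table()].
#' @return a list with `n`, `age_mean`, `age_sd_pop`, `pumns_max`,
#'   `pumns_min` and `onset_counts`.
#' @export
clinical_summary <- function(records) {
  n <- nrow(records)
  age <- records$age_years
  list(n = n,
       age_mean = mean(age),
       age_sd_pop = sqrt(mean((age - mean(age))^2)),
       pumns_max = max(records$pumns),
       pumns_min = min(records$pumns),
       onset_counts = table(factor(records$onset_type, levels = ONSET_CODES)))
}
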