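## Patient-record table input/output and validation.
##
## Records travel as a plain data.frame, one row per patient, with the
## documented column set below (CSV: comma-separated, UTF-8, dot decimal).
## Cartilage grades are serialized as the strings "0-I", "II", "III",
## "IV-focal" (modified Outerbridge categories); sex is coded 0 = female,
## 1 = male; the group label is "R" (responder, KOOS pain > 75) or "MPMS"
## (medial postmeniscectomy syndrome, KOOS pain <= 75).

.recordColumns <- c("patient_id", "group", "sex", "age", "height", "weight",
                    "bmi", "koos_symptoms", "koos_pain", "koos_adl",
                    "koos_sport", "koos_qol", "koos_total",
                    "cart_mfc", "cart_mtp", "cart_lfc", "cart_ltp")

.cartilageLevels <- c("0-I", "II", "III", "IV-focal")

#' KOOS pain threshold splitting responders from MPMS
#'
#' Patients with a KOOS pain subscore strictly above this value are
#' responders (group R); pain at or below it defines medial
#' postmeniscectomy syndrome (group MPMS).
#' @export
KOOS_SPLIT <- 75

#' Validate a patient-record table
#'
#' Enforces the record invariants: all documented columns present and
#' non-missing, KOOS subscores in \[0, 100\], sex in \{0, 1\}, cartilage
#' grades among the modified Outerbridge categories, BMI consistent with
#' weight/(height/100)^2 within 0.1 kg/m^2 (recomputed with a warning when
#' not), and group label consistent with the KOOS pain split at
#' `r KOOS_SPLIT`.
#'
#' @param records data.frame of patient records.
#' @return the validated (possibly BMI-recomputed) data.frame.
#' @export
validateRecords <- function(records) {
  missingCols <- setdiff(.recordColumns, names(records))
  if (length(missingCols))
    stop("record table is missing columns: ", paste(missingCols, collapse = ", "))
  for (cn in .recordColumns) {
    bad <- which(is.na(records[[cn]]) | (is.character(records[[cn]]) & !nzchar(records[[cn]])))
    if (length(bad))
      stop("missing '", cn, "' in record row(s): ", paste(bad, collapse = ", "))
  }
  if (!all(records$sex %in% c(0, 1)))
    stop("sex must be coded 0 (female) / 1 (male)")
  if (!all(records$group %in% c("R", "MPMS")))
    stop("group must be 'R' or 'MPMS'")
  for (cn in c("cart_mfc", "cart_mtp", "cart_lfc", "cart_ltp")) {
    bad <- which(!records[[cn]] %in% .cartilageLevels)
    if (length(bad))
      stop("invalid cartilage grade in '", cn, "' row(s): ",
           paste(bad, collapse = ", "))
  }
  koosCols <- c("koos_symptoms", "koos_pain", "koos_adl", "koos_sport",
                "koos_qol", "koos_total")
  for (cn in koosCols) {
    if (any(records[[cn]] < 0 | records[[cn]] > 100))
      stop("KOOS values in '", cn, "' must lie in [0, 100]")
  }
  bmiExpected <- records$weight / (records$height / 100)^2
  off <- which(abs(records$bmi - bmiExpected) > 0.1)
  if (length(off)) {
    warning("BMI inconsistent with weight/height in row(s) ",
            paste(off, collapse = ", "), "; recomputed")
    records$bmi[off] <- bmiExpected[off]
  }
  shouldBeR <- records$koos_pain > KOOS_SPLIT
  wrong <- which((records$group == "R") != shouldBeR)
  if (length(wrong))
    stop("group label inconsistent with KOOS pain split at ", KOOS_SPLIT,
         " (R iff pain > ", KOOS_SPLIT, ") in row(s): ",
         paste(wrong, collapse = ", "))
  records
}

#' Read a patient-record CSV
#'
#' @param path CSV file (comma-separated, UTF-8, dot decimal) with the
#'   documented header; see [validateRecords()] for the enforced
#'   invariants.
#' @return validated data.frame of patient records.
#' @export
readRecords <- function(path) {
  if (!file.exists(path)) stop("record file not found: ", path)
  rec <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validateRecords(rec)
}

#' Write a patient-record CSV
#' @param records validated record data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRecords <- function(records, path) {
  records <- validateRecords(records)
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
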