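# Clinical cohort table: parsing, validation, group summaries.
#
# The table schema follows the usual DOC case-series layout: one row per
# patient with diagnosis (MCS or UWS; the legacy label VS is accepted as a
# synonym of UWS), sex/age, aetiology, lesion description, months since
# injury, the six CRS-R sub-scores (auditory, visual, motor, verbal,
# communication, arousal) and the CRS-R total.

CRS_SUB_COLS <- c("crs_a", "crs_v", "crs_m", "crs_verbal", "crs_comm", "crs_arousal")
CRS_SUB_MAX <- c(crs_a = 4L, crs_v = 5L, crs_m = 6L, crs_verbal = 3L,
                 crs_comm = 2L, crs_arousal = 3L)

#' Parse a clinical cohort table
#'
#' Reads a tab-delimited cohort table (UTF-8, header required) into a
#' validated data frame with one row per patient. Both a packed `sex_age`
#' column (e.g. `"M/60"`) and separate `sex` / `age` columns are accepted.
#' Diagnosis labels `"VS"` and `"UWS"` are synonyms and are normalized to
#' `"UWS"`. Aetiology maps deterministically onto a traumatic/nontraumatic
#' grouping: trauma is traumatic; hemorrhage and anoxia are nontraumatic.
#'
#' @param path Path to a tab-delimited file. A packaged example reproducing a
#'   published 32-patient DOC case series is available via
#'   `system.file("extdata", "table1_cohort.tsv", package = "docnet")`.
#' @param validate_totals If `TRUE` (default), a row whose CRS-R total does
#'   not equal the sum of its six sub-scores is an error naming the row.
#' @return A `data.frame` of class `doc_cohort` with columns `patient_id`,
#'   `diagnosis` (factor MCS/UWS), `sex` (factor M/F), `age`, `etiology`
#'   (factor trauma/hemorrhage/anoxia), `traumatic_group` (factor
#'   traumatic/nontraumatic), `lesion`, `months_since_injury`, the six
#'   `crs_*` sub-scores and `crs_total`.
#' @export
#' @examples
#' tab <- parse_cohort_table(system.file("extdata", "table1_cohort.tsv",
#'                                       package = "docnet"))
#' summarize_group(tab, diagnosis = "UWS")
parse_cohort_table <- function(path, validate_totals = TRUE) {
  if (!file.exists(path)) stop_docnet("io", "cohort file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = TRUE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(df) == 0L && ncol(df) == 0L) {
    stop_docnet("schema", "cohort file has no header: %s", path)
  }
  names(df) <- tolower(names(df))

  packed <- "sex_age" %in% names(df)
  required <- c("patient_id", "diagnosis",
                if (packed) "sex_age" else c("sex", "age"),
                "etiology", "lesion", "months_since_injury",
                CRS_SUB_COLS, "crs_total")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_docnet("schema", "cohort table is missing column(s): %s",
                paste(missing, collapse = ", "))
  }

  if (packed && nrow(df)) {
    parts <- strsplit(df$sex_age, "/", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 2L
    if (any(bad)) stop_docnet("schema", "malformed sex_age value in row(s): %s",
                              paste(which(bad), collapse = ", "))
    df$sex <- vapply(parts, `[[`, "", 1L)
    df$age <- vapply(parts, `[[`, "", 2L)
  }

  out <- data.frame(
    patient_id = df$patient_id,
    diagnosis = toupper(trimws(df$diagnosis)),
    sex = toupper(trimws(df$sex)),
    age = as.integer(df$age),
    etiology = tolower(trimws(df$etiology)),
    lesion = df$lesion,
    months_since_injury = as.numeric(df$months_since_injury),
    stringsAsFactors = FALSE
  )
  for (cc in c(CRS_SUB_COLS, "crs_total")) out[[cc]] <- as.integer(df[[cc]])

  if (nrow(out)) {
    out$diagnosis[out$diagnosis == "VS"] <- "UWS"
    bad_dx <- !out$diagnosis %in% c("MCS", "UWS")
    if (any(bad_dx)) stop_docnet("schema", "unknown diagnosis in row(s): %s",
                                 paste(which(bad_dx), collapse = ", "))
    bad_et <- !out$etiology %in% c("trauma", "hemorrhage", "anoxia")
    if (any(bad_et)) stop_docnet("schema", "unknown etiology in row(s): %s",
                                 paste(which(bad_et), collapse = ", "))
    bad_sex <- !out$sex %in% c("M", "F")
    if (any(bad_sex)) stop_docnet("schema", "unknown sex in row(s): %s",
                                  paste(which(bad_sex), collapse = ", "))
    if (any(!is.finite(out$age) | out$age <= 0)) {
      stop_docnet("validation", "age must be a positive integer")
    }
    if (any(!is.finite(out$months_since_injury) | out$months_since_injury <= 0)) {
      stop_docnet("validation", "months_since_injury must be > 0")
    }
    subs <- as.matrix(out[CRS_SUB_COLS])
    if (any(subs < 0L)) stop_docnet("validation", "CRS-R sub-scores must be >= 0")
    if (validate_totals) {
      mism <- which(rowSums(subs) != out$crs_total)
      if (length(mism)) {
        stop_docnet("validation",
                    "CRS-R total does not match sub-score sum in row(s): %s (patient %s)",
                    paste(mism, collapse = ", "),
                    paste(out$patient_id[mism], collapse = ", "))
      }
    }
  }

  out$diagnosis <- factor(out$diagnosis, levels = c("MCS", "UWS"))
  out$sex <- factor(out$sex, levels = c("M", "F"))
  out$etiology <- factor(out$etiology, levels = c("trauma", "hemorrhage", "anoxia"))
  out$traumatic_group <- factor(
    ifelse(out$etiology == "trauma", "traumatic", "nontraumatic"),
    levels = c("traumatic", "nontraumatic")
  )
  out <- out[c("patient_id", "diagnosis", "sex", "age", "etiology",
               "traumatic_group", "lesion", "months_since_injury",
               CRS_SUB_COLS, "crs_total")]
  class(out) <- c("doc_cohort", "data.frame")
  out
}

#' Write a cohort table
#'
#' Serializes a cohort back to the tab-delimited interchange format read by
#' [parse_cohort_table()] (separate `sex`/`age` columns). Round-trips all
#' field values.
#'
#' @param cohort A `doc_cohort` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  keep <- c("patient_id", "diagnosis", "sex", "age", "etiology", "lesion",
            "months_since_injury", CRS_SUB_COLS, "crs_total")
  df <- as.data.frame(cohort)[keep]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Filter and summarize a cohort group
#'
#' Applies the diagnosis and/or aetiology-group filters used throughout the
#' pipeline and summarizes the selected patients.
#'
#' @param cohort A `doc_cohort` data frame from [parse_cohort_table()].
#' @param diagnosis Optional `"MCS"` or `"UWS"` filter.
#' @param traumatic_group Optional `"traumatic"` or `"nontraumatic"` filter.
#' @return A list with `n`, `mean_age` (unrounded), `mean_age_rounded`
#'   (one decimal and nearest integer, half away from zero), `age_min`,
#'   `age_max`, `n_male` and `n_traumatic`. An empty selection yields `n = 0`
#'   with `NA` summaries.
#' @export
summarize_group <- function(cohort, diagnosis = NULL, traumatic_group = NULL) {
  sel <- rep(TRUE, nrow(cohort))
  if (!is.null(diagnosis)) {
    diagnosis <- toupper(diagnosis)
    if (diagnosis == "VS") diagnosis <- "UWS"
    sel <- sel & cohort$diagnosis == diagnosis
  }
  if (!is.null(traumatic_group)) sel <- sel & cohort$traumatic_group == traumatic_group
  g <- cohort[sel, , drop = FALSE]
  if (nrow(g) == 0L) {
    return(list(n = 0L, mean_age = NA_real_, mean_age_rounded = NA_real_,
                mean_age_int = NA_integer_, age_min = NA_integer_,
                age_max = NA_integer_, n_male = 0L, n_traumatic = 0L))
  }
  mean_age <- mean(g$age)
  list(
    n = nrow(g),
    mean_age = mean_age,
    mean_age_rounded = round_half_up(mean_age, 1),
    mean_age_int = as.integer(round_half_up(mean_age)),
    age_min = min(g$age),
    age_max = max(g$age),
    n_male = sum(g$sex == "M"),
    n_traumatic = sum(g$traumatic_group == "traumatic")
  )
}

#' Subject filter as row indices
#'
#' @param cohort A `doc_cohort` data frame.
#' @param diagnosis,traumatic_group Optional filters as in [summarize_group()].
#' @return Integer row indices of the selected patients.
#' @export
cohort_rows <- function(cohort, diagnosis = NULL, traumatic_group = NULL) {
  sel <- rep(TRUE, nrow(cohort))
  if (!is.null(diagnosis)) {
    diagnosis <- toupper(diagnosis)
    if (diagnosis == "VS") diagnosis <- "UWS"
    sel <- sel & cohort$diagnosis == diagnosis
  }
  if (!is.null(traumatic_group)) sel <- sel & cohort$traumatic_group == traumatic_group
  which(sel)
}
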