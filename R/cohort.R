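# Cohort tables: one row per patient with molecular markers, pCR label,
# imaging center, and file references for the image and mask volumes.

cohort_columns <- c("patient_id", "her2", "er", "pr", "ki67", "pcr_label",
                    "center_id", "image_path", "gland_mask_path", "lesion_mask_path")

validate_cohort <- function(tbl) {
  missing <- setdiff(cohort_columns, names(tbl))
  if (length(missing) > 0) {
    stop_cs(paste0("cohort is missing column(s): ", paste(missing, collapse = ", ")),
            "cs_schema_error")
  }
  dup <- tbl$patient_id[duplicated(tbl$patient_id)]
  if (length(dup) > 0) {
    stop_cs(paste0("duplicate patient_id: ", paste(unique(dup), collapse = ", ")),
            "cs_validation_error")
  }
  for (col in c("her2", "er", "pr", "pcr_label")) {
    bad <- which(!(tbl[[col]] %in% c(0, 1)))
    if (length(bad) > 0) {
      stop_cs(sprintf("column %s must be 0/1; offending row(s): %s",
                      col, paste(bad, collapse = ", ")), "cs_validation_error")
    }
  }
  bad <- which(!is.finite(tbl$ki67) | tbl$ki67 < 0 | tbl$ki67 > 1)
  if (length(bad) > 0) {
    stop_cs(sprintf("ki67 must lie in [0,1]; offending row(s): %s",
                    paste(bad, collapse = ", ")), "cs_validation_error")
  }
  invisible(tbl)
}

#' Load a patient cohort table from CSV
#'
#' The cohort CSV has one row per patient and the fixed header
#' `patient_id, her2, er, pr, ki67, pcr_label, center_id, image_path,
#' gland_mask_path, lesion_mask_path`.  HER2/ER/PR and the pCR label are
#' binary (0/1); Ki-67 is a fraction in `[0, 1]`; `center_id` identifies the
#' imaging center (scanner) the sample came from.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one validated row per patient.
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop_cs(sprintf("file does not exist: %s", path), "cs_io_error")
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_cohort(tbl)
  tbl$patient_id <- as.character(tbl$patient_id)
  tbl$center_id <- as.character(tbl$center_id)
  tbl
}

#' Save a patient cohort table to CSV
#'
#' @param cohort A cohort tibble (see [load_cohort()] for the schema).
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
save_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort[, cohort_columns], path, row.names = FALSE)
  invisible(path)
}

#' Encode a patient's molecular markers as a numeric vector
#'
#' Produces the marker vector `(her2, er, pr, ki67)` consumed by the
#' tabular branch of the fusion model: binary receptor statuses as 0/1 and
#' the Ki-67 proliferation index kept as a fraction in `[0, 1]`.
#'
#' @param record A single cohort row (list or one-row data frame) with
#'   fields `her2`, `er`, `pr`, `ki67`.
#' @return Named numeric vector of length 4.
#' @export
encode_markers <- function(record) {
  for (f in c("her2", "er", "pr", "ki67")) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      stop_cs(sprintf("marker field missing or invalid: %s", f), "cs_encoding_error")
    }
  }
  assert_that(record$ki67 >= 0 && record$ki67 <= 1, "ki67 must lie in [0,1]",
              "cs_encoding_error")
  assert_that(all(c(record$her2, record$er, record$pr) %in% c(0, 1)),
              "her2/er/pr must be 0 or 1", "cs_encoding_error")
  c(her2 = as.numeric(record$her2), er = as.numeric(record$er),
    pr = as.numeric(record$pr), ki67 = as.numeric(record$ki67))
}
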