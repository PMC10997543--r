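## Delimited-text cohort I/O and report serialization. All tables are plain
## text with a header row; `died` and hospital flags are encoded 0/1.

.patient_cols <- c("patient_id", "hospital_id", "age", "sex", "race",
                   "insurance", "procedure", "comorbidity_index", "year",
                   "svi", "travel_minutes", "died")
.hospital_cols <- c("hospital_id", "teaching", "medical_school",
                    "cancer_program", "fte_per_bed", "beds",
                    "operating_rooms",
                    paste0("mean_annual_volume_", c("ES", "PN", "PD", "PR")))

#' Write a cohort to delimited text files
#'
#' @param cohort list with `patients` and `hospitals` (e.g. from
#'   [simulate_cohort()])
#' @param dir output directory (created if needed)
#' @param delim field delimiter (default comma)
#' @return invisibly, the two file paths written
#' @export
write_cohort <- function(cohort, dir, delim = ",") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pp <- file.path(dir, "patients.csv")
  hp <- file.path(dir, "hospitals.csv")
  utils::write.table(cohort$patients, pp, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  utils::write.table(cohort$hospitals, hp, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(patients = pp, hospitals = hp))
}

#' Read and validate a patient/hospital cohort from delimited text
#'
#' Schema-validated: required columns must be present (errors name the
#' missing column), `died` must be 0/1 (row-level errors cite line numbers),
#' and extra columns are preserved but ignored by the models.
#'
#' @param patient_path path to the patient table
#' @param hospital_path path to the hospital table
#' @param delim field delimiter (default comma; e.g. `";"` for
#'   semicolon-delimited files)
#' @return list with `patients` and `hospitals` data frames
#' @export
read_cohort <- function(patient_path, hospital_path, delim = ",") {
  for (p in c(patient_path, hospital_path)) {
    if (!file.exists(p)) ihm_validation_error(paste0("file not found: ", p))
  }
  patients <- utils::read.table(patient_path, header = TRUE, sep = delim,
                                stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  hospitals <- utils::read.table(hospital_path, header = TRUE, sep = delim,
                                 stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss_p <- setdiff(.patient_cols, names(patients))
  if (length(miss_p)) {
    ihm_validation_error(paste0("patient table missing required column(s): ",
                                paste(miss_p, collapse = ", ")))
  }
  miss_h <- setdiff(.hospital_cols, names(hospitals))
  if (length(miss_h)) {
    ihm_validation_error(paste0("hospital table missing required column(s): ",
                                paste(miss_h, collapse = ", ")))
  }
  bad <- which(!patients$died %in% c(0, 1))
  if (length(bad)) {
    ihm_validation_error(sprintf(
      "non-binary `died` value at line(s) %s of %s (header is line 1)",
      paste(head(bad + 1L, 5), collapse = ", "), patient_path))
  }
  list(patients = patients, hospitals = hospitals)
}

#' Write an analysis report to JSON plus companion delimited tables
#'
#' Numbers are serialized at full precision; display rounding lives only in
#' rendered tables.
#'
#' @param report an `analysis_report` from [run_analysis()]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)

  slim <- report
  slim$decomposition <- .dec_as_list(report$decomposition)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(slim, jp, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  paths <- c(paths, jp)

  write_tab <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$decomposition)) {
    dec <- report$decomposition
    tabs <- list(as.data.frame(dec))
    for (s in names(dec$strata %||% list())) {
      tabs[[length(tabs) + 1L]] <- as.data.frame(dec$strata[[s]])
    }
    write_tab(do.call(rbind, tabs), "variance_shares.csv")
  }
  if (!is.null(report$profiles)) write_tab(report$profiles, "hospital_profiles.csv")
  if (!is.null(report$funnel)) write_tab(report$funnel, "funnel_limits.csv")
  if (!is.null(report$rates)) write_tab(report$rates, "mortality_rates.csv")
  invisible(paths)
}

.dec_as_list <- function(dec) {
  if (is.null(dec)) return(NULL)
  one <- function(d) list(
    stratum = d$stratum,
    cumulative = as.list(d$cumulative),
    contributions = as.list(d$contributions),
    unexplained = unname(d$unexplained),
    components_per_model = d$components_per_model
  )
  out <- one(dec)
  if (!is.null(dec$strata)) out$strata <- lapply(dec$strata, one)
  out
}
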