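## Model specification: covariate blocks, reference levels, scalings, and
## construction of the analysis frame shared by all four nested models.

#' Specify the nested outcome models
#'
#' Defines the outcome, the four ordered covariate blocks added sequentially
#' across the nested models, reference levels for categorical covariates, and
#' the clustering variable. Default blocks:
#' * `PC` (patient characteristics): age, sex, race, comorbidity_index,
#'   year, procedure;
#' * `CV` (case volume): mean_annual_volume, entered per 10 procedures as the
#'   volume of the patient's own procedure at the treating hospital;
#' * `HC` (hospital characteristics): teaching, medical_school,
#'   cancer_program, fte_per_bed;
#' * `SDoH` (social determinants): svi, insurance, travel_minutes (per 10
#'   minutes).
#'
#' Insurance sits in the SDoH block (the block layout of the fully adjusted
#' model), so it enters at the fourth nested model.
#'
#' @param outcome binary outcome column name
#' @param blocks named list of character vectors, in nesting order
#' @param reference_levels named list: variable -> reference category
#' @param cluster clustering (random intercept) column name
#' @param scaling named vector: variable -> divisor applied before fitting
#'   (coefficients are then per `scaling` units)
#' @return object of class `model_spec`
#' @export
model_spec <- function(outcome = "died",
                       blocks = list(
                         PC = c("age", "sex", "race", "comorbidity_index",
                                "year", "procedure"),
                         CV = "mean_annual_volume",
                         HC = c("teaching", "medical_school",
                                "cancer_program", "fte_per_bed"),
                         SDoH = c("svi", "insurance", "travel_minutes")
                       ),
                       reference_levels = list(sex = "male", race = "White",
                                               insurance = "Private",
                                               procedure = "ES",
                                               year = "2010"),
                       cluster = "hospital_id",
                       scaling = c(mean_annual_volume = 10,
                                   travel_minutes = 10)) {
  all_vars <- unlist(blocks, use.names = FALSE)
  dup <- all_vars[duplicated(all_vars)]
  if (length(dup)) {
    ihm_validation_error(paste0("covariate(s) in more than one block: ",
                                paste(unique(dup), collapse = ", ")))
  }
  structure(list(outcome = outcome, blocks = blocks,
                 reference_levels = reference_levels, cluster = cluster,
                 scaling = scaling),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> outcome:", x$outcome, " cluster:", x$cluster, "\n")
  for (b in names(x$blocks)) {
    cat(sprintf("  %-5s %s\n", b, paste(x$blocks[[b]], collapse = ", ")))
  }
  invisible(x)
}

## Build the shared analysis frame: merge hospital attributes onto patients,
## derive the per-patient volume covariate, apply scalings, set factor
## reference levels, and restrict once to complete cases on ALL model
## variables so the four nested models share one estimation sample.
build_model_frame <- function(patients, hospitals, spec,
                              blocks = names(spec$blocks)) {
  if (!all(patients$hospital_id %in% hospitals$hospital_id)) {
    missing_ids <- setdiff(unique(patients$hospital_id), hospitals$hospital_id)
    ihm_validation_error(paste0("patients reference unknown hospital_id(s): ",
                                paste(head(missing_ids, 5), collapse = ", ")))
  }
  y <- patients[[spec$outcome]]
  if (is.null(y)) {
    ihm_validation_error(paste0("outcome column `", spec$outcome, "` not found"))
  }
  if (!all(y %in% c(0, 1))) {
    ihm_validation_error(paste0("outcome `", spec$outcome, "` must be binary 0/1"))
  }

  hidx <- match(patients$hospital_id, hospitals$hospital_id)
  d <- patients
  for (nm in c("teaching", "medical_school", "cancer_program", "fte_per_bed")) {
    if (nm %in% names(hospitals)) d[[nm]] <- hospitals[[nm]][hidx]
  }
  volcols <- paste0("mean_annual_volume_", .procedures)
  if (all(volcols %in% names(hospitals))) {
    volmat <- as.matrix(hospitals[volcols])
    d$mean_annual_volume <- volmat[cbind(hidx, match(patients$procedure, .procedures))]
  }

  for (nm in names(spec$scaling)) {
    if (nm %in% names(d)) d[[nm]] <- d[[nm]] / spec$scaling[[nm]]
  }

  ## complete cases across EVERY model variable (all blocks), once
  all_vars <- intersect(unlist(spec$blocks, use.names = FALSE), names(d))
  keep <- complete.cases(d[c(spec$outcome, spec$cluster, all_vars)])
  n_dropped <- sum(!keep)
  d <- d[keep, , drop = FALSE]

  ## factors with reference levels; drop unused levels, and drop from the
  ## model any requested variable that is constant on this sample
  used <- intersect(unlist(spec$blocks[blocks], use.names = FALSE), names(d))
  dropped_terms <- character(0)
  for (nm in used) {
    if (is.character(d[[nm]]) || is.factor(d[[nm]]) || nm == "year") {
      f <- droplevels(factor(d[[nm]]))
      ref <- spec$reference_levels[[nm]]
      if (!is.null(ref) && ref %in% levels(f)) f <- relevel(f, ref = ref)
      d[[nm]] <- f
      if (nlevels(f) < 2L) dropped_terms <- c(dropped_terms, nm)
    } else if (length(unique(d[[nm]])) < 2L) {
      dropped_terms <- c(dropped_terms, nm)
    }
  }
  used <- setdiff(used, dropped_terms)
  d[[spec$cluster]] <- factor(d[[spec$cluster]])

  list(data = d, terms = used, n_dropped = n_dropped,
       dropped_terms = dropped_terms,
       design_info = list(
         blocks = spec$blocks[blocks],
         scaling = spec$scaling,
         reference_levels = spec$reference_levels,
         outcome = spec$outcome, cluster = spec$cluster
       ))
}
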