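## Synthetic cohort generation: hospitals with structural attributes and
## random intercepts, then patients nested in hospitals with a Bernoulli
## outcome from the configured logistic model.

#' Generate hospitals and the simulation ground truth
#'
#' Draws `n_hospitals` facilities: which of the four procedures each one
#' offers (independent Bernoulli per procedure; a hospital offering none is
#' redrawn), per-procedure mean annual volumes (log-normal, 0 when not
#' offered), structural attributes, and the hospital random intercepts
#' `u_j ~ N(0, sigma_u^2)`. With `sigma_u = 0` every intercept is exactly 0.
#'
#' Draws come from named substreams of the global seed
#' ([substream_seed()]: `"hospitals"` for attributes, `"intercepts"` for
#' `u_j`), so the output is deterministic given `(config, seed)` and
#' unaffected by later generation stages.
#'
#' @param config a [simulation_config()]
#' @return list with `hospitals` (data frame: hospital_id, teaching,
#'   medical_school, cancer_program, fte_per_bed, beds, operating_rooms,
#'   mean_annual_volume_ES/PN/PD/PR) and `truth` (class `synthetic_truth`:
#'   true_effects, sigma_u, intercept, hospital_intercepts)
#' @export
generate_hospitals <- function(config) {
  validate_config(config)
  J <- config$n_hospitals
  hp <- config$hospital

  set.seed(substream_seed(config$seed, "hospitals"))
  offers <- sapply(.procedures, function(pr) {
    rbinom(J, 1, hp$offer_prob[[pr]]) == 1L
  })
  offers <- matrix(offers, nrow = J, dimnames = list(NULL, .procedures))
  ## every hospital must offer at least one procedure
  none <- which(rowSums(offers) == 0)
  while (length(none)) {
    for (pr in .procedures) {
      offers[none, pr] <- rbinom(length(none), 1, hp$offer_prob[[pr]]) == 1L
    }
    none <- which(rowSums(offers) == 0)
  }
  vols <- vapply(.procedures, function(pr) {
    v <- rlnorm(J, hp$volume[[pr]]$meanlog, hp$volume[[pr]]$sdlog)
    ifelse(offers[, pr], v, 0)
  }, numeric(J))
  vols <- matrix(vols, nrow = J, dimnames = list(NULL, .procedures))
  hospitals <- data.frame(
    hospital_id = sprintf("H%04d", seq_len(J)),
    teaching = rbinom(J, 1, hp$teaching),
    medical_school = rbinom(J, 1, hp$medical_school),
    cancer_program = rbinom(J, 1, hp$cancer_program),
    fte_per_bed = rlnorm(J, hp$fte_per_bed$meanlog, hp$fte_per_bed$sdlog),
    beds = pmax(1L, round(rlnorm(J, hp$beds$meanlog, hp$beds$sdlog))),
    operating_rooms = pmax(1L, round(rlnorm(J, hp$operating_rooms$meanlog,
                                            hp$operating_rooms$sdlog))),
    stringsAsFactors = FALSE
  )
  for (pr in .procedures) {
    hospitals[[paste0("mean_annual_volume_", pr)]] <- vols[, pr]
  }

  set.seed(substream_seed(config$seed, "intercepts"))
  u <- if (config$sigma_u == 0) rep(0, J) else rnorm(J, 0, config$sigma_u)
  truth <- structure(list(
    true_effects = config$true_effects,
    sigma_u = config$sigma_u,
    intercept = config$intercept,
    hospital_intercepts = setNames(u, hospitals$hospital_id)
  ), class = "synthetic_truth")
  list(hospitals = hospitals, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> sigma_u=%.4f intercept=%.4f, %d hospitals\n",
              x$sigma_u, x$intercept, length(x$hospital_intercepts)))
  invisible(x)
}

#' Generate patients nested in the simulated hospitals
#'
#' Each admission draws a procedure from the configured mix, then a hospital
#' among those offering that procedure with probability proportional to the
#' hospital's mean annual volume for it (reproducing the concentration of
#' cases at high-volume centers). Covariates are drawn from the configured
#' marginals (insurance conditionally on age when coupling is enabled), and
#' the death indicator is Bernoulli with
#' `p = plogis(intercept + x beta + u_j)`.
#'
#' Covariate draws use the `"patients"` substream and outcome draws the
#' `"outcomes"` substream of the global seed, so regenerating outcomes under
#' different effects leaves the covariates untouched.
#'
#' @param hospitals hospital data frame from [generate_hospitals()]
#' @param truth `synthetic_truth` from [generate_hospitals()]
#' @param config the same [simulation_config()]
#' @return data frame with one row per admission: patient_id, hospital_id,
#'   age, sex, race, insurance, procedure, comorbidity_index, year, svi,
#'   travel_minutes, died
#' @export
generate_patients <- function(hospitals, truth, config) {
  validate_config(config)
  if (nrow(hospitals) == 0) ihm_validation_error("`hospitals` must be nonempty")
  if (!identical(names(truth$hospital_intercepts), hospitals$hospital_id)) {
    ihm_validation_error("`truth` is not consistent with `hospitals`")
  }
  n <- config$n_patients
  cv <- config$covariates

  set.seed(substream_seed(config$seed, "patients"))
  procedure <- sample(names(config$procedure_mix), n, replace = TRUE,
                      prob = config$procedure_mix)

  hosp_idx <- integer(n)
  for (pr in .procedures) {
    rows <- which(procedure == pr)
    if (!length(rows)) next
    w <- hospitals[[paste0("mean_annual_volume_", pr)]]
    if (all(w <= 0)) {
      ihm_validation_error(sprintf(
        "no hospital offers procedure %s but procedure_mix[%s] > 0", pr, pr))
    }
    hosp_idx[rows] <- sample.int(nrow(hospitals), length(rows),
                                 replace = TRUE, prob = w)
  }

  age <- .rtruncnorm(n, cv$age$mean, cv$age$sd, cv$age$lower, cv$age$upper)
  sex <- sample(names(cv$sex), n, replace = TRUE, prob = cv$sex)
  race <- sample(names(cv$race), n, replace = TRUE, prob = cv$race)
  insurance <- .draw_insurance(n, age, cv, config$insurance_coupling)
  year <- as.integer(sample(names(cv$year), n, replace = TRUE, prob = cv$year))
  comorbidity_index <- pmin(rnbinom(n, size = cv$comorbidity_index$size,
                                    mu = cv$comorbidity_index$mu),
                            cv$comorbidity_index$max)
  svi <- 100 * qbeta(runif(n), cv$svi$shape1, cv$svi$shape2)
  travel_minutes <- rlnorm(n, cv$travel_minutes$meanlog, cv$travel_minutes$sdlog)

  patients <- data.frame(
    patient_id = sprintf("P%07d", seq_len(n)),
    hospital_id = hospitals$hospital_id[hosp_idx],
    age = age, sex = sex, race = race, insurance = insurance,
    procedure = procedure, comorbidity_index = comorbidity_index,
    year = year, svi = svi, travel_minutes = travel_minutes,
    stringsAsFactors = FALSE
  )

  eta <- .true_linear_predictor(patients, hospitals, truth)
  set.seed(substream_seed(config$seed, "outcomes"))
  patients$died <- rbinom(n, 1, plogis(eta))
  patients
}

.rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd); phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

.draw_insurance <- function(n, age, cv, coupling) {
  cats <- names(cv$insurance)
  if (!isTRUE(coupling$enabled)) {
    return(sample(cats, n, replace = TRUE, prob = cv$insurance))
  }
  tn <- .truncnorm_moments(cv$age$mean, cv$age$sd, cv$age$lower, cv$age$upper)
  p_old <- (pnorm(cv$age$upper, cv$age$mean, cv$age$sd) -
              pnorm(coupling$age_cut, cv$age$mean, cv$age$sd)) / tn$Z
  probs <- .insurance_given_age(cv$insurance, p_old, coupling$p_medicare_older)
  out <- character(n)
  old <- age >= coupling$age_cut
  if (any(old)) out[old] <- sample(cats, sum(old), replace = TRUE, prob = probs$older)
  if (any(!old)) out[!old] <- sample(cats, sum(!old), replace = TRUE, prob = probs$younger)
  out
}

## linear predictor under the TRUE (data-generating) coefficients
.true_linear_predictor <- function(patients, hospitals, truth) {
  b <- truth$true_effects
  bn <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  eta <- rep(truth$intercept, nrow(patients))
  eta <- eta + bn("age") * patients$age
  add_cat <- function(eta, values, prefix) {
    for (lev in unique(values)) {
      nm <- paste0(prefix, lev)
      if (nm %in% names(b)) eta[values == lev] <- eta[values == lev] + b[[nm]]
    }
    eta
  }
  eta <- add_cat(eta, patients$sex, "sex")
  eta <- add_cat(eta, patients$race, "race")
  eta <- add_cat(eta, patients$insurance, "insurance")
  eta <- add_cat(eta, patients$procedure, "procedure")
  eta <- add_cat(eta, as.character(patients$year), "year")
  eta <- eta + bn("comorbidity_index") * patients$comorbidity_index
  eta <- eta + bn("svi") * patients$svi
  eta <- eta + bn("travel_minutes") * patients$travel_minutes / 10

  hidx <- match(patients$hospital_id, hospitals$hospital_id)
  volmat <- as.matrix(hospitals[paste0("mean_annual_volume_", .procedures)])
  vol <- volmat[cbind(hidx, match(patients$procedure, .procedures))]
  eta <- eta + bn("mean_annual_volume") * vol / 10
  for (nm in c("teaching", "medical_school", "cancer_program", "fte_per_bed")) {
    eta <- eta + bn(nm) * hospitals[[nm]][hidx]
  }
  eta + truth$hospital_intercepts[hidx]
}

#' Simulate a full cohort in one call
#'
#' Convenience wrapper: [generate_hospitals()] then [generate_patients()].
#'
#' @param config a [simulation_config()]
#' @return list with `patients`, `hospitals`, `truth`, `config`
#' @export
#' @examples
#' cohort <- simulate_cohort(scenario("null", n_hospitals = 5, n_patients = 200))
#' table(cohort$patients$procedure)
simulate_cohort <- function(config) {
  gh <- generate_hospitals(config)
  patients <- generate_patients(gh$hospitals, gh$truth, config)
  list(patients = patients, hospitals = gh$hospitals,
       truth = gh$truth, config = config)
}
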