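# Small cohorts and toy clustered datasets built in code, shared across tests.

# a reduced registry-style cohort, cheap enough for repeated fitting
small_cohort <- function(name = "calibrated", n_hospitals = 30,
                         n_patients = 1500, seed = 20260101) {
  simulate_cohort(scenario(name, n_hospitals = n_hospitals,
                           n_patients = n_patients, seed = seed))
}

# toy clustered binary data with a single covariate and known truth;
# cluster sizes large enough that sigma2_u is estimated off the boundary
toy_clustered <- function(J = 8, nj = 40, beta = c(-0.5, 0.8), sigma_u = 1.2,
                          seed = 11) {
  set.seed(seed)
  cluster <- rep(seq_len(J), each = nj)
  x <- rnorm(J * nj)
  u <- rnorm(J, 0, sigma_u)
  eta <- beta[1] + beta[2] * x + u[cluster]
  y <- rbinom(J * nj, 1, plogis(eta))
  data.frame(y = y, x = x, cluster = factor(cluster))
}

# wrap toy data in the patient/hospital schema so the full fit surface can
# be exercised on it: x plays the role of (centered) age
toy_as_cohort <- function(d) {
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(nrow(d))),
    hospital_id = sprintf("H%02d", as.integer(d$cluster)),
    age = d$x, sex = "male", race = "White", insurance = "Private",
    procedure = "PN", comorbidity_index = 0L, year = 2010L,
    svi = 50, travel_minutes = 20, died = d$y,
    stringsAsFactors = FALSE)
  J <- nlevels(d$cluster)
  hospitals <- data.frame(
    hospital_id = sprintf("H%02d", seq_len(J)),
    teaching = 0L, medical_school = 0L, cancer_program = 0L,
    fte_per_bed = 0.1, beds = 100L, operating_rooms = 8L,
    mean_annual_volume_ES = 0, mean_annual_volume_PN = 10,
    mean_annual_volume_PD = 0, mean_annual_volume_PR = 0,
    stringsAsFactors = FALSE)
  list(patients = patients, hospitals = hospitals)
}

# spec restricted to the terms that vary in the toy cohort
toy_spec <- function() {
  model_spec(blocks = list(PC = "age"))
}

# slim blocks for small-sample pipeline runs, where the full year/race/
# insurance factor set would be separation-prone within thin strata
slim_spec <- function() {
  model_spec(blocks = list(
    PC = c("age", "sex", "comorbidity_index", "procedure"),
    CV = "mean_annual_volume",
    HC = c("teaching", "cancer_program"),
    SDoH = c("svi", "travel_minutes")))
}
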