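test_that("invalid configurations are rejected with the field named", {
  cfg <- scenario("null", n_hospitals = 5, n_patients = 100)

  bad <- cfg; bad$sigma_u <- -0.1
  expect_error(validate_config(bad), "sigma_u")

  bad <- cfg; bad$procedure_mix <- c(ES = 0.5, PN = 0.5, PD = 0.5, PR = 0.5)
  expect_error(validate_config(bad), "procedure_mix")

  bad <- cfg; bad$covariates$sex <- c(male = 0.6, female = 0.5)
  expect_error(validate_config(bad), "sex")

  bad <- cfg; bad$true_effects <- c(not_a_term = 1)
  expect_error(validate_config(bad), "not_a_term")

  bad <- cfg; bad$n_hospitals <- 0L
  expect_error(validate_config(bad), "n_hospitals")

  expect_error(scenario("nope"), "valid presets")
})

test_that("hospital generation honors the zero-variance and sampling-interval cases", {
  # sigma_u = 0: intercepts exactly zero
  gh <- generate_hospitals(scenario("null", n_hospitals = 1, n_patients = 10))
  expect_identical(unname(gh$truth$hospital_intercepts), 0)
  expect_equal(nrow(gh$hospitals), 1L)

  # sigma_u = 0.5, J = 294: sample SD of the intercepts inside the 95%
  # chi-square sampling interval for a normal-sample SD
  cfg <- scenario("calibrated", n_hospitals = 294, n_patients = 10, seed = 41)
  cfg$sigma_u <- 0.5
  u <- generate_hospitals(cfg)$truth$hospital_intercepts
  expect_length(u, 294L)
  n <- 294
  lims <- 0.5 * sqrt(qchisq(c(0.025, 0.975), n - 1) / (n - 1))
  expect_gt(sd(u), lims[1])
  expect_lt(sd(u), lims[2])
})

test_that("california preset matches the registry hospital and cohort structure", {
  cfg <- scenario("california", seed = 20260101)
  expect_equal(cfg$n_hospitals, 294L)
  expect_equal(cfg$n_patients, 52838L)

  gh <- generate_hospitals(cfg)
  # expected per-procedure offering counts 158/245/166/255 of 294: observed
  # counts within 99% binomial intervals (Bonferroni across 4 procedures)
  offer <- colSums(gh$hospitals[paste0("mean_annual_volume_",
                                       c("ES", "PN", "PD", "PR"))] > 0)
  expected <- c(158, 245, 166, 255)
  a <- 0.01 / 4
  for (i in 1:4) {
    expect_gte(offer[i], qbinom(a / 2, 294, expected[i] / 294))
    expect_lte(offer[i], qbinom(1 - a / 2, 294, expected[i] / 294))
  }
})

test_that("california categorical marginals fall inside multinomial 99% intervals", {
  co <- simulate_cohort(scenario("california", seed = 20260101))
  p <- co$patients
  n <- nrow(p)
  targets <- list(
    sex = c(male = 26526, female = 26312) / 52838,
    race = c(White = 33327, Black = 2653, Hispanic = 7503,
             Asian = 7121, Other = 2234) / 52838,
    insurance = c(Medicare = 30345, Medicaid = 4526, Private = 16357,
                  `Self-pay` = 473, Other = 1137) / 52838,
    procedure = c(ES = 2700, PN = 30822, PD = 7530, PR = 11786) / 52838
  )
  for (v in names(targets)) {
    tab <- table(p[[v]])
    probs <- targets[[v]]
    a <- 0.01 / length(probs)  # joint 99% via Bonferroni across categories
    for (lev in names(probs)) {
      expect_gte(tab[[lev]], qbinom(a / 2, n, probs[[lev]]))
      expect_lte(tab[[lev]], qbinom(1 - a / 2, n, probs[[lev]]))
    }
  }
})

test_that("patient records satisfy their range invariants", {
  co <- simulate_cohort(scenario("california", n_hospitals = 40,
                                 n_patients = 4000, seed = 2))
  p <- co$patients
  expect_true(all(p$age >= 18 & p$age <= 95))
  expect_true(all(p$svi >= 0 & p$svi <= 100))
  expect_true(all(p$travel_minutes >= 0))
  expect_true(all(p$died %in% c(0, 1)))
  expect_true(all(p$comorbidity_index >= 0 & p$comorbidity_index <= 27))
  expect_true(all(p$year %in% 2010:2020))
  expect_true(all(p$hospital_id %in% co$hospitals$hospital_id))
})

test_that("generation is deterministic and substreams are independent", {
  cfg <- scenario("calibrated", n_hospitals = 20, n_patients = 800, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$hospitals, b$hospitals)

  # changing only the outcome model leaves hospital + covariate draws intact
  cfg2 <- cfg
  cfg2$true_effects["age"] <- 0.1
  c2 <- simulate_cohort(cfg2)
  expect_identical(a$hospitals, c2$hospitals)
  expect_identical(a$patients[setdiff(names(a$patients), "died")],
                   c2$patients[setdiff(names(c2$patients), "died")])

  expect_false(substream_seed(9, "patients") == substream_seed(9, "outcomes"))
})

test_that("null preset death rate calibrates to the configured baseline", {
  co <- simulate_cohort(scenario("null", n_hospitals = 100,
                                 n_patients = 100000, seed = 13))
  deaths <- sum(co$patients$died)
  # 99.9% exact binomial interval around 1.7% at n = 1e5
  expect_gte(deaths, qbinom(0.0005, 1e5, 0.017))
  expect_lte(deaths, qbinom(0.9995, 1e5, 0.017))
})

test_that("extreme intercept underflows to zero deaths", {
  cfg <- scenario("null", n_hospitals = 5, n_patients = 2000, seed = 3)
  cfg$intercept <- -30
  co <- simulate_cohort(cfg)
  expect_equal(sum(co$patients$died), 0)
})

test_that("a single-covariate effect is recovered by a plain logistic fit", {
  # oracle: glm on a large simulated sample recovers the designed age slope
  cfg <- scenario("null", n_hospitals = 50, n_patients = 200000, seed = 17)
  cfg$true_effects["age"] <- 0.03
  cfg$intercept <- qlogis(0.017) - 0.03 * 67.6 # recenter so rate stays ~1.7%
  co <- simulate_cohort(cfg)
  g <- glm(died ~ age, data = co$patients, family = binomial())
  expect_equal(unname(coef(g)["age"]), 0.03,
               tolerance = 3 * summary(g)$coefficients["age", 2] / 0.03)
})

test_that("designed explained proportion matches direct arithmetic for pc_only", {
  cfg <- scenario("pc_only", n_hospitals = 10, n_patients = 100)
  v <- designed_linear_predictor_variance(cfg)
  # direct ratio from the same documented constants
  expect_equal(designed_explained_proportion(cfg),
               v$total / (v$total + pi^2 / 3), tolerance = 1e-12)
  # only patient-level terms contribute
  expect_true(all(v$terms[c("mean_annual_volume", "teaching", "svi",
                            "travel_minutes", "insurance")] == 0))
  expect_identical(cfg$sigma_u, 0)
})
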