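test_that("zero between-hospital variance gives zero effects and weights", {
  co <- toy_as_cohort(toy_clustered(J = 6, nj = 30, sigma_u = 0, seed = 13))
  f <- fit_random_intercept_logit(co$patients, co$hospitals, toy_spec(),
                                  options = list(fix_sigma_u = 0))
  eff <- eb_hospital_effects(f)
  expect_true(all(eff$u_hat == 0))
  expect_true(all(eff$reliability_weight == 0))

  # shrink-to-center limit: every adjusted rate equals the reference rate
  prof <- shrunken_rates(f, eff)
  expect_equal(prof$adjusted_rate,
               rep(mean(plogis(f$eta_fixed)), nrow(prof)), tolerance = 1e-12)
})

test_that("normal_approx shrinkage is exact and monotone in caseload", {
  # two hospitals with identical case mix and identical raw death rates,
  # n = 20 vs n = 2000, plus background hospitals to identify the model
  set.seed(29)
  mk <- function(id, n, rate) {
    k <- round(n * rate)
    data.frame(y = rep(c(1, 0), c(k, n - k)), x = 0,
               cluster = id, stringsAsFactors = FALSE)
  }
  bg <- do.call(rbind, lapply(1:10, function(j) {
    n <- 150
    u <- rnorm(1, 0, 0.8)
    data.frame(y = rbinom(n, 1, plogis(-2 + u)), x = rnorm(n),
               cluster = sprintf("B%02d", j), stringsAsFactors = FALSE)
  }))
  d <- rbind(mk("S01", 20, 0.3), mk("S02", 2000, 0.3), bg)
  d$cluster <- factor(d$cluster)
  co <- toy_as_cohort(d)
  f <- fit_random_intercept_logit(co$patients, co$hospitals, toy_spec(),
                                  options = list(nAGQ = 7))
  eff <- eb_hospital_effects(f, method = "normal_approx")

  # shrinkage bound holds exactly for every hospital
  expect_true(all(abs(eff$u_hat) <= abs(eff$u_raw) + 1e-12))
  # reliability weight increases with caseload at fixed case mix and rate
  i20 <- match(unique(co$patients$hospital_id[d$cluster == "S01"]), eff$hospital_id)
  i2000 <- match(unique(co$patients$hospital_id[d$cluster == "S02"]), eff$hospital_id)
  expect_gt(eff$reliability_weight[i2000], eff$reliability_weight[i20])
  expect_gt(abs(eff$u_hat[i2000]), abs(eff$u_hat[i20]))
})

test_that("posterior effects approach the fixed-effect estimate for a huge hospital", {
  # one constructed hospital with n = 10^4 and strong excess mortality:
  # the EB posterior mean should be close to an explicit dummy estimate
  set.seed(37)
  bg <- do.call(rbind, lapply(1:8, function(j) {
    u <- rnorm(1, 0, 0.6)
    data.frame(y = rbinom(400, 1, plogis(-2.2 + u)), x = rnorm(400),
               cluster = sprintf("B%02d", j), stringsAsFactors = FALSE)
  }))
  big <- data.frame(y = rbinom(10000, 1, plogis(-2.2 + 1.0)),
                    x = rnorm(10000), cluster = "BIG",
                    stringsAsFactors = FALSE)
  d <- rbind(bg, big); d$cluster <- factor(d$cluster)
  co <- toy_as_cohort(d)
  f <- fit_random_intercept_logit(co$patients, co$hospitals, toy_spec(),
                                  options = list(nAGQ = 7))
  eff <- eb_hospital_effects(f, method = "posterior")
  ib <- match(unique(co$patients$hospital_id[d$cluster == "BIG"]),
              eff$hospital_id)

  # oracle: logistic fit with an explicit indicator for the big hospital,
  # centered like u (offset by the overall intercept)
  dd <- co$patients
  dd$big <- as.integer(dd$hospital_id == eff$hospital_id[ib])
  g <- glm(died ~ age + big, data = dd, family = binomial())
  u_dummy <- unname(coef(g)["big"]) +
    unname(coef(g)["(Intercept)"]) - unname(f$beta["(Intercept)"])
  expect_lt(abs(eff$u_hat[ib] - u_dummy) / abs(u_dummy), 0.05)
  expect_gt(eff$reliability_weight[ib], 0.9)
})

test_that("adjusted-rate ordering follows the EB effect ordering", {
  co <- small_cohort(n_hospitals = 20, n_patients = 2500, seed = 55)
  f <- fit_random_intercept_logit(co$patients, co$hospitals, model_spec(),
                                  options = list(nAGQ = 1))
  eff <- eb_hospital_effects(f)
  prof <- shrunken_rates(f, eff)
  expect_equal(order(prof$adjusted_rate), order(prof$u_hat))
  # center preservation: expected deaths sum to model-predicted deaths
  expect_equal(sum(prof$expected_deaths), sum(plogis(f$eta_fixed)),
               tolerance = 1e-8)
  expect_true(all(prof$observed_deaths <= prof$n_patients))
})

test_that("absent hospitals are flagged with zero effect", {
  co <- toy_as_cohort(toy_clustered(J = 5, nj = 40, seed = 41))
  f <- fit_random_intercept_logit(co$patients, co$hospitals, toy_spec(),
                                  options = list(nAGQ = 7))
  extra <- co$hospitals[1, ]
  extra$hospital_id <- "H99"
  eff <- eb_hospital_effects(f, hospitals = rbind(co$hospitals, extra))
  i <- match("H99", eff$hospital_id)
  expect_true(eff$flagged[i])
  expect_identical(eff$u_hat[i], 0)
  expect_identical(eff$reliability_weight[i], 0)
})

test_that("tertile grouping follows percentile ranks with the mean-rank tie rule", {
  mk <- function(rates) data.frame(hospital_id = seq_along(rates),
                                   stratum = "overall",
                                   adjusted_rate = rates)
  # three distinct rates -> low / medium / high
  expect_equal(tertile_groups(mk(c(0.01, 0.02, 0.03)))$tertile,
               c("low", "medium", "high"))
  # six distinct rates -> exactly two per group
  t6 <- tertile_groups(mk(c(0.06, 0.02, 0.04, 0.01, 0.05, 0.03)))$tertile
  expect_equal(as.vector(table(t6)[c("low", "medium", "high")]), c(2L, 2L, 2L))
  expect_equal(t6[order(c(0.06, 0.02, 0.04, 0.01, 0.05, 0.03))],
               rep(c("low", "medium", "high"), each = 2))
  # all identical -> mean percentile rank 50 -> all medium
  expect_equal(tertile_groups(mk(rep(0.02, 5)))$tertile, rep("medium", 5))
  # < 3 hospitals refuses with unclassified labels
  expect_warning(t2 <- tertile_groups(mk(c(0.01, 0.02))), "unclassified")
  expect_equal(t2$tertile, rep("unclassified", 2))
  # per-stratum labelling and exhaustiveness
  p <- rbind(cbind(mk(c(0.01, 0.02, 0.03, 0.04)), s = 1),
             cbind(mk(c(0.05, 0.06, 0.07)), s = 2))
  p$stratum <- p$s
  lab <- tertile_groups(p)
  expect_false(any(is.na(lab$tertile)))
  expect_equal(nrow(lab), 7L)
})

test_that("funnel limits match brute-force binomial quantiles", {
  fc <- funnel_limits(0.017, c(25, 100, 400, 1600))
  expect_true(all(fc$lower <= fc$center & fc$center <= fc$upper))

  # oracle at n=100, p=0.017: direct CDF summation
  cdf <- cumsum(dbinom(0:100, 100, 0.017))
  lo <- (which(cdf >= 0.025)[1] - 1) / 100
  hi <- (which(cdf >= 0.975)[1] - 1) / 100
  row <- fc[fc$volume == 100 & fc$alpha == 0.05, ]
  expect_equal(row$lower, lo, tolerance = 1e-12)
  expect_equal(row$upper, hi, tolerance = 1e-12)

  # limits narrow as volume grows (discreteness-tolerant: compare widths)
  w <- with(fc[fc$alpha == 0.05, ], upper - lower)
  expect_true(all(diff(w) <= 1e-12))

  # alpha = 1 collapses to the median band: both limits within 1/n of center
  f1 <- funnel_limits(0.3, c(50, 200), alphas = 1)
  expect_true(all(abs(f1$lower - 0.3) <= 1 / f1$volume))
  expect_true(all(abs(f1$upper - 0.3) <= 1 / f1$volume))

  expect_error(funnel_limits(0, 1:10), "center_rate")
  expect_error(funnel_limits(0.5, c(0, 10)), ">= 1")
})

test_that("null simulation puts ~5% of hospitals outside the 95% limits", {
  set.seed(61)
  J <- 500; nj <- 120; p0 <- 0.05
  deaths <- rbinom(J, nj, p0)
  fc <- funnel_limits(p0, nj, alphas = 0.05)
  outside <- deaths / nj < fc$lower | deaths / nj > fc$upper
  # exact binomial: actual alpha at this n (discreteness makes it < 5%)
  alpha_exact <- pbinom(fc$lower * nj - 1, nj, p0) +
    (1 - pbinom(fc$upper * nj, nj, p0))
  expect_lt(abs(mean(outside) - alpha_exact),
            3 * sqrt(alpha_exact * (1 - alpha_exact) / J) + 1e-12)
  expect_lt(mean(outside), 0.08)
})
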