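test_that("with the variance fixed at zero the 2x2 slope is the log cross-product ratio", {
  # exposed: 10 deaths / 100; unexposed: 5 deaths / 100
  d <- data.frame(
    y = c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95)),
    x = rep(c(1, 0), each = 100),
    cluster = factor(rep(1, 200)))
  co <- toy_as_cohort(data.frame(y = d$y, x = d$x, cluster = d$cluster))
  f <- fit_random_intercept_logit(co$patients, co$hospitals, toy_spec(),
                                  options = list(fix_sigma_u = 0))
  expect_equal(unname(f$beta["age"]), log((10 * 95) / (5 * 90)),
               tolerance = 1e-8)
  expect_identical(f$sigma2_u, 0)
})

test_that("fixing sigma2_u at zero reduces to ordinary logistic regression", {
  co <- toy_as_cohort(toy_clustered(J = 6, nj = 30, seed = 5))
  f0 <- fit_random_intercept_logit(co$patients, co$hospitals, toy_spec(),
                                   options = list(fix_sigma_u = 0))
  g <- glm(died ~ age, data = co$patients, family = binomial())
  expect_equal(unname(f0$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f0$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("the oracle degenerates to the Bernoulli log-likelihood at sigma2_u = 0", {
  d <- toy_clustered(J = 4, nj = 20, seed = 2)
  eta <- -0.5 + 0.8 * d$x
  expect_equal(marginal_loglik_oracle(d$y, eta, d$cluster, 0),
               sum(dbinom(d$y, 1, plogis(eta), log = TRUE)), tolerance = 1e-12)
  expect_error(marginal_loglik_oracle(d$y, eta, d$cluster, -1), "sigma2_u")
  expect_error(marginal_loglik_oracle(d$y, eta, d$cluster, 1,
                                      grid = list(half_width = 4)), "8 SDs")
})

test_that("the oracle is grid-converged and agrees with independent integration", {
  d <- toy_clustered(J = 5, nj = 25, seed = 7)
  eta <- -0.4 + 0.6 * d$x
  a1 <- marginal_loglik_oracle(d$y, eta, d$cluster, 0.8,
                               grid = list(half_width = 10, step = 0.01))
  a2 <- marginal_loglik_oracle(d$y, eta, d$cluster, 0.8,
                               grid = list(half_width = 10, step = 0.005))
  expect_lt(abs(a1 - a2), 1e-8)

  # independent scheme: per-cluster adaptive quadrature via integrate()
  ll_int <- sum(vapply(levels(d$cluster), function(cl) {
    idx <- d$cluster == cl
    f <- Vectorize(function(u) {
      exp(sum(dbinom(d$y[idx], 1, plogis(eta[idx] + u), log = TRUE))) *
        dnorm(u, 0, sqrt(0.8))
    })
    log(integrate(f, -10, 10, rel.tol = 1e-12)$value)
  }, numeric(1)))
  expect_lt(abs(a2 - ll_int), 1e-8)
})

test_that("the fitted AGQ log-likelihood matches the integration oracle", {
  co <- toy_as_cohort(toy_clustered(J = 8, nj = 40, sigma_u = 1.2, seed = 11))
  f <- fit_random_intercept_logit(co$patients, co$hospitals, toy_spec())
  expect_true(f$converged)
  expect_gt(f$sigma2_u, 0) # non-degenerate check
  expect_lt(abs(f$loglik - oracle_loglik(f)), 1e-6)
})

test_that("estimates are stable across quadrature orders", {
  co <- toy_as_cohort(toy_clustered(J = 10, nj = 50, sigma_u = 1.0, seed = 23))
  f7 <- fit_random_intercept_logit(co$patients, co$hospitals, toy_spec(),
                                   options = list(nAGQ = 7))
  f15 <- fit_random_intercept_logit(co$patients, co$hospitals, toy_spec(),
                                    options = list(nAGQ = 15))
  expect_lt(max(abs(f7$beta - f15$beta)), 1e-4)
  expect_lt(abs(f7$sigma2_u - f15$sigma2_u), 1e-4)
})

test_that("parameter recovery on a generated two-parameter cohort", {
  # beta = (-4, 0.5) on centered age, sigma_u = 0.5, 100 hospitals x 100
  d_n <- 100 * 100
  set.seed(31)
  cluster <- rep(1:100, each = 100)
  x <- rnorm(d_n)
  u <- rnorm(100, 0, 0.5)
  y <- rbinom(d_n, 1, plogis(-4 + 0.5 * x + u[cluster]))
  co <- toy_as_cohort(data.frame(y = y, x = x, cluster = factor(cluster)))
  f <- fit_random_intercept_logit(co$patients, co$hospitals, toy_spec(),
                                  options = list(nAGQ = 7))
  expect_true(f$converged)
  expect_lt(abs(f$beta[["(Intercept)"]] - (-4)), 3 * f$se[["(Intercept)"]])
  expect_lt(abs(f$beta[["age"]] - 0.5), 3 * f$se[["age"]])
  expect_lt(abs(sqrt(f$sigma2_u) - 0.5), 0.25)
})

test_that("validation and estimation errors are classed and informative", {
  co <- toy_as_cohort(toy_clustered(J = 4, nj = 10, seed = 3))
  p <- co$patients

  p_bad <- p; p_bad$died[1] <- 2
  expect_error(fit_random_intercept_logit(p_bad, co$hospitals, toy_spec()),
               "binary", class = "ihmvar_validation_error")

  # collinear columns named
  sp <- model_spec(blocks = list(PC = c("age", "svi")))
  p2 <- p; p2$svi <- 2 * p2$age
  expect_error(fit_random_intercept_logit(p2, co$hospitals, sp),
               "collinear", class = "ihmvar_estimation_error")

  # single cluster requires fixed sigma
  p1 <- p[p$hospital_id == "H01", ]
  expect_error(fit_random_intercept_logit(p1, co$hospitals, toy_spec()),
               "clusters", class = "ihmvar_validation_error")

  # unknown hospital id
  p3 <- p; p3$hospital_id[1] <- "H99"
  expect_error(fit_random_intercept_logit(p3, co$hospitals, toy_spec()),
               "H99", class = "ihmvar_validation_error")
})

test_that("odds-ratio table applies Wald arithmetic and design scalings", {
  co <- small_cohort(n_hospitals = 25, n_patients = 1200, seed = 77)
  f <- fit_random_intercept_logit(co$patients, co$hospitals, model_spec(),
                                  options = list(nAGQ = 1))
  tab <- odds_ratio_table(f)
  expect_setequal(
    setdiff(tab$term, "(Intercept)")[1:2],
    setdiff(names(f$beta), "(Intercept)")[1:2])
  i <- match("age", tab$term)
  expect_equal(tab$OR[i], exp(f$beta[["age"]]), tolerance = 1e-12)
  expect_equal(tab$CI_low[i], exp(f$beta[["age"]] - qnorm(0.975) * f$se[["age"]]),
               tolerance = 1e-12)
  # frozen arithmetic: beta 0.0296, se 0.0050 prints as 1.03 (1.02-1.04)
  expect_equal(round(exp(0.0296), 2), 1.03)
  expect_equal(round(exp(0.0296 - 1.96 * 0.005), 2), 1.02)
  expect_equal(round(exp(0.0296 + 1.96 * 0.005), 2), 1.04)
  # volume and travel enter per 10 units
  expect_match(tab$scale[match("mean_annual_volume", tab$term)], "per 10")
  expect_match(tab$scale[match("travel_minutes", tab$term)], "per 10")

  f$converged <- FALSE
  expect_error(odds_ratio_table(f), "converge",
               class = "ihmvar_estimation_error")
})

test_that("latent-threshold ICC follows the variance ratio", {
  expect_identical(icc(0), 0)
  expect_equal(icc(pi^2 / 3), 0.5, tolerance = 1e-12)
  expect_equal(icc(1), 1 / (1 + pi^2 / 3), tolerance = 1e-5)
  expect_equal(icc(1), 0.23310, tolerance = 1e-4)
  expect_error(icc(-1), "sigma2_u")
})
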