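## Empirical-Bayes reliability adjustment of hospital mortality, tertile
## mortality groups, and binomial funnel-plot control limits.

## Newton iteration for the posterior mode of one cluster's random intercept
## (or, with prior_prec = 0, the cluster's raw maximum-likelihood offset).
.cluster_mode <- function(y, eta, prior_prec, start = 0, cap = 8) {
  u <- start
  for (it in 1:50) {
    p <- plogis(eta + u)
    g <- sum(y - p) - prior_prec * u
    h <- -sum(p * (1 - p)) - prior_prec
    step <- g / h
    u <- u - step
    if (u > cap) { u <- cap; break }
    if (u < -cap) { u <- -cap; break }
    if (abs(step) < 1e-12) break
  }
  u
}

#' Empirical-Bayes hospital effects and reliability weights
#'
#' Estimates each hospital's deviation `u_j` on the log-odds scale under a
#' fitted random-intercept model, together with a reliability weight in
#' `[0, 1]` measuring how much of the raw signal survives shrinkage.
#'
#' Methods:
#' * `"posterior"` (default): `u_hat` is the posterior mean of `u_j` given
#'   the hospital's own outcomes, computed by numerical integration on a grid
#'   centered at the posterior mode; `reliability_weight = 1 -
#'   posterior_variance / sigma2_u` (floored at 0).
#' * `"normal_approx"`: classic shrinkage-estimator form
#'   `u_hat = w_j * u_raw_j` with `w_j = sigma2_u / (sigma2_u + v_j)`, where
#'   `u_raw_j` is the hospital's maximum-likelihood log-odds offset given the
#'   fixed effects and `v_j = 1 / I_j(u_raw_j)` its large-sample variance.
#'   Raw offsets of degenerate hospitals (all deaths or none) are capped at
#'   +/-8 before weighting. Satisfies `|u_hat| <= |u_raw|` exactly.
#'
#' With `sigma2_u = 0` every effect is 0 with weight 0. Hospitals listed in
#' `hospitals` but absent from the estimation sample are reported with
#' `u_hat = 0`, weight 0, and `flagged = TRUE`.
#'
#' @param fit a converged `glmm_fit`
#' @param method `"posterior"` or `"normal_approx"`
#' @param hospitals optional hospital table; absent facilities are appended
#'   flagged
#' @return data frame: hospital_id, n_patients, observed_deaths, u_raw,
#'   u_hat, reliability_weight, posterior_var (posterior method), flagged
#' @export
eb_hospital_effects <- function(fit, method = c("posterior", "normal_approx"),
                                hospitals = NULL) {
  method <- match.arg(method)
  if (!inherits(fit, "glmm_fit")) ihm_validation_error("`fit` must be a glmm_fit")
  if (!isTRUE(fit$converged)) ihm_estimation_error("fit did not converge")
  s2 <- fit$sigma2_u
  ids <- levels(fit$cluster)

  out <- data.frame(hospital_id = ids,
                    n_patients = as.integer(table(fit$cluster)[ids]),
                    observed_deaths = as.integer(tapply(fit$y, fit$cluster, sum)[ids]),
                    u_raw = 0, u_hat = 0, reliability_weight = 0,
                    posterior_var = if (s2 > 0) NA_real_ else 0,
                    flagged = FALSE, stringsAsFactors = FALSE)

  if (s2 > 0) {
    for (i in seq_along(ids)) {
      idx <- fit$cluster == ids[i]
      y <- fit$y[idx]; eta <- fit$eta_fixed[idx]
      raw <- .cluster_mode(y, eta, prior_prec = 0)
      out$u_raw[i] <- raw
      if (method == "posterior") {
        mode <- .cluster_mode(y, eta, prior_prec = 1 / s2)
        p <- plogis(eta + mode)
        post_sd <- sqrt(1 / (sum(p * (1 - p)) + 1 / s2))
        u <- seq(mode - 8 * post_sd, mode + 8 * post_sd, length.out = 401)
        lf <- vapply(u, function(uu) {
          sum(dbinom(y, 1, plogis(eta + uu), log = TRUE)) +
            dnorm(uu, 0, sqrt(s2), log = TRUE)
        }, numeric(1))
        w <- exp(lf - max(lf))
        w <- w / sum(w)
        m1 <- sum(w * u)
        v1 <- sum(w * (u - m1)^2)
        out$u_hat[i] <- m1
        out$posterior_var[i] <- v1
        out$reliability_weight[i] <- max(0, 1 - v1 / s2)
      } else {
        p <- plogis(eta + raw)
        info <- sum(p * (1 - p))
        v <- if (info > 0) 1 / info else Inf
        w <- s2 / (s2 + v)
        out$u_hat[i] <- w * raw
        out$reliability_weight[i] <- w
      }
    }
  }

  if (!is.null(hospitals)) {
    absent <- setdiff(hospitals$hospital_id, ids)
    if (length(absent)) {
      out <- rbind(out, data.frame(
        hospital_id = absent, n_patients = 0L, observed_deaths = 0L,
        u_raw = 0, u_hat = 0, reliability_weight = 0,
        posterior_var = if (s2 > 0) NA_real_ else 0,
        flagged = TRUE, stringsAsFactors = FALSE))
    }
  }
  attr(out, "sigma2_u") <- s2
  attr(out, "method") <- method
  out
}

#' Risk- and reliability-adjusted hospital mortality profiles
#'
#' For each hospital: `adjusted_rate = mean over the reference patient mix of
#' plogis(x beta_hat + u_hat_j)` (indirect standardization to a common case
#' mix; the default reference mix is the full estimation sample), and
#' `expected_deaths = sum over the hospital's own patients of
#' plogis(x beta_hat)` (the model-based expectation at `u = 0`).
#'
#' @param fit a converged `glmm_fit`
#' @param effects output of [eb_hospital_effects()] from the same fit
#' @param reference_mix optional numeric vector of fixed-effect linear
#'   predictors defining the reference case mix (default: the fit's own
#'   estimation sample)
#' @param stratum label recorded in the output (default `"overall"`)
#' @return data frame of class `hospital_profile`: hospital_id, stratum,
#'   n_patients, observed_deaths, expected_deaths, u_hat,
#'   reliability_weight, adjusted_rate, tertile (NA until
#'   [tertile_groups()])
#' @export
shrunken_rates <- function(fit, effects, reference_mix = NULL,
                           stratum = "overall") {
  if (!inherits(fit, "glmm_fit")) ihm_validation_error("`fit` must be a glmm_fit")
  eta_ref <- reference_mix %||% fit$eta_fixed
  if (!length(eta_ref)) ihm_validation_error("`reference_mix` must be nonempty")

  expected <- tapply(plogis(fit$eta_fixed), fit$cluster, sum)
  prof <- data.frame(
    hospital_id = effects$hospital_id,
    stratum = stratum,
    n_patients = effects$n_patients,
    observed_deaths = effects$observed_deaths,
    expected_deaths = as.numeric(expected[effects$hospital_id]),
    u_hat = effects$u_hat,
    reliability_weight = effects$reliability_weight,
    adjusted_rate = vapply(effects$u_hat,
                           function(u) mean(plogis(eta_ref + u)), numeric(1)),
    tertile = NA_character_,
    stringsAsFactors = FALSE
  )
  prof$expected_deaths[is.na(prof$expected_deaths)] <- 0
  class(prof) <- c("hospital_profile", class(prof))
  prof
}

#' Assign tertile mortality groups
#'
#' Hospitals are percentile-ranked on their adjusted mortality rate within
#' each stratum and labelled low (< 33.3rd percentile), medium (33.3rd to
#' 66.7th), or high (> 66.7th). Percentile rank uses the Hazen definition
#' `100 * (rank - 0.5) / n` with mean ranks across ties, so tied hospitals
#' always share one group (all-identical rates rank at the 50th percentile:
#' all medium). Strata with fewer than 3 hospitals are labelled
#' `"unclassified"`.
#'
#' @param profiles a `hospital_profile` data frame ([shrunken_rates()])
#' @return the profiles with the `tertile` column filled in
#' @export
#' @examples
#' p <- data.frame(hospital_id = c("a", "b", "c"), stratum = "overall",
#'                 adjusted_rate = c(0.01, 0.02, 0.03))
#' tertile_groups(p)$tertile
tertile_groups <- function(profiles) {
  if (!"adjusted_rate" %in% names(profiles)) {
    ihm_validation_error("`profiles` must carry an adjusted_rate column")
  }
  if (!"stratum" %in% names(profiles)) profiles$stratum <- "overall"
  profiles$tertile <- NA_character_
  for (s in unique(profiles$stratum)) {
    idx <- which(profiles$stratum == s)
    if (length(idx) < 3L) {
      warning(sprintf("stratum '%s' has < 3 hospitals; labelled unclassified", s),
              call. = FALSE)
      profiles$tertile[idx] <- "unclassified"
      next
    }
    r <- rank(profiles$adjusted_rate[idx], ties.method = "average")
    pctl <- 100 * (r - 0.5) / length(idx)
    profiles$tertile[idx] <- ifelse(pctl < 100 / 3, "low",
                             ifelse(pctl <= 200 / 3, "medium", "high"))
  }
  profiles
}

#' Binomial funnel-plot control limits
#'
#' Exact binomial control limits for a funnel plot of hospital mortality
#' against caseload: at volume `n`, the limits are the `alpha/2` and
#' `1 - alpha/2` binomial quantiles of `deaths / n` at the center rate.
#'
#' @param center_rate overall adjusted mortality rate, strictly in (0, 1)
#' @param volume_grid vector of caseloads (>= 1)
#' @param alphas significance levels (default 0.05 and 0.002, i.e. ~95% and
#'   ~99.8% limits)
#' @return data frame of class `funnel_curve`: volume, center, alpha,
#'   lower, upper
#' @export
#' @examples
#' funnel_limits(0.017, c(25, 100, 400))
funnel_limits <- function(center_rate, volume_grid, alphas = c(0.05, 0.002)) {
  if (!is.numeric(center_rate) || center_rate <= 0 || center_rate >= 1) {
    ihm_validation_error("`center_rate` must lie strictly in (0, 1)")
  }
  if (any(volume_grid < 1)) ihm_validation_error("volumes must be >= 1")
  out <- do.call(rbind, lapply(alphas, function(a) {
    data.frame(volume = volume_grid, center = center_rate, alpha = a,
               lower = qbinom(a / 2, volume_grid, center_rate) / volume_grid,
               upper = qbinom(1 - a / 2, volume_grid, center_rate) / volume_grid)
  }))
  class(out) <- c("funnel_curve", class(out))
  out
}
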