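## Random-intercept logistic regression (marginal maximum likelihood by
## adaptive Gauss-Hermite quadrature, via lme4), the brute-force integration
## oracle used to verify reported log-likelihoods, odds-ratio presentation,
## and the latent-threshold intraclass correlation.

#' Fit a random-intercept logistic regression
#'
#' Maximizes the marginal likelihood of a logistic model with a normal
#' hospital random intercept,
#' `P(y_ij = 1 | u_j) = plogis(x_ij beta + u_j)`, `u_j ~ N(0, sigma2_u)`,
#' integrating each cluster's likelihood by adaptive Gauss-Hermite quadrature
#' (`lme4::glmer`, `nAGQ` points; default 15). With
#' `options$fix_sigma_u = 0` the model reduces to ordinary logistic
#' regression fitted by [glm()].
#'
#' Iteration limits or optimizer failures set `converged = FALSE` on the
#' returned fit rather than raising an error; a collinear (singular) design
#' raises an estimation error naming the aliased columns.
#'
#' @param patients patient-level data frame (one row per admission)
#' @param hospitals hospital-level data frame
#' @param spec a [model_spec()]
#' @param blocks which covariate blocks to include (in nesting order);
#'   default all
#' @param options list: `nAGQ` (0-25, default 15; 1 = Laplace; 0 = lme4's
#'   fast profiled penalized-likelihood approximation, appropriate for very
#'   large fits - it coincides with maximum likelihood as the
#'   random-intercept variance approaches zero), `fix_sigma_u` (set to 0 for
#'   ordinary logistic regression), `maxit` outer iteration cap (default
#'   200), `optimizer` (default `"nloptwrap"`)
#' @return object of class `glmm_fit`: `beta` (named log-odds estimates),
#'   `se`, `vcov`, `sigma2_u`, `loglik`, `converged`, `boundary`, `n_obs`,
#'   `n_clusters`, `design_info`, plus the estimation-sample design
#'   (`X`, `y`, `cluster`, `eta_fixed`) used by downstream stages
#' @export
#' @examples
#' cohort <- simulate_cohort(scenario("null", n_hospitals = 8, n_patients = 400))
#' f <- fit_random_intercept_logit(cohort$patients, cohort$hospitals,
#'                                 model_spec(), blocks = "PC",
#'                                 options = list(nAGQ = 1))
#' f$sigma2_u
fit_random_intercept_logit <- function(patients, hospitals, spec = model_spec(),
                                       blocks = names(spec$blocks),
                                       options = list()) {
  nAGQ <- options$nAGQ %||% 15L
  if (nAGQ < 0L || nAGQ > 25L) {
    ihm_validation_error("`options$nAGQ` must be between 0 and 25")
  }
  maxit <- options$maxit %||% 200L
  optimizer <- options$optimizer %||% "nloptwrap"
  fix0 <- !is.null(options$fix_sigma_u) && options$fix_sigma_u == 0

  mf <- build_model_frame(patients, hospitals, spec, blocks = blocks)
  d <- mf$data
  if (nrow(d) == 0) ihm_validation_error("no complete-case rows to fit")
  rhs <- if (length(mf$terms)) paste(mf$terms, collapse = " + ") else "1"
  fixed_fml <- as.formula(paste(spec$outcome, "~", rhs))

  X <- model.matrix(fixed_fml, data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    ihm_estimation_error(paste0("singular design; collinear column(s): ",
                                paste(aliased, collapse = ", ")))
  }
  y <- d[[spec$outcome]]
  cluster <- d[[spec$cluster]]
  if (!fix0 && nlevels(cluster) < 2L) {
    ihm_validation_error("need >= 2 clusters unless sigma2_u is fixed at 0")
  }

  if (fix0) {
    g <- glm(fixed_fml, data = d, family = binomial())
    beta <- coef(g)
    V <- vcov(g)
    fit <- list(beta = beta, se = sqrt(diag(V)), vcov = V,
                sigma2_u = 0, loglik = as.numeric(logLik(g)),
                converged = g$converged, boundary = FALSE,
                n_obs = nrow(d), n_clusters = nlevels(cluster),
                n_iter = g$iter)
  } else {
    fml <- as.formula(paste(spec$outcome, "~", rhs, "+ (1 |", spec$cluster, ")"))
    ctrl <- lme4::glmerControl(
      optimizer = optimizer, calc.derivs = FALSE,
      optCtrl = list(maxeval = 100000),
      check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
    )
    g <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(fml, data = d, family = binomial(), nAGQ = nAGQ,
                    control = ctrl)
      )),
      error = function(e) e
    )
    if (inherits(g, "error")) {
      fit <- list(beta = setNames(rep(NA_real_, ncol(X)), colnames(X)),
                  se = NULL, vcov = NULL, sigma2_u = NA_real_,
                  loglik = NA_real_, converged = FALSE, boundary = FALSE,
                  n_obs = nrow(d), n_clusters = nlevels(cluster),
                  n_iter = NA_integer_, error = conditionMessage(g))
    } else {
      beta <- lme4::fixef(g)
      V <- as.matrix(vcov(g))
      s2 <- as.numeric(lme4::VarCorr(g)[[spec$cluster]])
      conv_ok <- is.null(g@optinfo$conv$opt) || g@optinfo$conv$opt == 0
      msgs <- unlist(g@optinfo$conv$lme4$messages)
      if (length(msgs)) {
        bad <- grepl("failed to converge|Hessian", msgs, ignore.case = TRUE)
        conv_ok <- conv_ok && !any(bad)
      }
      fit <- list(beta = beta, se = sqrt(pmax(diag(V), 0)), vcov = V,
                  sigma2_u = max(s2, 0),
                  loglik = as.numeric(logLik(g)),
                  converged = isTRUE(conv_ok),
                  boundary = s2 < 1e-8,
                  n_obs = nrow(d), n_clusters = nlevels(cluster),
                  n_iter = g@optinfo$feval %||% NA_integer_)
    }
  }

  fit$design_info <- mf$design_info
  fit$design_info$nAGQ <- if (fix0) 0L else nAGQ
  fit$design_info$terms <- mf$terms
  fit$design_info$n_dropped <- mf$n_dropped
  fit$design_info$dropped_terms <- mf$dropped_terms
  fit$X <- X
  fit$y <- y
  fit$cluster <- cluster
  fit$eta_fixed <- if (all(is.finite(fit$beta))) drop(X %*% fit$beta) else NULL
  class(fit) <- "glmm_fit"
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> n=%d, clusters=%d, converged=%s\n",
              x$n_obs, x$n_clusters, x$converged))
  cat(sprintf("  sigma2_u=%.5f  loglik=%.4f  ICC=%.4f\n",
              x$sigma2_u, x$loglik, icc(x)))
  invisible(x)
}

#' Brute-force marginal log-likelihood by trapezoid integration
#'
#' Independent verification oracle for [fit_random_intercept_logit()]: for
#' each cluster, the integral over the random intercept
#' `int prod_i Bernoulli(y_i; plogis(eta_i + u)) phi(u; 0, sigma2_u) du`
#' is computed by a composite trapezoid rule on a fine equispaced grid (in a
#' numerically stable log-sum-exp form); the total is the sum of per-cluster
#' log integrals. With `sigma2_u = 0` the integral degenerates to the
#' ordinary Bernoulli log-likelihood.
#'
#' @param y binary outcomes
#' @param eta_fixed fixed-effect linear predictor `x beta` per observation
#' @param cluster cluster identifier per observation
#' @param sigma2_u random-intercept variance (>= 0)
#' @param grid list: `half_width` (in SDs of the random effect; must be
#'   >= 8, default 10) and `step` (in SDs, default 0.005)
#' @return total marginal log-likelihood
#' @export
marginal_loglik_oracle <- function(y, eta_fixed, cluster, sigma2_u,
                                   grid = list(half_width = 10, step = 0.005)) {
  if (!is.numeric(sigma2_u) || is.na(sigma2_u) || sigma2_u < 0) {
    ihm_validation_error("`sigma2_u` must be >= 0")
  }
  if (sigma2_u == 0) {
    return(sum(dbinom(y, 1, plogis(eta_fixed), log = TRUE)))
  }
  hw <- grid$half_width %||% 10
  if (hw < 8) ihm_validation_error("`grid$half_width` must cover >= 8 SDs")
  step <- grid$step %||% 0.005
  s <- sqrt(sigma2_u)
  u <- seq(-hw * s, hw * s, by = step * s)
  K <- length(u)
  w <- rep(1, K); w[c(1, K)] <- 0.5
  du <- step * s

  total <- 0
  for (cl in levels(factor(cluster))) {
    idx <- cluster == cl
    yc <- y[idx]; ec <- eta_fixed[idx]
    ## log f(u_k) = sum_i log Bern(y_i; invlogit(eta_i + u_k)) + log phi(u_k)
    em <- outer(ec, u, "+")
    lp <- plogis(em, log.p = TRUE)
    lq <- plogis(-em, log.p = TRUE)
    lf <- colSums(yc * lp + (1 - yc) * lq) + dnorm(u, 0, s, log = TRUE)
    m <- max(lf)
    total <- total + m + log(sum(w * exp(lf - m)) * du)
  }
  total
}

#' Verify a fit's log-likelihood against the integration oracle
#'
#' Convenience wrapper evaluating [marginal_loglik_oracle()] at a fit's own
#' estimates on its own estimation sample.
#'
#' @param fit a converged `glmm_fit`
#' @param grid forwarded to [marginal_loglik_oracle()]
#' @return oracle log-likelihood
#' @export
oracle_loglik <- function(fit, grid = list(half_width = 10, step = 0.005)) {
  if (!inherits(fit, "glmm_fit")) ihm_validation_error("`fit` must be a glmm_fit")
  marginal_loglik_oracle(fit$y, fit$eta_fixed, fit$cluster, fit$sigma2_u, grid)
}

#' Odds-ratio table with Wald confidence intervals
#'
#' `OR = exp(beta)`, `CI = exp(beta -/+ z * se)`, two-sided Wald p-values.
#' Coefficients are reported on the scale they entered the design:
#' `mean_annual_volume` per 10 procedures, `travel_minutes` per 10 minutes,
#' age per year, svi and comorbidity_index per unit (see the `scale` column).
#'
#' @param fit a converged `glmm_fit`
#' @param level confidence level (default 0.95)
#' @return data frame: term, estimate (log-odds), se, OR, CI_low, CI_high, p
#' @export
odds_ratio_table <- function(fit, level = 0.95) {
  if (!inherits(fit, "glmm_fit")) ihm_validation_error("`fit` must be a glmm_fit")
  if (!isTRUE(fit$converged)) {
    ihm_estimation_error("fit did not converge; odds ratios not reported")
  }
  z <- qnorm(1 - (1 - level) / 2)
  b <- fit$beta; se <- fit$se
  scaling <- fit$design_info$scaling
  scale_of <- function(term) {
    hit <- names(scaling)[vapply(names(scaling), function(nm) startsWith(term, nm), logical(1))]
    if (length(hit)) paste0("per ", scaling[[hit[1]]], " units") else "per unit / vs reference"
  }
  data.frame(
    term = names(b),
    estimate = unname(b),
    se = unname(se),
    OR = exp(unname(b)),
    CI_low = exp(unname(b) - z * unname(se)),
    CI_high = exp(unname(b) + z * unname(se)),
    p = 2 * pnorm(-abs(unname(b) / unname(se))),
    scale = vapply(names(b), scale_of, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Latent-threshold intraclass correlation
#'
#' Share of latent outcome variance attributable to hospitals:
#' `sigma2_u / (sigma2_u + pi^2/3)`, with the standard-logistic residual
#' variance `pi^2/3` as the patient-level component.
#'
#' @param fit a `glmm_fit`, or a single non-negative variance
#' @return proportion in `[0, 1]`
#' @export
#' @examples
#' icc(0)            # 0
#' icc(pi^2 / 3)     # 0.5
icc <- function(fit) {
  s2 <- if (inherits(fit, "glmm_fit")) fit$sigma2_u else fit
  if (!is.numeric(s2) || is.na(s2) || s2 < 0) {
    ihm_validation_error("`sigma2_u` must be >= 0")
  }
  s2 / (s2 + logit_residual_variance())
}
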