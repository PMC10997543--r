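## Variance partition across the four nested random-intercept models:
## latent-scale explained share per model, block increments, and the
## unexplained remainder.

#' Variance of the fitted linear predictor (latent scale)
#'
#' Population variance (divisor `n`) of `x beta_hat` across the estimation
#' sample: the fixed-effect component `sigma2_F` of the latent-scale variance
#' decomposition.
#'
#' @param fit a converged `glmm_fit`
#' @return non-negative variance
#' @export
linear_predictor_variance <- function(fit) {
  if (!inherits(fit, "glmm_fit")) ihm_validation_error("`fit` must be a glmm_fit")
  if (is.null(fit$eta_fixed) || !length(fit$eta_fixed)) {
    ihm_validation_error("fit carries no estimation sample")
  }
  eta <- fit$eta_fixed
  mean((eta - mean(eta))^2)
}

#' Latent-scale explained proportion of one model
#'
#' Marginal latent-scale R-squared:
#' `sigma2_F / (sigma2_F + sigma2_u + pi^2/3)`, where `sigma2_F` is the
#' variance of the fitted fixed-effect predictor
#' ([linear_predictor_variance()]) and `sigma2_u` the fitted random-intercept
#' variance. The hospital random-intercept variance counts as *unexplained*
#' (together with the logistic residual) unless `credit_random_effect = TRUE`,
#' which moves `sigma2_u` into the numerator.
#'
#' @param fit a converged `glmm_fit`
#' @param credit_random_effect credit `sigma2_u` as explained? (default FALSE)
#' @return proportion in `[0, 1]`
#' @export
explained_proportion <- function(fit, credit_random_effect = FALSE) {
  vF <- linear_predictor_variance(fit)
  denom <- vF + fit$sigma2_u + logit_residual_variance()
  if (credit_random_effect) (vF + fit$sigma2_u) / denom else vF / denom
}

#' Sequential variance decomposition across the four nested models
#'
#' Fits the nested models that add the covariate blocks in order (by default
#' PC, then +CV, then +HC, then +SDoH), each with a hospital random
#' intercept, on one shared complete-case sample; computes the explained
#' proportion of each model; and reports block contributions as successive
#' differences, with `unexplained = 1 - cumulative[last]`.
#'
#' Each model's denominator uses its own refitted `sigma2_u`, so increments
#' can in principle be negative; they are reported as computed (with a
#' warning), never clipped.
#'
#' @param patients,hospitals cohort tables
#' @param spec a [model_spec()]
#' @param block_order order in which blocks are added
#' @param strata optional column name (e.g. `"procedure"`) to also run the
#'   decomposition within each stratum, dropping the stratum variable from
#'   the blocks
#' @param options fitting options forwarded to
#'   [fit_random_intercept_logit()]
#' @param credit_random_effect forwarded to [explained_proportion()]
#' @return object of class `variance_decomposition`: `cumulative` (per
#'   model), `contributions` (per block), `unexplained`,
#'   `components_per_model` (data frame of `sigma2_F`, `sigma2_u`, residual),
#'   `stratum`, and - when `strata` is given - `strata`, a named list of
#'   per-stratum decompositions
#' @export
sequential_decomposition <- function(patients, hospitals, spec = model_spec(),
                                     block_order = names(spec$blocks),
                                     strata = NULL,
                                     options = list(),
                                     credit_random_effect = FALSE) {
  if (!all(block_order %in% names(spec$blocks))) {
    ihm_validation_error("`block_order` must name blocks of the spec")
  }
  dec <- .decompose_one(patients, hospitals, spec, block_order, options,
                        credit_random_effect, stratum = "overall")
  if (!is.null(strata)) {
    lv <- sort(unique(patients[[strata]]))
    dec$strata <- lapply(setNames(lv, lv), function(s) {
      sub <- patients[patients[[strata]] == s, , drop = FALSE]
      spec_s <- spec
      spec_s$blocks <- lapply(spec$blocks, function(v) setdiff(v, strata))
      .decompose_one(sub, hospitals, spec_s, block_order, options,
                     credit_random_effect, stratum = s)
    })
  }
  dec
}

.decompose_one <- function(patients, hospitals, spec, block_order, options,
                           credit_random_effect, stratum) {
  k <- length(block_order)
  fits <- vector("list", k)
  cumulative <- numeric(k)
  comp <- data.frame(model = seq_len(k), sigma2_F = NA_real_,
                     sigma2_u = NA_real_,
                     residual = logit_residual_variance())
  for (i in seq_len(k)) {
    fits[[i]] <- fit_random_intercept_logit(patients, hospitals, spec,
                                            blocks = block_order[seq_len(i)],
                                            options = options)
    if (!isTRUE(fits[[i]]$converged)) {
      ihm_estimation_error(sprintf(
        "model %d (blocks %s) did not converge; decomposition aborted",
        i, paste(block_order[seq_len(i)], collapse = "+")))
    }
    comp$sigma2_F[i] <- linear_predictor_variance(fits[[i]])
    comp$sigma2_u[i] <- fits[[i]]$sigma2_u
    cumulative[i] <- explained_proportion(fits[[i]], credit_random_effect)
  }
  contributions <- diff(c(0, cumulative))
  names(contributions) <- block_order
  names(cumulative) <- paste0("model", seq_len(k))
  if (any(contributions < 0)) {
    warning(sprintf("negative block increment(s): %s (reported as computed)",
                    paste(names(contributions)[contributions < 0],
                          collapse = ", ")), call. = FALSE)
  }
  structure(list(cumulative = cumulative, contributions = contributions,
                 unexplained = 1 - cumulative[[k]],
                 components_per_model = comp,
                 stratum = stratum, fits = fits),
            class = "variance_decomposition")
}

#' Difference a cumulative explained-variance sequence
#'
#' Pure arithmetic on an already-computed cumulative explained-proportion
#' row: block contributions are successive differences and the unexplained
#' share is one minus the final cumulative value. Useful for re-expressing a
#' printed cumulative row as per-block shares.
#'
#' @param cumulative numeric vector of cumulative explained proportions
#'   (one per nested model, in nesting order)
#' @param blocks optional block names (default PC, CV, HC, SDoH)
#' @return list with `contributions` and `unexplained`
#' @export
#' @examples
#' decompose_cumulative(c(0.320, 0.343, 0.356, 0.368))
decompose_cumulative <- function(cumulative,
                                 blocks = c("PC", "CV", "HC", "SDoH")[seq_along(cumulative)]) {
  if (any(cumulative < 0 | cumulative > 1)) {
    ihm_validation_error("`cumulative` values must lie in [0, 1]")
  }
  contributions <- setNames(diff(c(0, cumulative)), blocks)
  list(contributions = contributions,
       unexplained = 1 - cumulative[[length(cumulative)]])
}

#' @export
print.variance_decomposition <- function(x, digits = 3, ...) {
  cat(sprintf("<variance_decomposition> stratum: %s\n", x$stratum))
  cat("  cumulative explained:",
      paste(sprintf("%.1f%%", 100 * x$cumulative), collapse = "  "), "\n")
  cat("  contributions:",
      paste(sprintf("%s %.1f%%", names(x$contributions),
                    100 * x$contributions), collapse = "  "), "\n")
  cat(sprintf("  unexplained: %.1f%%\n", 100 * x$unexplained))
  invisible(x)
}

#' @export
as.data.frame.variance_decomposition <- function(x, ...) {
  data.frame(stratum = x$stratum,
             block = c(names(x$contributions), "unexplained"),
             share = c(unname(x$contributions), x$unexplained),
             row.names = NULL)
}
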