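## End-to-end orchestration: cohort -> descriptives -> four nested model
## fits -> variance decomposition (overall and per procedure) -> hospital
## profiling with funnel limits -> one report object.

#' Run the full mortality-variation analysis
#'
#' Executes every stage on either a simulated cohort (pass a
#' [simulation_config()], e.g. from [scenario()]) or user-supplied tables
#' (pass a list with `patients` and `hospitals`, e.g. from [read_cohort()]):
#'
#' 1. cohort summary: mortality rates, procedure mix, descriptive table;
#' 2. the four nested random-intercept fits with odds-ratio tables;
#' 3. [sequential_decomposition()], overall and per procedure;
#' 4. per-procedure hospital profiling: empirical-Bayes effects
#'    ([eb_hospital_effects()]), reliability-adjusted rates
#'    ([shrunken_rates()]), tertile groups and [funnel_limits()].
#'
#' A failed stage is recorded in the report (section marked failed) rather
#' than aborting the run; the report's `status` attribute is 0 on success, 2
#' after a validation failure and 3 after an estimation failure, so a thin
#' scripting wrapper can use it as an exit code.
#'
#' @param input a `simulation_config`, or a list with `patients` and
#'   `hospitals`
#' @param spec a [model_spec()]
#' @param options fitting options (see [fit_random_intercept_logit()])
#' @param strata run per-procedure strata? (default TRUE)
#' @param exclude_es sensitivity option: drop the esophagectomy cohort and
#'   refit everything without the ES level
#' @param profile_hospitals run the reliability-profiling stage?
#' @param eb_method method for [eb_hospital_effects()]
#' @param funnel_alphas significance levels for [funnel_limits()]
#' @return an `analysis_report` list: `config`, `seed`, `cohort_summary`,
#'   `or_tables`, `decomposition`, `profiles`, `funnel`, `rates`,
#'   `provenance`; attribute `status` as above
#' @export
run_analysis <- function(input, spec = model_spec(), options = list(),
                         strata = TRUE, exclude_es = FALSE,
                         profile_hospitals = TRUE,
                         eb_method = "posterior",
                         funnel_alphas = c(0.05, 0.002)) {
  status <- 0L
  note_failure <- function(e) {
    status <<- max(status,
                   if (inherits(e, "ihmvar_estimation_error")) 3L else 2L)
    list(failed = TRUE, message = conditionMessage(e))
  }

  if (inherits(input, "simulation_config")) {
    cohort <- simulate_cohort(input)
    cfg_echo <- input[c("name", "n_hospitals", "n_patients", "sigma_u",
                        "intercept", "seed")]
    seed <- input$seed
  } else if (is.list(input) && all(c("patients", "hospitals") %in% names(input))) {
    cohort <- input
    cfg_echo <- list(name = "user-supplied")
    seed <- NA_integer_
  } else {
    ihm_validation_error("`input` must be a simulation_config or a cohort list")
  }
  patients <- cohort$patients
  hospitals <- cohort$hospitals
  if (exclude_es) patients <- patients[patients$procedure != "ES", , drop = FALSE]

  report <- list(config = cfg_echo, seed = seed, exclude_es = exclude_es)

  report$rates <- tryCatch(rate_summary(patients), error = note_failure)
  report$cohort_summary <- tryCatch({
    mix <- procedure_mix(table(patients$procedure))
    list(n_patients = nrow(patients), n_hospitals = nrow(hospitals),
         procedure_mix_pct = as.list(mix),
         high_volume_share = {
           hv <- classify_volume(
             patients$procedure,
             as.matrix(hospitals[paste0("mean_annual_volume_", .procedures)])[
               cbind(match(patients$hospital_id, hospitals$hospital_id),
                     match(patients$procedure, .procedures))])
           mean(hv == "high")
         })
  }, error = note_failure)

  dec <- tryCatch(
    sequential_decomposition(patients, hospitals, spec,
                             strata = if (strata) "procedure" else NULL,
                             options = options),
    error = note_failure)
  report$decomposition <- dec

  report$or_tables <- tryCatch({
    if (is.list(dec) && isTRUE(dec$failed)) stop("decomposition unavailable")
    lapply(dec$fits, odds_ratio_table)
  }, error = function(e) note_failure(e))

  if (profile_hospitals) {
    prof <- tryCatch({
      if (is.list(dec) && isTRUE(dec$failed)) stop("decomposition unavailable")
      src <- if (strata && !is.null(dec$strata)) {
        lapply(names(dec$strata), function(s) {
          fit_s <- dec$strata[[s]]$fits[[length(dec$strata[[s]]$fits)]]
          eff <- eb_hospital_effects(fit_s, method = eb_method)
          tertile_groups(shrunken_rates(fit_s, eff, stratum = s))
        })
      } else {
        fit_o <- dec$fits[[length(dec$fits)]]
        eff <- eb_hospital_effects(fit_o, method = eb_method)
        list(tertile_groups(shrunken_rates(fit_o, eff, stratum = "overall")))
      }
      do.call(rbind, src)
    }, error = note_failure)
    report$profiles <- prof

    report$funnel <- tryCatch({
      if (is.data.frame(prof)) {
        do.call(rbind, lapply(unique(prof$stratum), function(s) {
          sub <- prof[prof$stratum == s, ]
          center <- sum(sub$expected_deaths) / sum(sub$n_patients)
          grid <- unique(pmax(1, round(seq(1, max(sub$n_patients),
                                           length.out = 60))))
          fc <- funnel_limits(center, grid, alphas = funnel_alphas)
          fc$stratum <- s
          fc
        }))
      } else {
        stop("profiles unavailable")
      }
    }, error = note_failure)
  }

  report$provenance <- list(
    package_version = as.character(packageVersion("ihmvar")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    input_digests = if (!is.null(cohort$paths)) {
      as.list(tools::md5sum(unlist(cohort$paths)))
    } else NULL
  )
  attr(report, "status") <- status
  class(report) <- "analysis_report"
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", if (attr(x, "status") == 0L) "ok" else
    paste("status", attr(x, "status")), "\n")
  if (is.data.frame(x$rates)) {
    cat("  overall IHM:",
        sprintf("%.1f%% (%d/%d)", 100 * x$rates$rate[1], x$rates$deaths[1],
                x$rates$n[1]), "\n")
  }
  if (inherits(x$decomposition, "variance_decomposition")) {
    print(x$decomposition)
  }
  invisible(x)
}
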