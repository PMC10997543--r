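## Descriptive and univariable machinery: Leapfrog volume classification,
## mortality-rate and cohort-mix summaries, chi-square / Kruskal-Wallis
## comparisons, and stratified descriptive tables.

#' Leapfrog minimum annual volume thresholds
#'
#' Minimum annual procedure counts defining a high-volume hospital:
#' esophagectomy 20, pneumonectomy 40, pancreatectomy 20, proctectomy 16.
#'
#' @return named numeric vector (ES, PN, PD, PR)
#' @export
leapfrog_thresholds <- function() c(ES = 20, PN = 40, PD = 20, PR = 16)

#' Classify hospital volume against the Leapfrog thresholds
#'
#' A hospital is high-volume for a procedure when its mean annual volume
#' meets or exceeds the threshold (boundary-inclusive: volume = threshold is
#' high).
#'
#' @param procedure procedure code(s): ES, PN, PD or PR (recycled)
#' @param mean_annual_volume mean annual caseload(s), >= 0
#' @param thresholds named thresholds (default [leapfrog_thresholds()])
#' @return character vector `"high"` / `"low"`
#' @export
#' @examples
#' classify_volume("ES", 20)  # "high"
#' classify_volume("PN", 0)   # "low"
classify_volume <- function(procedure, mean_annual_volume,
                            thresholds = leapfrog_thresholds()) {
  if (any(!procedure %in% names(thresholds))) {
    ihm_stop(paste0("unknown procedure(s): ",
                    paste(setdiff(unique(procedure), names(thresholds)),
                          collapse = ", ")),
             "ihmvar_lookup_error")
  }
  if (any(mean_annual_volume < 0)) {
    ihm_validation_error("`mean_annual_volume` must be >= 0")
  }
  ifelse(mean_annual_volume >= thresholds[procedure], "high", "low")
}

#' In-hospital mortality rates, overall and per procedure
#'
#' Proportion of deaths per stratum with raw counts; percentages are
#' reported to one decimal (round half to even). Empty strata are reported
#' with `NA` rates, not 0.
#'
#' @param patients patient table with `died` and `procedure` columns
#' @return data frame: stratum, n, deaths, rate (unrounded proportion),
#'   pct (1-decimal percentage)
#' @export
#' @examples
#' rate_summary(data.frame(procedure = "ES", died = rep(c(0, 1), c(96, 4))))
rate_summary <- function(patients) {
  if (!all(patients$died %in% c(0, 1))) {
    ihm_validation_error("`died` must be binary 0/1")
  }
  strata <- c("overall", .procedures)
  out <- do.call(rbind, lapply(strata, function(s) {
    rows <- if (s == "overall") rep(TRUE, nrow(patients)) else patients$procedure == s
    n <- sum(rows); deaths <- sum(patients$died[rows])
    rate <- if (n > 0) deaths / n else NA_real_
    data.frame(stratum = s, n = n, deaths = deaths, rate = rate,
               pct = if (n > 0) pct1(rate) else NA_real_)
  }))
  out
}

#' Procedure mix as percentages
#'
#' @param counts named non-negative counts (total > 0)
#' @return named percentages to one decimal; attribute `"raw"` carries the
#'   unrounded values
#' @export
#' @examples
#' procedure_mix(c(ES = 2700, PN = 30822, PD = 7530, PR = 11786))
procedure_mix <- function(counts) {
  if (any(counts < 0)) ihm_validation_error("`counts` must be >= 0")
  total <- sum(counts)
  if (total <= 0) ihm_validation_error("total count must be > 0")
  raw <- 100 * counts / total
  out <- round(raw, 1)
  attr(out, "raw") <- raw
  out
}

#' Univariable comparison of a variable against the outcome
#'
#' Categorical variables: Pearson chi-square test of independence on the
#' contingency table (no continuity correction), df = (r-1)(c-1).
#' Continuous variables: Kruskal-Wallis rank test (with tie correction)
#' across outcome groups. A warning is attached (test still computed) when
#' any expected cell count is below 1.
#'
#' @param patients patient table
#' @param variable column to compare
#' @param outcome grouping column (default `"died"`)
#' @return list: test, statistic, df, p_value, warning
#' @export
univariable_compare <- function(patients, variable, outcome = "died") {
  x <- patients[[variable]]
  g <- patients[[outcome]]
  if (is.null(x)) ihm_validation_error(paste0("unknown variable `", variable, "`"))
  if (is.null(g)) ihm_validation_error(paste0("unknown outcome `", outcome, "`"))
  warn <- NA_character_
  if (is.character(x) || is.factor(x) || is.logical(x)) {
    tab <- table(x, g)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 1)) warn <- "expected cell count < 1"
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(test = "chi-square", statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = unname(ct$p.value),
         warning = warn)
  } else {
    kt <- kruskal.test(x, factor(g))
    list(test = "kruskal-wallis", statistic = unname(kt$statistic),
         df = unname(kt$parameter), p_value = unname(kt$p.value),
         warning = warn)
  }
}

#' Stratified descriptive table with univariable tests
#'
#' Counts and percentages for categorical variables, median (IQR) for
#' patient-level continuous variables, and mean (SD) for hospital structural
#' variables, per stratum, with a chi-square (categorical) or
#' Kruskal-Wallis (continuous) test across strata attached per variable.
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7).
#'
#' @param patients patient table
#' @param hospitals optional hospital table (adds structural rows, linked
#'   through `hospital_id`)
#' @param stratify_by categorical column to stratify on (default
#'   `"procedure"`); a single-stratum input emits the table without tests
#' @return long data frame: variable, level, stratum, statistic
#'   (`"n_pct"`, `"median_iqr"` or `"mean_sd"`), and value columns, plus a
#'   `tests` attribute (per-variable test results)
#' @export
descriptive_table <- function(patients, hospitals = NULL,
                              stratify_by = "procedure") {
  if (!stratify_by %in% names(patients)) {
    ihm_validation_error(paste0("unknown stratification field `", stratify_by, "`"))
  }
  strata <- sort(unique(as.character(patients[[stratify_by]])))
  single <- length(strata) < 2L

  cat_vars <- intersect(c("sex", "race", "insurance", "year"), names(patients))
  cont_vars <- intersect(c("age", "comorbidity_index", "svi", "travel_minutes"),
                         names(patients))

  rows <- list(); tests <- list()
  for (v in cat_vars) {
    x <- as.character(patients[[v]])
    for (s in c("overall", strata)) {
      sel <- if (s == "overall") rep(TRUE, nrow(patients)) else patients[[stratify_by]] == s
      tab <- table(x[sel])
      for (lev in names(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lev, stratum = s, statistic = "n_pct",
          n = as.integer(tab[[lev]]),
          value = pct1(tab[[lev]] / sum(tab)), value2 = NA_real_)
      }
    }
    if (!single) tests[[v]] <- univariable_compare(patients, v, stratify_by)
  }
  for (v in cont_vars) {
    x <- patients[[v]]
    for (s in c("overall", strata)) {
      sel <- if (s == "overall") rep(TRUE, nrow(patients)) else patients[[stratify_by]] == s
      q <- quantile(x[sel], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, stratum = s,
        statistic = "median_iqr", n = sum(sel),
        value = q[2], value2 = q[3] - q[1])
    }
    if (!single) tests[[v]] <- univariable_compare(patients, v, stratify_by)
  }
  if (!is.null(hospitals)) {
    hvars <- intersect(c("fte_per_bed", "beds", "operating_rooms"),
                       names(hospitals))
    for (v in hvars) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_, stratum = "overall",
        statistic = "mean_sd", n = nrow(hospitals),
        value = mean(hospitals[[v]]), value2 = sd(hospitals[[v]]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "tests") <- tests
  out
}
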