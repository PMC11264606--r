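#' Run the full comparison study on a cohort table
#'
#' Orchestrates the complete analysis: baseline agreement between the two
#' utilities (correlation, both ICC forms, means/SDs, mean difference,
#' ceiling fraction), a correlation block of the utilities with the
#' available pain-impact scores, the two 22-condition regressions and the
#' correlation of their coefficient vectors, the crosswalk fitted in both
#' directions (OLS with linear equating, and optionally the beta-family
#' alternative) with their evaluation suites, and — when a follow-up table
#' is supplied — the longitudinal change-correlation block. All statistics
#' are delegated to the module functions, so the report is deterministic
#' given its inputs.
#'
#' @param baseline person-level baseline table with `eq5d_utility`,
#'   `propr_utility` and the 22 condition columns.
#' @param followup optional follow-up table (`person_id`, both utilities,
#'   `retro_*` items).
#' @param config list of options: `fit_beta` (default TRUE) fits the
#'   beta-family crosswalks; `beta_mode` (`"beta"`); `conditions`
#'   (condition column names).
#' @return A list of class `study_report`.
#' @export
run_study <- function(baseline, followup = NULL, config = list()) {
  cfg <- utils::modifyList(list(fit_beta = TRUE, beta_mode = "beta",
                                conditions = condition_names()), config)
  need <- c("eq5d_utility", "propr_utility", cfg$conditions)
  missing_cols <- setdiff(need, names(baseline))
  if (length(missing_cols))
    stop(sprintf("schema violation in baseline table; missing columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  eq <- baseline$eq5d_utility; pr <- baseline$propr_utility

  agreement <- agreement_report(eq, pr, labels = c("EQ-5D-5L", "PROPr"))
  ceiling_fraction <- mean(eq[is.finite(eq)] == 1)

  pain_cols <- intersect(c("odi", "rmdq", "peg", "startback",
                           "gcps_intensity", "gcps_disability", "chronic_pain"),
                         names(baseline))
  pain_correlations <- if (length(pain_cols))
    correlation_matrix(baseline, c("propr_utility", "eq5d_utility", pain_cols))
  else NULL

  fit_pr <- fit_condition_regression(baseline, "propr_utility", cfg$conditions)
  fit_eq <- fit_condition_regression(baseline, "eq5d_utility", cfg$conditions)
  beta_vector_correlation <- compare_coefficient_vectors(fit_pr, fit_eq)

  cw <- list(
    propr2eq5d = fit_ols_map(pr, eq, "propr2eq5d"),
    eq5d2propr = fit_ols_map(eq, pr, "eq5d2propr"))
  cw_eval <- list(
    propr2eq5d = evaluate_map(cw$propr2eq5d, pr, eq),
    eq5d2propr = evaluate_map(cw$eq5d2propr, eq, pr))
  beta_eval <- NULL
  if (isTRUE(cfg$fit_beta)) {
    bm <- list(
      propr2eq5d = fit_beta_binomial_map(pr, eq, mode = cfg$beta_mode),
      eq5d2propr = fit_beta_binomial_map(eq, pr, mode = cfg$beta_mode))
    beta_eval <- list(
      propr2eq5d = evaluate_map(bm$propr2eq5d, pr, eq),
      eq5d2propr = evaluate_map(bm$eq5d2propr, eq, pr))
  }

  longitudinal <- NULL
  if (!is.null(followup) && nrow(followup) > 0) {
    if (!"person_id" %in% names(baseline))
      stop("schema violation: baseline lacks person_id for follow-up linkage",
           call. = FALSE)
    longitudinal <- change_correlations(baseline, followup)
  }

  structure(list(
    n_baseline = length(eq),
    baseline_agreement = agreement,
    ceiling_fraction = ceiling_fraction,
    pain_correlations = pain_correlations,
    condition_fits = list(propr = fit_pr, eq5d = fit_eq),
    beta_vector_correlation = beta_vector_correlation,
    crosswalk = cw, crosswalk_evaluation = cw_eval,
    beta_crosswalk_evaluation = beta_eval,
    longitudinal = longitudinal),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> baseline n = %d\n", x$n_baseline))
  print(x$baseline_agreement)
  cat(sprintf("  EQ-5D-5L ceiling fraction: %.1f%%\n", 100 * x$ceiling_fraction))
  cat(sprintf("  condition models: PROPr adj R^2 = %.2f, EQ-5D-5L adj R^2 = %.2f, beta-vector r = %.2f\n",
              x$condition_fits$propr$adj_r_squared,
              x$condition_fits$eq5d$adj_r_squared,
              x$beta_vector_correlation))
  cat("  crosswalk propr->eq5d: "); print(x$crosswalk_evaluation$propr2eq5d)
  cat("  crosswalk eq5d->propr: "); print(x$crosswalk_evaluation$eq5d2propr)
  if (!is.null(x$longitudinal)) print(x$longitudinal)
  invisible(x)
}

# Strip non-serializable pieces and flatten for JSON
.report_to_list <- function(x) {
  ev <- function(e) if (is.null(e)) NULL else unclass(e)
  list(
    n_baseline = x$n_baseline,
    baseline_agreement = unclass(x$baseline_agreement),
    ceiling_fraction = x$ceiling_fraction,
    pain_correlations = if (is.null(x$pain_correlations)) NULL else
      list(r = x$pain_correlations$r, n = x$pain_correlations$n),
    condition_fits = lapply(x$condition_fits, function(f)
      list(outcome = f$outcome, intercept = f$intercept,
           r_squared = f$r_squared, adj_r_squared = f$adj_r_squared,
           n = f$n, table = as.data.frame(f))),
    beta_vector_correlation = x$beta_vector_correlation,
    crosswalk_models = lapply(x$crosswalk, unclass),
    crosswalk_evaluation = lapply(x$crosswalk_evaluation, ev),
    beta_crosswalk_evaluation = lapply(x$beta_crosswalk_evaluation, ev),
    longitudinal = if (is.null(x$longitudinal)) NULL else
      unclass(x$longitudinal))
}

#' Serialize a study report to JSON
#'
#' @param report a `study_report` from [run_study()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  jsonlite::write_json(.report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
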