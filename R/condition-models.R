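#' Canonical 22-condition indicator list
#'
#' The 22 self-reported health conditions, in the canonical reporting
#' order: thirteen lifetime diagnoses (hypertension through depression)
#' followed by nine current conditions (allergies through trouble
#' sleeping). The two fake screening conditions (Syndomitis, Chekalism) are
#' excluded: they are careless-responder screens, never regressors.
#'
#' @return Character vector of 22 column names.
#' @export
condition_names <- function() {
  c("hypertension", "high_cholesterol", "heart_disease", "angina",
    "heart_attack", "stroke", "asthma", "cancer", "diabetes", "copd",
    "arthritis", "anxiety", "depression", "allergies", "back_pain",
    "sciatica", "neck_pain", "trouble_seeing", "dermatitis",
    "stomach_trouble", "trouble_hearing", "trouble_sleeping")
}

#' Published condition effects on the two utilities
#'
#' The packaged table of the 22 conditions' prevalences, OLS regression
#' coefficients and zero-order correlations for both utilities (reported
#' from a U.S. general-population baseline sample, n = 4098, to 3 and 2
#' decimals respectively), with the model intercepts and R squared as
#' attributes `propr_intercept`, `eq5d_intercept`, `propr_r_squared`,
#' `eq5d_r_squared`. These printed coefficients also serve as the true
#' effects of the synthetic cohort generator.
#'
#' @return Data frame with columns `condition`, `prevalence`, `propr_beta`,
#'   `propr_zero_order`, `eq5d_beta`, `eq5d_zero_order`.
#' @export
published_condition_effects <- function() {
  path <- system.file("extdata", "us_condition_effects.csv",
                      package = "prefcross", mustWork = TRUE)
  parsed <- .read_meta(path)
  df <- read.csv(text = paste(parsed$body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  stopifnot(identical(df$condition, condition_names()))
  for (k in c("propr_intercept", "eq5d_intercept",
              "propr_r_squared", "eq5d_r_squared"))
    attr(df, k) <- .meta_num(parsed$meta, k, path)
  df
}

.stars <- function(p) {
  ifelse(p < 0.0001, "****",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Regress a utility on the 22 condition indicators
#'
#' One simultaneous OLS model per outcome: the utility regressed on all 22
#' binary indicators (complete cases), reported with per-condition
#' zero-order correlations, significance stars at the 0.05 / 0.01 / 0.001 /
#' 0.0001 thresholds, intercept, and both R squared and adjusted R squared.
#'
#' @param data person-level data frame containing the outcome column and
#'   all condition columns coded 0/1.
#' @param outcome name of the utility column.
#' @param conditions condition column names (default [condition_names()]).
#' @return Object of class `condition_fit` with `coefficients`,
#'   `zero_order`, `p_values`, `stars`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `n`, `outcome`.
#' @export
fit_condition_regression <- function(data, outcome,
                                     conditions = condition_names()) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(c(outcome, conditions), names(data))
  if (length(missing_cols))
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  sub <- data[, c(outcome, conditions)]
  sub <- sub[complete.cases(sub), ]
  n <- nrow(sub)
  if (n <= length(conditions) + 1)
    stop("insufficient data: need n > number of regressors + 1", call. = FALSE)
  bad <- conditions[!vapply(conditions, function(cn)
    all(sub[[cn]] %in% c(0, 1)), logical(1))]
  if (length(bad))
    stop(sprintf("condition columns must be coded 0/1: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  X <- as.matrix(sub[, conditions])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    aliased <- conditions[qrX$pivot[-seq_len(qrX$rank)] - 1]
    stop(sprintf("rank deficiency among condition indicators: %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  form <- stats::as.formula(paste(outcome, "~",
                                  paste(conditions, collapse = " + ")))
  fit <- lm(form, data = sub)
  sm <- summary(fit)
  co <- sm$coefficients
  zero_order <- vapply(conditions, function(cn) {
    if (sd(sub[[cn]]) == 0) NA_real_ else cor(sub[[outcome]], sub[[cn]])
  }, numeric(1))
  p_values <- setNames(co[conditions, "Pr(>|t|)"], conditions)
  structure(list(outcome = outcome,
                 coefficients = setNames(co[conditions, "Estimate"], conditions),
                 std_errors = setNames(co[conditions, "Std. Error"], conditions),
                 zero_order = zero_order,
                 p_values = p_values,
                 stars = .stars(p_values),
                 intercept = co["(Intercept)", "Estimate"],
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 n = n),
            class = "condition_fit")
}

#' @export
print.condition_fit <- function(x, ...) {
  cat(sprintf("<condition_fit> outcome %s (n = %d): R^2 = %.3f, adj R^2 = %.3f, intercept = %.3f\n",
              x$outcome, x$n, x$r_squared, x$adj_r_squared, x$intercept))
  df <- data.frame(beta = round(x$coefficients, 3),
                   zero_order = round(x$zero_order, 2),
                   sig = x$stars)
  print(head(df, 22))
  invisible(x)
}

#' As a data frame: condition, beta, zero-order r, stars
#' @param x a `condition_fit`.
#' @param ... unused.
#' @export
as.data.frame.condition_fit <- function(x, ...) {
  data.frame(condition = names(x$coefficients),
             beta = unname(x$coefficients),
             zero_order_r = unname(x$zero_order),
             stars = unname(x$stars),
             row.names = NULL)
}

#' Correlate two condition-coefficient vectors
#'
#' Product-moment correlation between the per-condition regression
#' coefficients of two fits (or two named coefficient vectors), after
#' verifying that the condition name lists match.
#'
#' @param fit_a,fit_b `condition_fit` objects or named numeric vectors.
#' @return Scalar correlation.
#' @export
compare_coefficient_vectors <- function(fit_a, fit_b) {
  va <- if (inherits(fit_a, "condition_fit")) fit_a$coefficients else fit_a
  vb <- if (inherits(fit_b, "condition_fit")) fit_b$coefficients else fit_b
  if (is.null(names(va)) || is.null(names(vb)) ||
      !identical(sort(names(va)), sort(names(vb))))
    stop("alignment error: condition name lists do not match", call. = FALSE)
  cor(va, vb[names(va)])
}

#' Correlate six-month utility changes with retrospective change items
#'
#' Computes per-person change (`followup - baseline`) for both utilities on
#' the persons present in both waves (linked by `person_id`), the
#' change-change correlation between the two utilities, and product-moment
#' correlations of each utility's change with each retrospective item
#' (items scored so that higher = more positive change). Pairs involving a
#' zero-variance vector are flagged undefined (`NA`).
#'
#' @param baseline,followup data frames with `person_id`, `eq5d_utility`,
#'   `propr_utility`; `followup` additionally holds the retrospective item
#'   columns.
#' @param retro_items character vector of retrospective item column names
#'   in `followup` (default: columns starting with `retro_`).
#' @return List of class `change_correlations`: `table` (one row per item:
#'   r and p for each utility's change), `change_change_r`,
#'   `change_change_p`, `mean_change` (per utility), `n`.
#' @export
change_correlations <- function(baseline, followup, retro_items = NULL) {
  need <- c("person_id", "eq5d_utility", "propr_utility")
  for (nm in need) {
    if (!nm %in% names(baseline)) stop(sprintf("baseline lacks column %s", nm), call. = FALSE)
    if (!nm %in% names(followup)) stop(sprintf("followup lacks column %s", nm), call. = FALSE)
  }
  if (is.null(retro_items))
    retro_items <- grep("^retro_", names(followup), value = TRUE)
  idx <- match(followup$person_id, baseline$person_id)
  ok <- !is.na(idx)
  if (!any(ok)) stop("insufficient data: no linked person IDs", call. = FALSE)
  fu <- followup[ok, ]; bl <- baseline[idx[ok], ]
  d_eq <- fu$eq5d_utility - bl$eq5d_utility
  d_pr <- fu$propr_utility - bl$propr_utility
  safe_cor <- function(a, b) {
    cc <- is.finite(a) & is.finite(b)
    if (sum(cc) < 3 || sd(a[cc]) == 0 || sd(b[cc]) == 0)
      return(c(r = NA_real_, p = NA_real_))
    ct <- cor.test(a[cc], b[cc])
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  cc <- safe_cor(d_eq, d_pr)
  tab <- do.call(rbind, lapply(retro_items, function(it) {
    r_pr <- safe_cor(d_pr, fu[[it]])
    r_eq <- safe_cor(d_eq, fu[[it]])
    data.frame(item = it, r_change_propr = r_pr["r"], p_change_propr = r_pr["p"],
               r_change_eq5d = r_eq["r"], p_change_eq5d = r_eq["p"],
               row.names = NULL)
  }))
  structure(list(table = tab,
                 change_change_r = unname(cc["r"]),
                 change_change_p = unname(cc["p"]),
                 mean_change = c(eq5d = mean(d_eq, na.rm = TRUE),
                                 propr = mean(d_pr, na.rm = TRUE)),
                 n = nrow(fu)),
            class = "change_correlations")
}

#' @export
print.change_correlations <- function(x, ...) {
  cat(sprintf("<change_correlations> n = %d linked persons\n", x$n))
  cat(sprintf("  mean change: EQ-5D-5L %.3f, PROPr %.3f; change-change r = %.3f\n",
              x$mean_change["eq5d"], x$mean_change["propr"], x$change_change_r))
  if (nrow(x$table)) {
    df <- x$table
    df$r_change_propr <- round(df$r_change_propr, 2)
    df$r_change_eq5d <- round(df$r_change_eq5d, 2)
    print(df[, c("item", "r_change_propr", "r_change_eq5d")])
  }
  invisible(x)
}
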