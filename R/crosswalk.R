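#' Construct a crosswalk model
#'
#' A crosswalk model maps one utility score onto the other in three ordered
#' steps: OLS prediction (`intercept + slope * source`), linear equating of
#' the predicted scores onto the observed target's mean and SD, and
#' clamping of the equated scores to bounds (the target's observed or
#' theoretical range).
#'
#' @param direction `"propr2eq5d"` or `"eq5d2propr"`.
#' @param intercept,slope OLS coefficients (utility units).
#' @param target_mean,target_sd observed moments of the target score (the
#'   equating targets).
#' @param predicted_sd SD of the predicted scores on the fitting sample.
#' @param clamp length-2 numeric, lower and upper recoding bounds.
#' @param adj_r_squared,n fit diagnostics (optional).
#' @return An object of class `crosswalk_model`.
#' @export
crosswalk_model <- function(direction, intercept, slope, target_mean, target_sd,
                            predicted_sd, clamp, adj_r_squared = NA_real_,
                            n = NA_integer_) {
  direction <- match.arg(direction, c("propr2eq5d", "eq5d2propr"))
  if (!is.finite(target_sd) || target_sd <= 0) stop("target_sd must be > 0", call. = FALSE)
  if (!is.finite(predicted_sd) || predicted_sd <= 0)
    stop("predicted_sd must be > 0", call. = FALSE)
  if (length(clamp) != 2 || clamp[1] >= clamp[2])
    stop("clamp must be c(lower, upper) with lower < upper", call. = FALSE)
  structure(list(direction = direction, intercept = intercept, slope = slope,
                 target_mean = target_mean, target_sd = target_sd,
                 predicted_sd = predicted_sd, clamp = as.numeric(clamp),
                 adj_r_squared = adj_r_squared, n = n),
            class = "crosswalk_model")
}

#' @export
print.crosswalk_model <- function(x, ...) {
  cat(sprintf("<crosswalk_model> %s: predicted = %.3f + %.3f * source\n",
              x$direction, x$intercept, x$slope))
  cat(sprintf("  equating target %.3f (SD %.3f), predicted SD %.3f, clamp [%.3f, %.3f]\n",
              x$target_mean, x$target_sd, x$predicted_sd, x$clamp[1], x$clamp[2]))
  if (is.finite(x$adj_r_squared))
    cat(sprintf("  adjusted R^2 = %.3f (n = %d)\n", x$adj_r_squared, x$n))
  invisible(x)
}

#' Fit an OLS crosswalk between two utility scores
#'
#' Regresses the target score on the source score by least squares and
#' packages the result, together with the equating targets (the observed
#' target mean and SD) and the predicted-score SD, as a
#' [crosswalk_model]. By default the clamp bounds are the observed range of
#' the target (out-of-range equated scores are recoded to the nearest
#' observed score).
#'
#' @param source,target aligned score vectors (complete cases used).
#' @param direction model direction label.
#' @param clamp optional explicit clamp bounds; default observed
#'   `range(target)`.
#' @return A [crosswalk_model].
#' @export
fit_ols_map <- function(source, target, direction = "propr2eq5d", clamp = NULL) {
  p <- paired_sample(source, target)
  if (p$n < 3) stop("insufficient data: need >= 3 complete pairs", call. = FALSE)
  if (sd(p$x) == 0) stop("degenerate fit: source score has zero variance", call. = FALSE)
  fit <- lm(y ~ x, data = data.frame(x = p$x, y = p$y))
  sm <- suppressWarnings(summary(fit))  # perfect fits warn harmlessly
  if (is.null(clamp)) clamp <- range(p$y)
  crosswalk_model(direction = direction,
                  intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
                  target_mean = mean(p$y), target_sd = sd(p$y),
                  predicted_sd = sd(fitted(fit)),
                  clamp = clamp,
                  adj_r_squared = sm$adj.r.squared, n = p$n)
}

#' The published U.S. general-population crosswalk constants
#'
#' Returns the published mapping between the two scores estimated on a U.S.
#' general-population baseline sample (n = 4092 complete pairs):
#' `EQ-5D-5L_predicted = 0.563 + 0.543 * PROPr`, equated onto mean 0.855 /
#' SD 0.195 with predicted-score SD 0.135 and clamped to the theoretical
#' EQ-5D-5L range (-0.573, 1); and
#' `PROPr_predicted = -0.218 + 0.885 * EQ-5D-5L`, equated onto mean 0.538 /
#' SD 0.249 with predicted-score SD 0.173 and clamped to (-0.022, 1).
#'
#' @param direction `"propr2eq5d"` or `"eq5d2propr"`.
#' @return A [crosswalk_model] carrying the published constants.
#' @export
published_crosswalk <- function(direction = c("propr2eq5d", "eq5d2propr")) {
  direction <- match.arg(direction)
  if (direction == "propr2eq5d") {
    crosswalk_model("propr2eq5d", intercept = 0.563, slope = 0.543,
                    target_mean = 0.855, target_sd = 0.195,
                    predicted_sd = 0.135, clamp = c(-0.573, 1),
                    adj_r_squared = 0.48, n = 4092L)
  } else {
    crosswalk_model("eq5d2propr", intercept = -0.218, slope = 0.885,
                    target_mean = 0.538, target_sd = 0.249,
                    predicted_sd = 0.173, clamp = c(-0.022, 1),
                    adj_r_squared = 0.48, n = 4092L)
  }
}

#' Apply a crosswalk: predict, equate, clamp
#'
#' Applies the three stages in strict order: `predicted = intercept +
#' slope * source`; `equated = target_mean + (target_sd / predicted_sd) *
#' (predicted - target_mean)`; equated scores outside the clamp bounds are
#' recoded to the nearest bound.
#'
#' @param model a [crosswalk_model].
#' @param source numeric source scores.
#' @param value which stage to return: the final `"equated"` scores
#'   (default), the raw `"predicted"` scores, or `"both"` as a data frame.
#' @return Numeric vector, or a data frame with columns `predicted` and
#'   `equated` when `value = "both"`.
#' @export
apply_crosswalk <- function(model, source, value = c("equated", "predicted", "both")) {
  if (!inherits(model, "crosswalk_model"))
    stop("`model` must be a crosswalk_model", call. = FALSE)
  value <- match.arg(value)
  .check_numeric(source, "source")
  predicted <- model$intercept + model$slope * source
  if (value == "predicted") return(predicted)
  equated <- model$target_mean +
    (model$target_sd / model$predicted_sd) * (predicted - model$target_mean)
  equated <- pmin(pmax(equated, model$clamp[1]), model$clamp[2])
  if (value == "both") data.frame(predicted = predicted, equated = equated)
  else equated
}

#' Rescale scores to the unit interval
#'
#' `(x - min(x)) / (max(x) - min(x))`: the observed minimum maps to 0 and
#' the observed maximum to 1. The returned transform record allows exact
#' inversion with [from_unit_interval()].
#'
#' @param scores numeric vector with positive range.
#' @return List with `values` (rescaled scores) and `transform` (list with
#'   `minimum` and `range`).
#' @export
to_unit_interval <- function(scores) {
  .check_numeric(scores, "scores", 2)
  ok <- is.finite(scores)
  lo <- min(scores[ok]); rg <- max(scores[ok]) - lo
  if (rg == 0) stop("degenerate input: observed range is zero", call. = FALSE)
  list(values = (scores - lo) / rg, transform = list(minimum = lo, range = rg))
}

#' Invert a unit-interval rescaling
#'
#' @param values unit-interval scores.
#' @param transform the transform record from [to_unit_interval()].
#' @return Scores on the original scale.
#' @export
from_unit_interval <- function(values, transform) {
  transform$minimum + values * transform$range
}

#' Fit a beta-family crosswalk on the unit interval
#'
#' Alternative to the OLS map for bounded utility scores: the target is
#' rescaled to the unit interval by its observed range, a mean model with
#' logit link is fitted, and predictions are mapped back through the
#' inverse rescaling. Two likelihoods are available: a continuous beta
#' regression (`mode = "beta"`, the default; boundary values are nudged by
#' the usual `(y (n - 1) + 0.5) / n` adjustment), and an integer-trials
#' beta-binomial (`mode = "betabinomial"`) in which the rescaled target is
#' rounded to `trials` equal steps.
#'
#' @param source numeric predictor scores.
#' @param target numeric target scores on the original (bounded) scale.
#' @param mode likelihood family, `"beta"` or `"betabinomial"`.
#' @param trials integer binomial denominator for `mode = "betabinomial"`.
#' @param covariates optional data frame of extra covariates (e.g. age,
#'   gender) entered additively; off by default.
#' @return Object of class `beta_crosswalk`: the fitted `glmmTMB` model,
#'   the unit-interval transform, coefficients, fitted values on the
#'   original scale, and `mode`.
#' @export
fit_beta_binomial_map <- function(source, target,
                                  mode = c("beta", "betabinomial"),
                                  trials = 100L, covariates = NULL) {
  mode <- match.arg(mode)
  p <- paired_sample(source, target)
  ui <- to_unit_interval(p$y)
  df <- data.frame(x = p$x)
  form_rhs <- "x"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)[p$complete, , drop = FALSE]
    df <- cbind(df, covariates)
    form_rhs <- paste(c("x", names(covariates)), collapse = " + ")
  }
  fit <- tryCatch({
    if (mode == "beta") {
      n <- length(ui$values)
      df$y <- (ui$values * (n - 1) + 0.5) / n   # pull 0/1 off the boundary
      glmmTMB::glmmTMB(stats::as.formula(paste("y ~", form_rhs)), data = df,
                       family = glmmTMB::beta_family())
    } else {
      m <- as.integer(trials)
      df$succ <- as.integer(round(ui$values * m))
      df$fail <- m - df$succ
      glmmTMB::glmmTMB(stats::as.formula(paste("cbind(succ, fail) ~", form_rhs)),
                       data = df, family = glmmTMB::betabinomial())
    }
  }, error = function(e)
    stop(sprintf("fit failure in %s crosswalk: %s", mode, conditionMessage(e)),
         call. = FALSE),
  warning = function(w)
    stop(sprintf("fit failure in %s crosswalk: %s", mode, conditionMessage(w)),
         call. = FALSE))
  if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0)
    stop(sprintf("fit failure in %s crosswalk: optimizer reported '%s'",
                 mode, fit$fit$message), call. = FALSE)
  mu <- predict(fit, type = "response")
  structure(list(model = fit, mode = mode, trials = as.integer(trials),
                 transform = ui$transform,
                 coefficients = glmmTMB::fixef(fit)$cond,
                 fitted_unit = as.numeric(mu),
                 fitted = from_unit_interval(as.numeric(mu), ui$transform),
                 n = p$n),
            class = "beta_crosswalk")
}

#' @export
print.beta_crosswalk <- function(x, ...) {
  cat(sprintf("<beta_crosswalk> %s likelihood (n = %d), logit-mean coefficients:\n",
              x$mode, x$n))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a beta-family crosswalk on the original scale
#'
#' @param object a `beta_crosswalk`.
#' @param newdata optional data frame with column `x` (and any covariates);
#'   when omitted the fitted values are returned.
#' @param ... unused.
#' @return Predicted target scores on the original scale.
#' @export
predict.beta_crosswalk <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  mu <- predict(object$model, newdata = newdata, type = "response")
  from_unit_interval(as.numeric(mu), object$transform)
}

#' Evaluate a crosswalk against observed target scores
#'
#' Computes the evaluation suite used for mapping models: adjusted R
#' squared, product-moment correlation and two-way random-effects ICC
#' between the mapped and observed scores, NMAE, and the mapped scores'
#' mean and SD. For an OLS [crosswalk_model] the mapped scores are the
#' equated (clamped) scores; for a `beta_crosswalk` they are the
#' back-transformed model predictions.
#'
#' @param model a [crosswalk_model] or `beta_crosswalk`.
#' @param source source scores.
#' @param observed observed target scores.
#' @return List of class `crosswalk_evaluation`.
#' @export
evaluate_map <- function(model, source, observed) {
  UseMethod("evaluate_map")
}

.evaluate_predictions <- function(mapped, observed, n_par) {
  p <- paired_sample(observed, mapped)
  r <- cor(p$x, p$y)
  r2 <- r^2
  adj <- 1 - (1 - r2) * (p$n - 1) / (p$n - n_par - 1)
  structure(list(adj_r_squared = adj,
                 pearson_r = r,
                 icc_random = icc_two_way_random(p$y, p$x),
                 nmae = nmae(p$x, p$y),
                 mapped_mean = mean(p$y), mapped_sd = sd(p$y),
                 observed_mean = mean(p$x), observed_sd = sd(p$x),
                 n = p$n),
            class = "crosswalk_evaluation")
}

#' @export
evaluate_map.crosswalk_model <- function(model, source, observed) {
  .evaluate_predictions(apply_crosswalk(model, source), observed, n_par = 1)
}

#' @export
evaluate_map.beta_crosswalk <- function(model, source, observed) {
  mapped <- predict(model, newdata = data.frame(x = source))
  .evaluate_predictions(mapped, observed, n_par = length(model$coefficients) - 1)
}

#' @export
print.crosswalk_evaluation <- function(x, ...) {
  cat(sprintf("<crosswalk_evaluation> n = %d\n", x$n))
  cat(sprintf("  adj R^2 = %.3f, r = %.3f, ICC random = %.3f, NMAE = %.3f\n",
              x$adj_r_squared, x$pearson_r, x$icc_random, x$nmae))
  cat(sprintf("  mapped mean %.3f (SD %.3f) vs observed %.3f (SD %.3f)\n",
              x$mapped_mean, x$mapped_sd, x$observed_mean, x$observed_sd))
  invisible(x)
}
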