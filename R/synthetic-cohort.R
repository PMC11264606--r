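#' Specification of the synthetic study cohorts
#'
#' Collects every calibration target of the synthetic generator. The
#' defaults emulate the published baseline cohort: n = 4098 respondents,
#' EQ-5D-5L mean 0.855 / SD 0.195 with 31% at the ceiling (utility exactly
#' 1), PROPr mean 0.539 / SD 0.249, cross-measure correlation 0.69,
#' condition prevalences and true effects from the packaged 22-condition
#' table (back-pain prevalence 38% defines the longitudinal subgroup), a
#' 6-month back-pain follow-up of n = 1256 with mean change 0.00 in both
#' utilities and change-change correlation 0.34, nine retrospective change
#' items with the reported "about the same" fractions and small
#' correlations with true change, and back-pain instrument scores with the
#' reported utility correlations.
#'
#' @param n_baseline,n_followup default cohort sizes.
#' @param eq_mean,eq_sd,propr_mean,propr_sd target post-censoring utility
#'   moments.
#' @param cor_eq_propr target cross-measure correlation at baseline.
#' @param eq_ceiling target fraction at EQ-5D-5L = 1 (0 switches the
#'   generator to the uncensored closed-form Gaussian mechanism).
#' @param eq_range,propr_range theoretical instrument ranges (clamp bounds).
#' @param conditions data frame with columns `condition`, `prevalence`,
#'   `eq5d_beta`, `propr_beta` (default: the packaged published table).
#' @param change_sd_eq,change_sd_propr latent SDs of the 6-month utility
#'   changes.
#' @param change_cor target correlation between the two observed changes.
#' @param retro data frame of retrospective items: `item`, `levels` (5 or
#'   7), `same_frac`, and target correlations `r_propr`, `r_eq` with the
#'   two change scores.
#' @param pain data frame of instrument targets for the back-pain
#'   subgroup: `instrument`, `mean`, `sd`, `step`, `lo`, `hi`, `r_propr`,
#'   `r_eq` (a `step` of 0 denotes a binary instrument with prevalence
#'   `mean`).
#' @param seed default random seed for generation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_baseline = 4098L, n_followup = 1256L,
                        eq_mean = 0.855, eq_sd = 0.195,
                        propr_mean = 0.539, propr_sd = 0.249,
                        cor_eq_propr = 0.69, eq_ceiling = 0.31,
                        eq_range = c(-0.573, 1), propr_range = c(-0.022, 0.954),
                        conditions = published_condition_effects(),
                        change_sd_eq = 0.13, change_sd_propr = 0.17,
                        change_cor = 0.34,
                        retro = default_retro_targets(),
                        pain = default_pain_targets(),
                        seed = 20240719L) {
  spec <- list(n_baseline = as.integer(n_baseline),
               n_followup = as.integer(n_followup),
               eq_mean = eq_mean, eq_sd = eq_sd,
               propr_mean = propr_mean, propr_sd = propr_sd,
               cor_eq_propr = cor_eq_propr, eq_ceiling = eq_ceiling,
               eq_range = eq_range, propr_range = propr_range,
               conditions = as.data.frame(conditions),
               change_sd_eq = change_sd_eq, change_sd_propr = change_sd_propr,
               change_cor = change_cor,
               retro = as.data.frame(retro), pain = as.data.frame(pain),
               seed = as.integer(seed))
  fr <- c(spec$eq_ceiling, spec$conditions$prevalence, spec$retro$same_frac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (any(abs(c(spec$cor_eq_propr, spec$change_cor,
                spec$retro$r_propr, spec$retro$r_eq)) > 1))
    stop("correlation targets must lie in [-1, 1]", call. = FALSE)
  if (any(c(spec$eq_sd, spec$propr_sd) < 0) ||
      any(c(spec$change_sd_eq, spec$change_sd_propr) < 0))
    stop("SD targets must be non-negative", call. = FALSE)
  need <- c("condition", "prevalence", "eq5d_beta", "propr_beta")
  if (!all(need %in% names(spec$conditions)))
    stop("`conditions` must have columns condition, prevalence, eq5d_beta, propr_beta",
         call. = FALSE)
  if (spec$n_baseline < 1 || spec$n_followup < 0)
    stop("cohort sizes must be positive", call. = FALSE)
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> n = %d (+%d follow-up), EQ %.3f/%.3f (ceiling %.0f%%), PROPr %.3f/%.3f, r = %.2f\n",
              x$n_baseline, x$n_followup, x$eq_mean, x$eq_sd,
              100 * x$eq_ceiling, x$propr_mean, x$propr_sd, x$cor_eq_propr))
  invisible(x)
}

#' Default retrospective-item targets
#'
#' Nine retrospective change items: the "about the same" fraction of each
#' and its target correlation with the change in each utility. Eight items
#' have 5 ordered levels, the back-pain item has 7.
#' @return Data frame used by [cohort_spec()].
#' @export
default_retro_targets <- function() {
  data.frame(
    item = c("physical_function", "social", "pain", "fatigue", "mood",
             "cognition", "sleep", "health", "back_pain"),
    levels = c(5, 5, 5, 5, 5, 5, 5, 5, 7),
    same_frac = c(0.65, 0.76, 0.62, 0.65, 0.66, 0.76, 0.66, 0.64, 0.58),
    r_propr = c(0.13, 0.15, 0.15, 0.14, 0.10, 0.06, 0.14, 0.12, 0.14),
    r_eq = c(0.19, 0.15, 0.20, 0.13, 0.11, 0.09, 0.10, 0.20, 0.16))
}

#' Default back-pain instrument targets
#'
#' Marginal summaries (plausible values for a community back-pain sample;
#' the published report gives only correlations) and target correlations
#' with the two utilities. `step` is the score granularity implied by each
#' instrument's items; `step = 0` marks the binary chronic-pain
#' classification, whose `mean` is its prevalence.
#' @return Data frame used by [cohort_spec()].
#' @export
default_pain_targets <- function() {
  data.frame(
    instrument = c("odi", "rmdq", "peg", "startback",
                   "gcps_intensity", "gcps_disability", "chronic_pain"),
    mean = c(28, 9, 4.5, 3.5, 48, 38, 0.55),
    sd = c(16, 6, 2.4, 2.3, 19, 26, NA),
    step = c(2, 1, 1 / 3, 1, 10 / 3, 10 / 3, 0),
    lo = c(0, 0, 0, 0, 0, 0, 0),
    hi = c(100, 24, 10, 9, 100, 100, 1),
    r_propr = c(-0.69, -0.62, -0.66, -0.66, -0.55, -0.65, -0.30),
    r_eq = c(-0.75, -0.65, -0.73, -0.66, -0.58, -0.68, -0.31))
}

.spec_digest <- function(spec) {
  paste(deparse(unclass(spec)), collapse = "")
}

# Ordinal scoring attenuation: corr between a standard-normal latent and
# its thresholded integer scoring, given category probabilities.
.ordinal_attenuation <- function(probs) {
  stopifnot(abs(sum(probs) - 1) < 1e-8)
  k <- length(probs)
  tau <- qnorm(cumsum(probs))        # upper thresholds; last is Inf
  phi_hi <- dnorm(tau)               # dnorm(Inf) = 0
  phi_lo <- c(0, phi_hi[-k])         # dnorm(-Inf) = 0
  s <- seq_len(k)
  cov_ls <- sum(s * (phi_lo - phi_hi))
  mu_s <- sum(s * probs)
  sd_s <- sqrt(sum(s^2 * probs) - mu_s^2)
  list(rho = cov_ls / sd_s, tau = tau)
}

# Category probabilities for a retrospective item: point mass `same` in the
# middle, remaining mass split equally across the two sides, fixed within-
# side splits putting more mass adjacent to "about the same".
.retro_probs <- function(same_frac, levels) {
  side <- (1 - same_frac) / 2
  if (levels == 5) {
    c(side * 1 / 3, side * 2 / 3, same_frac, side * 2 / 3, side * 1 / 3)
  } else if (levels == 7) {
    c(side * 1 / 3, side * 2 / 3, same_frac,
      side * 0.4, side * 0.3, side * 0.2, side * 0.1)
  } else stop("retrospective items must have 5 or 7 levels", call. = FALSE)
}

# Solve loading weights for a latent that must correlate (t1, t2) with two
# standardized variables whose mutual correlation is r12, after ordinal
# attenuation rho. Returns w1, w2 and the residual SD.
.solve_loadings <- function(t1, t2, r12, rho = 1) {
  t1 <- t1 / rho; t2 <- t2 / rho
  det <- 1 - r12^2
  w1 <- (t1 - r12 * t2) / det
  w2 <- (t2 - r12 * t1) / det
  v <- w1^2 + w2^2 + 2 * r12 * w1 * w2
  if (v > 1)
    stop(sprintf("calibration error: infeasible correlation targets (%.2f, %.2f)",
                 t1 * rho, t2 * rho), call. = FALSE)
  list(w1 = w1, w2 = w2, resid_sd = sqrt(1 - v))
}

# Draw the common-random-number calibration table
.calibration_draws <- function(spec, n_cal, force_backpain = FALSE) {
  p <- spec$conditions$prevalence
  if (force_backpain) p[spec$conditions$condition == "back_pain"] <- 1
  C <- matrix(rbinom(n_cal * length(p), 1, rep(p, each = n_cal)), n_cal, length(p))
  list(B1 = as.vector(C %*% (-spec$conditions$eq5d_beta)),
       B2 = as.vector(C %*% (-spec$conditions$propr_beta)),
       U = runif(n_cal), Z = rnorm(n_cal), ZC = rnorm(n_cal),
       ZA = rnorm(n_cal), ZB = rnorm(n_cal))
}

.eq_from_latent <- function(d_raw, spec) {
  d <- pmin(pmax(d_raw, 0), 1 - spec$eq_range[1])
  pmin(1 - d, spec$eq_range[2])
}

.propr_clamp <- function(x, spec) pmin(pmax(x, spec$propr_range[1]), spec$propr_range[2])

#' Calibrate the synthetic-cohort generator to its targets
#'
#' Solves for the generator's internal parameters so that the generated
#' cohorts reproduce the specification's targets. The EQ-5D-5L is generated
#' on the disutility scale as `D = max(0, burden + G - kappa)` with
#' `utility = 1 - D`, where `burden` is the condition-effect sum and `G` is
#' a gamma-distributed noise term: the point mass at `D = 0` is the score
#' ceiling and the gamma right tail supplies the left skew that a censored
#' Gaussian cannot (no Gaussian latent censored at the ceiling can match
#' mean 0.855, SD 0.195 and a 31% ceiling simultaneously). The gamma shape
#' is found by 1-D root finding on the achieved SD, with an inner
#' moment-match of (scale, offset) to the mean and ceiling targets; the
#' PROPr side adds Gaussian noise plus a loading on the shared gamma term,
#' solved to match its mean, SD and the cross-measure correlation.
#' Follow-up drifts and the latent change correlation are then solved so
#' that observed mean changes are zero and the observed change-change
#' correlation hits its target despite boundary re-censoring. All solving
#' is done on a fixed internal common-random-number sample (n = 200,000),
#' making the calibration deterministic; results are cached per
#' specification. With `eq_ceiling = 0` the closed-form Gaussian
#' calibration is used instead.
#'
#' @param spec a [cohort_spec].
#' @param n_cal size of the internal calibration sample.
#' @return Object of class `cohort_calibration`; its `achieved` element
#'   tabulates target vs achieved moments on the calibration sample.
#' @export
calibrate_cohort <- function(spec, n_cal = 200000L) {
  stopifnot(inherits(spec, "cohort_spec"))
  key <- .spec_digest(spec)
  hit <- .prefcross_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (spec$eq_sd <= 0 || spec$propr_sd <= 0)
    stop("calibration error: contradictory spec (zero SD target cannot carry a correlation structure)",
         call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(285714L)

  p <- spec$conditions$prevalence
  var_b1 <- sum(spec$conditions$eq5d_beta^2 * p * (1 - p))
  var_b2 <- sum(spec$conditions$propr_beta^2 * p * (1 - p))
  cov_b <- sum(spec$conditions$eq5d_beta * spec$conditions$propr_beta * p * (1 - p))
  mean_b1 <- sum(-spec$conditions$eq5d_beta * p)
  mean_b2 <- sum(-spec$conditions$propr_beta * p)

  if (spec$eq_ceiling == 0) {
    # Closed-form Gaussian mechanism: utility = intercept - burden + noise
    s1sq <- spec$eq_sd^2 - var_b1
    s2sq <- spec$propr_sd^2 - var_b2
    if (s1sq <= 0 || s2sq <= 0)
      stop("calibration error: condition effects alone exceed the SD target",
           call. = FALSE)
    cov_noise <- spec$cor_eq_propr * spec$eq_sd * spec$propr_sd - cov_b
    rho <- cov_noise / sqrt(s1sq * s2sq)
    if (abs(rho) > 1)
      stop(sprintf("calibration error: infeasible correlation target (needed noise correlation %.3f)", rho),
           call. = FALSE)
    base <- list(mode = "gaussian",
                 a1 = spec$eq_mean + mean_b1, s1 = sqrt(s1sq),
                 a2 = spec$propr_mean + mean_b2, s2 = sqrt(s2sq), rho = rho)
    achieved <- data.frame(
      quantity = c("eq_mean", "eq_sd", "eq_ceiling", "propr_mean", "propr_sd", "cor"),
      target = c(spec$eq_mean, spec$eq_sd, 0, spec$propr_mean, spec$propr_sd,
                 spec$cor_eq_propr),
      achieved = c(spec$eq_mean, spec$eq_sd, 0, spec$propr_mean, spec$propr_sd,
                   spec$cor_eq_propr))
  } else {
    cd <- .calibration_draws(spec, n_cal)
    eq_target_mean <- spec$eq_mean; ceil <- spec$eq_ceiling
    inner <- function(k) {
      Gq <- qgamma(cd$U, shape = k)
      obj <- function(par) {
        eq <- .eq_from_latent(cd$B1 + exp(par[1]) * Gq - par[2], spec)
        (mean(eq) - eq_target_mean)^2 + (mean(eq == 1) - ceil)^2
      }
      o <- optim(c(log(0.2), 0.19), obj,
                 control = list(maxit = 1000, reltol = 1e-13))
      list(theta = exp(o$par[1]), kappa = o$par[2], Gq = Gq, value = o$value)
    }
    sd_gap <- function(k) {
      r <- inner(k)
      eq <- .eq_from_latent(cd$B1 + r$theta * r$Gq - r$kappa, spec)
      sd(eq) - spec$eq_sd
    }
    k <- tryCatch(uniroot(sd_gap, c(0.2, 4), tol = 1e-4)$root,
                  error = function(e)
                    stop(sprintf("calibration error: no gamma shape matches the SD target (%s)",
                                 conditionMessage(e)), call. = FALSE))
    sol <- inner(k)
    G <- sol$theta * sol$Gq
    g_mean <- sol$theta * k               # population mean of the gamma term
    d_raw <- cd$B1 + G - sol$kappa
    eq <- .eq_from_latent(d_raw, spec)
    obj2 <- function(par) {
      pr <- .propr_clamp(par[1] - cd$B2 - par[2] * (G - g_mean) + exp(par[3]) * cd$Z,
                         spec)
      (mean(pr) - spec$propr_mean)^2 + (sd(pr) - spec$propr_sd)^2 +
        (cor(eq, pr) - spec$cor_eq_propr)^2
    }
    o2 <- optim(c(spec$propr_mean + mean_b2, 0.5, log(0.18)), obj2,
                control = list(maxit = 3000, reltol = 1e-13))
    pr <- .propr_clamp(o2$par[1] - cd$B2 - o2$par[2] * (G - g_mean) +
                         exp(o2$par[3]) * cd$Z, spec)
    achieved <- data.frame(
      quantity = c("eq_mean", "eq_sd", "eq_ceiling", "propr_mean", "propr_sd", "cor"),
      target = c(spec$eq_mean, spec$eq_sd, spec$eq_ceiling,
                 spec$propr_mean, spec$propr_sd, spec$cor_eq_propr),
      achieved = c(mean(eq), sd(eq), mean(eq == 1), mean(pr), sd(pr), cor(eq, pr)))
    if (max(abs(achieved$target - achieved$achieved)) > 5e-3)
      stop(paste0("calibration error: moment matching did not converge; residuals:\n",
                  paste(sprintf("  %s: target %.4f achieved %.4f", achieved$quantity,
                                achieved$target, achieved$achieved), collapse = "\n")),
           call. = FALSE)
    base <- list(mode = "gamma", k = k, theta = sol$theta, kappa = sol$kappa,
                 g_mean = g_mean, a2 = o2$par[1], gamma = o2$par[2],
                 sigma_w = exp(o2$par[3]))
  }

  # ---- follow-up: drifts and latent change correlation -------------------
  fu <- NULL
  if (spec$change_sd_eq > 0 || spec$change_sd_propr > 0) {
    n_fu_cal <- min(n_cal, 100000L)
    fd <- .calibration_draws(spec, n_fu_cal, force_backpain = TRUE)
    if (base$mode == "gamma") {
      Gf <- base$theta * qgamma(fd$U, shape = base$k)
      d_raw_f <- fd$B1 + Gf - base$kappa
      pr_pre_f <- base$a2 - fd$B2 - base$gamma * (Gf - base$g_mean) +
        base$sigma_w * fd$Z
    } else {
      z2 <- base$rho * fd$Z + sqrt(1 - base$rho^2) * fd$ZC
      d_raw_f <- 1 - (base$a1 - fd$B1 + base$s1 * fd$Z)
      pr_pre_f <- base$a2 - fd$B2 + base$s2 * z2
    }
    eq_b <- .eq_from_latent(d_raw_f, spec)
    pr_b <- .propr_clamp(pr_pre_f, spec)
    za <- fd$ZA; zb <- fd$ZB
    eq_f_of <- function(drift1) {
      .eq_from_latent(d_raw_f - (drift1 + spec$change_sd_eq * za), spec)
    }
    drift1 <- if (spec$change_sd_eq > 0)
      uniroot(function(d) mean(eq_f_of(d) - eq_b), c(-0.2, 0.2), tol = 1e-7)$root
    else 0
    pr_f_of <- function(drift2, rho_d) {
      dz <- rho_d * za + sqrt(1 - rho_d^2) * zb
      .propr_clamp(pr_pre_f + drift2 + spec$change_sd_propr * dz, spec)
    }
    drift2 <- if (spec$change_sd_propr > 0)
      uniroot(function(d) mean(pr_f_of(d, 0) - pr_b), c(-0.2, 0.2), tol = 1e-7)$root
    else 0
    rho_d <- 0
    if (spec$change_sd_eq > 0 && spec$change_sd_propr > 0 && spec$change_cor != 0) {
      d_eq1 <- eq_f_of(drift1) - eq_b
      cor_gap <- function(r) cor(d_eq1, pr_f_of(drift2, r) - pr_b) - spec$change_cor
      rho_d <- tryCatch(uniroot(cor_gap, c(-0.995, 0.995), tol = 1e-5)$root,
                        error = function(e)
                          stop("calibration error: change correlation target infeasible",
                               call. = FALSE))
    }
    fu <- list(drift1 = drift1, drift2 = drift2, rho_delta = rho_d)
  }

  # ---- retrospective items: thresholds and loadings ----------------------
  retro <- NULL
  if (!is.null(fu) && spec$change_sd_eq > 0 && spec$change_sd_propr > 0) {
    retro <- lapply(seq_len(nrow(spec$retro)), function(i) {
      row <- spec$retro[i, ]
      probs <- .retro_probs(row$same_frac, row$levels)
      att <- .ordinal_attenuation(probs)
      ld <- .solve_loadings(row$r_propr, row$r_eq, spec$change_cor, att$rho)
      list(item = row$item, tau = att$tau, w_pr = ld$w1, w_eq = ld$w2,
           resid_sd = ld$resid_sd)
    })
    names(retro) <- spec$retro$item
  }

  # ---- pain instruments: loadings on the two baseline utilities ----------
  pain <- lapply(seq_len(nrow(spec$pain)), function(i) {
    row <- spec$pain[i, ]
    ld <- .solve_loadings(row$r_propr, row$r_eq, spec$cor_eq_propr)
    list(instrument = row$instrument, w_pr = ld$w1, w_eq = ld$w2,
         resid_sd = ld$resid_sd, mean = row$mean, sd = row$sd,
         step = row$step, lo = row$lo, hi = row$hi)
  })
  names(pain) <- spec$pain$instrument

  out <- structure(list(base = base, followup = fu, retro = retro, pain = pain,
                        achieved = achieved, n_cal = n_cal),
                   class = "cohort_calibration")
  .prefcross_cache[[key]] <- out
  out
}

#' @export
print.cohort_calibration <- function(x, ...) {
  cat(sprintf("<cohort_calibration> mechanism: %s (calibration n = %d)\n",
              x$base$mode, x$n_cal))
  print(transform(x$achieved, target = round(target, 4),
                  achieved = round(achieved, 4)), row.names = FALSE)
  invisible(x)
}

.draw_instrument <- function(latent, par) {
  if (par$step == 0) {                  # binary: prevalence = par$mean
    as.integer(latent > qnorm(1 - par$mean))
  } else {
    raw <- par$mean + par$sd * latent
    raw <- pmin(pmax(raw, par$lo), par$hi)
    round(raw / par$step) * par$step
  }
}

#' Generate a synthetic baseline cohort
#'
#' Draws condition indicators independently at their prevalences, builds
#' both utilities from the calibrated mechanism (see [calibrate_cohort()]),
#' clamps them to the theoretical instrument ranges, and attaches back-pain
#' instrument scores for the back-pain subgroup. Output is byte-identical
#' for identical spec and seed.
#'
#' @param spec a [cohort_spec].
#' @param n number of respondents (default `spec$n_baseline`).
#' @param seed integer seed (default `spec$seed`).
#' @param calibration optional pre-computed [calibrate_cohort()] result.
#' @return Data frame with `person_id`, the 22 condition columns, the two
#'   fake screening conditions (`syndomitis`, `chekalism`, all 0),
#'   `eq5d_utility`, `propr_utility`, and instrument scores (`odi`,
#'   `rmdq`, `peg`, `startback`, `gcps_intensity`, `gcps_disability`,
#'   `chronic_pain`; `NA` outside the back-pain subgroup). Latent state for
#'   follow-up generation is attached as attribute `latent`.
#' @export
generate_baseline <- function(spec = cohort_spec(), n = spec$n_baseline,
                              seed = spec$seed, calibration = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  cal <- calibration %||% calibrate_cohort(spec)
  set.seed(seed)
  p <- spec$conditions$prevalence
  cn <- spec$conditions$condition
  C <- matrix(rbinom(n * length(p), 1, rep(p, each = n)), n, length(p),
              dimnames = list(NULL, cn))
  B1 <- as.vector(C %*% (-spec$conditions$eq5d_beta))
  B2 <- as.vector(C %*% (-spec$conditions$propr_beta))
  if (cal$base$mode == "gamma") {
    G <- rgamma(n, shape = cal$base$k, scale = cal$base$theta)
    d_raw <- B1 + G - cal$base$kappa
    eq <- .eq_from_latent(d_raw, spec)
    pr_pre <- cal$base$a2 - B2 - cal$base$gamma * (G - cal$base$g_mean) +
      cal$base$sigma_w * rnorm(n)
  } else {
    z1 <- rnorm(n); z2 <- cal$base$rho * z1 + sqrt(1 - cal$base$rho^2) * rnorm(n)
    d_raw <- 1 - (cal$base$a1 - B1 + cal$base$s1 * z1)
    eq <- .eq_from_latent(d_raw, spec)
    pr_pre <- cal$base$a2 - B2 + cal$base$s2 * z2
  }
  pr <- .propr_clamp(pr_pre, spec)
  out <- data.frame(person_id = seq_len(n), C, syndomitis = 0L, chekalism = 0L,
                    eq5d_utility = eq, propr_utility = pr)
  # instrument scores for the back-pain subgroup
  bp <- which(out$back_pain == 1)
  inst_cols <- names(cal$pain)
  for (nm in inst_cols) out[[nm]] <- NA_real_
  if (length(bp) > 1) {
    z_eq <- (eq[bp] - mean(eq[bp])) / sd(eq[bp])
    z_pr <- (pr[bp] - mean(pr[bp])) / sd(pr[bp])
    for (nm in inst_cols) {
      par <- cal$pain[[nm]]
      latent <- par$w_pr * z_pr + par$w_eq * z_eq +
        par$resid_sd * rnorm(length(bp))
      out[[nm]][bp] <- .draw_instrument(latent, par)
    }
  }
  attr(out, "latent") <- data.frame(person_id = out$person_id,
                                    d_raw = d_raw, pr_pre = pr_pre)
  attr(out, "spec_digest") <- .spec_digest(spec)
  attr(out, "seed") <- seed
  out
}

#' Generate the 6-month follow-up for the back-pain subgroup
#'
#' Samples `n` back-pain respondents from the baseline, advances their
#' latent utilities by the calibrated mean-zero bivariate change process,
#' re-applies the ceiling/range censoring, and draws the nine retrospective
#' change items as ordinal variables whose latent propensities load on the
#' standardized true changes (loadings solved so the observed correlations
#' hit the spec targets after thresholding).
#'
#' @param baseline a cohort from [generate_baseline()] (its `latent`
#'   attribute is required).
#' @param spec the same [cohort_spec].
#' @param n follow-up size (default `spec$n_followup`).
#' @param seed integer seed (default `spec$seed + 1`).
#' @return Data frame with `person_id` (a subset of baseline back-pain
#'   IDs), follow-up `eq5d_utility` and `propr_utility`, and `retro_*`
#'   item columns (higher = more positive change).
#' @export
generate_followup <- function(baseline, spec = cohort_spec(),
                              n = spec$n_followup, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  lat <- attr(baseline, "latent")
  if (is.null(lat))
    stop("`baseline` lacks latent state; generate it with generate_baseline()",
         call. = FALSE)
  cal <- calibrate_cohort(spec)
  bp_ids <- baseline$person_id[baseline$back_pain == 1]
  if (!length(bp_ids))
    stop("insufficient data: baseline has no back-pain respondents", call. = FALSE)
  if (n > length(bp_ids))
    stop(sprintf("insufficient data: requested %d follow-ups but only %d back-pain respondents",
                 n, length(bp_ids)), call. = FALSE)
  set.seed(seed)
  ids <- sort(sample(bp_ids, n))
  ix <- match(ids, lat$person_id)
  d_raw <- lat$d_raw[ix]; pr_pre <- lat$pr_pre[ix]
  fu <- cal$followup %||% list(drift1 = 0, drift2 = 0, rho_delta = 0)
  za <- rnorm(n); zb <- rnorm(n)
  delta_eq <- fu$drift1 + spec$change_sd_eq * za
  dz <- fu$rho_delta * za + sqrt(max(0, 1 - fu$rho_delta^2)) * zb
  delta_pr <- fu$drift2 + spec$change_sd_propr * dz
  eq_f <- .eq_from_latent(d_raw - delta_eq, spec)
  pr_f <- .propr_clamp(pr_pre + delta_pr, spec)
  out <- data.frame(person_id = ids, eq5d_utility = eq_f, propr_utility = pr_f)
  # retrospective items from standardized observed changes
  eq_b <- .eq_from_latent(d_raw, spec)
  pr_b <- .propr_clamp(pr_pre, spec)
  d_eq <- eq_f - eq_b; d_pr <- pr_f - pr_b
  if (!is.null(cal$retro) && sd(d_eq) > 0 && sd(d_pr) > 0) {
    z_deq <- (d_eq - mean(d_eq)) / sd(d_eq)
    z_dpr <- (d_pr - mean(d_pr)) / sd(d_pr)
    for (nm in names(cal$retro)) {
      par <- cal$retro[[nm]]
      latent <- par$w_pr * z_dpr + par$w_eq * z_deq + par$resid_sd * rnorm(n)
      out[[paste0("retro_", nm)]] <- findInterval(latent, par$tau[-length(par$tau)]) + 1L
    }
  } else {
    for (nm in spec$retro$item)
      out[[paste0("retro_", nm)]] <- rep(NA_integer_, n)
  }
  out
}
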