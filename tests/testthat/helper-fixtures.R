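# Shared fixtures, built in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bivariate normal pairs with given moments. With exact = TRUE the sample
# moments (mean, n-1 SD, correlation) are imposed exactly by
# orthogonalization, so moment-determined statistics become deterministic.
make_mvn_pairs <- function(n, m1 = 0.855, m2 = 0.539, s1 = 0.195, s2 = 0.249,
                           r = 0.69, seed = 1, exact = FALSE) {
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  if (exact) {
    z1 <- (z1 - mean(z1)) / sd(z1)
    e <- z2 - mean(z2)
    e <- e - z1 * sum(e * z1) / sum(z1^2)   # orthogonal to z1, mean 0
    e <- e / sd(e)
    z2 <- r * z1 + sqrt(1 - r^2) * e
  } else {
    z2 <- r * z1 + sqrt(1 - r^2) * z2
  }
  data.frame(x = m1 + s1 * z1, y = m2 + s2 * z2)
}

# Small additive value-set fixture: item i, level l decrement = w_i * (l-1)
make_fixture_value_set <- function(weights = c(0.10, 0.05, 0.15, 0.20, 0.08)) {
  items <- c("mobility", "self_care", "usual_activities",
             "pain_discomfort", "anxiety_depression")
  df <- expand.grid(level = 1:5, item = items, stringsAsFactors = FALSE)
  df$decrement <- rep(weights, each = 5) * (df$level - 1)
  value_set_table(df[, c("item", "level", "decrement")], instrument = "fixture")
}

# Two-domain toy MAUT spec with identity disutility curves on [0, 1]
make_toy_maut <- function(wa = 0.7, wb = 0.6, ub = 1, uw = 0) {
  knots <- data.frame(domain = rep(c("a", "b"), each = 2),
                      score = c(0, 1, 0, 1), disutility = c(0, 1, 0, 1))
  maut_spec(knots, weights = c(a = wa, b = wb), util_best = ub, util_worst = uw,
            instrument = "toy")
}

# Independent two-way ANOVA oracle via anova(lm(...)) on long data
aov_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(score = c(x, y), person = factor(rep(seq_len(n), 2)),
                  measure = factor(rep(1:2, each = n)))
  a <- anova(lm(score ~ person + measure, data = d))
  list(ms_between = a["person", "Mean Sq"],
       ms_time = a["measure", "Mean Sq"],
       ms_within = a["Residuals", "Mean Sq"])
}

# A small, non-degenerate cohort spec for linear-recovery tests: no score
# ceiling and targets far from the clamp bounds, so the generating model is
# exactly linear-Gaussian.
make_linear_spec <- function(...) {
  cohort_spec(eq_mean = 0.5, eq_sd = 0.16, propr_mean = 0.45, propr_sd = 0.17,
              cor_eq_propr = 0.6, eq_ceiling = 0, ...)
}
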