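test_that("OLS map on exact-moment study data reproduces the closed-form coefficients", {
  d <- make_mvn_pairs(20000, m1 = 0.539, m2 = 0.855, s1 = 0.249, s2 = 0.195,
                      r = 0.69, seed = 101, exact = TRUE)
  m <- fit_ols_map(d$x, d$y, "propr2eq5d")
  slope_cf <- 0.69 * 0.195 / 0.249
  intercept_cf <- 0.855 - slope_cf * 0.539
  expect_equal(m$slope, slope_cf, tolerance = 1e-10)       # 0.5404
  expect_equal(m$intercept, intercept_cf, tolerance = 1e-10)
  # within 0.005 of the published exact-data constants
  expect_lt(abs(m$slope - 0.543), 0.005)
  expect_lt(abs(m$intercept - 0.563), 0.005)
  expect_equal(m$target_mean, 0.855, tolerance = 1e-10)
  expect_equal(m$target_sd, 0.195, tolerance = 1e-10)
  # linearity: predicted-score SD = |slope| * SD(source)
  expect_equal(m$predicted_sd, abs(m$slope) * sd(d$x), tolerance = 1e-10)
})

test_that("mapping a score onto itself gives the identity with adjusted R^2 of 1", {
  x <- c(0.1, 0.3, 0.35, 0.6, 0.92)
  m <- fit_ols_map(x, x)
  expect_equal(m$slope, 1, tolerance = 1e-12)
  expect_equal(m$intercept, 0, tolerance = 1e-12)
  expect_equal(m$adj_r_squared, 1, tolerance = 1e-10)
  expect_error(fit_ols_map(rep(0.4, 5), x), "zero variance")
  expect_error(fit_ols_map(c(1, 2), c(1, 2)), "insufficient|complete pairs")
})

test_that("published crosswalk constants and the clamp worked example", {
  f <- published_crosswalk("propr2eq5d")
  b <- published_crosswalk("eq5d2propr")
  expect_equal(f$slope, 0.543)
  expect_equal(f$intercept, 0.563)
  expect_equal(b$slope, 0.885)
  expect_equal(b$intercept, -0.218)
  expect_equal(f$clamp, c(-0.573, 1))
  expect_equal(b$clamp, c(-0.022, 1))
  st <- apply_crosswalk(f, 0.954, value = "both")
  expect_equal(round(st$predicted, 3), 1.081)
  # equated value before clamping: 0.855 + (0.195/0.135)(1.081022 - 0.855)
  pre <- 0.855 + (0.195 / 0.135) * (st$predicted - 0.855)
  expect_equal(round(pre, 3), 1.181)
  expect_equal(st$equated, 1.000)
  expect_error(published_crosswalk("sideways"))
})

test_that("apply_crosswalk is predict -> equate -> clamp, monotone, moment-preserving", {
  d <- make_mvn_pairs(5000, m1 = 0.539, m2 = 0.855, s1 = 0.249, s2 = 0.195,
                      r = 0.69, seed = 111)
  m <- fit_ols_map(d$x, d$y, clamp = c(-0.573, 1))
  xs <- sort(runif(200, -0.022, 0.954))
  eq <- apply_crosswalk(m, xs)
  expect_true(all(diff(eq) >= -1e-12))                     # weak monotonicity
  expect_true(all(eq >= -0.573 & eq <= 1))
  # pre-clamp equated scores on the fitting sample carry exactly the target moments
  pred <- apply_crosswalk(m, d$x, value = "predicted")
  pre <- m$target_mean + (m$target_sd / m$predicted_sd) * (pred - m$target_mean)
  expect_equal(mean(pre), m$target_mean, tolerance = 1e-10)
  expect_equal(sd(pre), m$target_sd, tolerance = 1e-10)
  # identity equating when the model's targets equal the predicted moments
  m_id <- crosswalk_model("propr2eq5d", m$intercept, m$slope,
                          target_mean = mean(pred), target_sd = sd(pred),
                          predicted_sd = sd(pred), clamp = c(-10, 10))
  expect_equal(apply_crosswalk(m_id, d$x), pred, tolerance = 1e-10)
})

test_that("unit-interval transform maps extremes and inverts exactly", {
  x <- c(0.2, 0.5, 0.8, 1.4)
  ui <- to_unit_interval(x)
  expect_equal(ui$values[1], 0)
  expect_equal(ui$values[4], 1)
  expect_equal(to_unit_interval(c(0, 1, 2))$values[2], 0.5)
  expect_equal(from_unit_interval(ui$values, ui$transform), x, tolerance = 1e-12)
  expect_error(to_unit_interval(rep(0.3, 4)), "range is zero")
})

test_that("beta-family map recovers its own generating parameters", {
  set.seed(121)
  n <- 5000
  x <- rnorm(n)
  b0 <- 0.4; b1 <- 0.7; phi <- 25
  mu <- plogis(b0 + b1 * x)
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  y[1] <- 0; y[2] <- 1      # pin the observed range so the rescaling is identity
  fit <- fit_beta_binomial_map(x, y, mode = "beta")
  se <- sqrt(diag(vcov(fit$model)$cond))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - b0), 2 * se[1] + 0.02)
  expect_lt(abs(fit$coefficients[["x"]] - b1), 2 * se[2] + 0.02)
  # fitted conditional means track the truth on the original scale
  expect_lt(mean(abs(fit$fitted - mu)), 0.01)
  # integer-trials variant agrees closely with the continuous fit
  fit_bb <- fit_beta_binomial_map(x, y, mode = "betabinomial", trials = 100)
  expect_lt(abs(fit_bb$coefficients[["x"]] - fit$coefficients[["x"]]), 0.05)
})

test_that("beta map: flat relationships give near-zero slope; NMAE comparable to OLS", {
  set.seed(131)
  x <- rnorm(3000)
  y <- rbeta(3000, 5, 5)
  flat <- fit_beta_binomial_map(x, y)
  expect_lt(abs(flat$coefficients[["x"]]), 0.1)

  d <- make_mvn_pairs(20000, m1 = 0.539, m2 = 0.855, s1 = 0.249, s2 = 0.195,
                      r = 0.69, seed = 141)
  ols <- fit_ols_map(d$x, d$y)
  bet <- fit_beta_binomial_map(d$x, d$y)
  nmae_ols <- evaluate_map(ols, d$x, d$y)$nmae
  nmae_bet <- evaluate_map(bet, d$x, d$y)$nmae
  expect_lt(abs(nmae_ols - nmae_bet), 0.1)
})

test_that("map evaluation: perfect linear map scores perfectly; forward/backward slopes square to r^2", {
  x <- seq(0.1, 0.9, length.out = 50)
  y <- 0.2 + 0.7 * x
  m <- fit_ols_map(x, y)
  ev <- evaluate_map(m, x, y)
  expect_equal(ev$adj_r_squared, 1, tolerance = 1e-10)
  expect_equal(ev$pearson_r, 1, tolerance = 1e-10)
  expect_equal(ev$icc_random, 1, tolerance = 1e-8)
  expect_equal(ev$nmae, 0, tolerance = 1e-10)
  # mutual consistency of the two published models with a single correlation
  expect_lt(abs(0.543 * 0.885 - 0.69^2), 0.01)
})
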