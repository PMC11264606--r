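test_that("ANOVA decomposition matches the anova(lm()) oracle", {
  # 4-row worked pairs plus random small samples
  cases <- list(list(x = c(0.2, 0.5, 0.9, 1.0), y = c(0.1, 0.4, 0.5, 0.9)))
  set.seed(11)
  for (i in 1:5) cases[[length(cases) + 1]] <-
    list(x = rnorm(sample(3:9, 1)), y = NULL)
  for (cs in cases) {
    x <- cs$x
    y <- cs$y %||% (0.5 * x + rnorm(length(x), sd = 0.3))
    d <- anova_decompose(x, y)
    o <- aov_oracle(x, y)
    expect_equal(d$ms_between, o$ms_between, tolerance = 1e-10)
    expect_equal(d$ms_within, o$ms_within, tolerance = 1e-10)
    expect_equal(d$ms_time, o$ms_time, tolerance = 1e-10)
    # sums of squares conserved
    expect_equal(d$ss_total, d$ss_between + d$ss_within + d$ss_time,
                 tolerance = 1e-10)
  }
})

test_that("degenerate paired samples produce the documented mean squares", {
  x <- c(0.1, 0.4, 0.7, 0.9)
  d_id <- anova_decompose(x, x)              # identical columns
  expect_equal(d_id$ms_within, 0, tolerance = 1e-14)
  expect_equal(d_id$ms_time, 0, tolerance = 1e-14)
  expect_equal(icc_two_way_mixed(d_id), 1)
  expect_equal(icc_two_way_random(d_id), 1)

  n <- 6; c0 <- 0.3                           # constant columns differing by c
  d_c <- anova_decompose(rep(0.5, n), rep(0.5 + c0, n))
  expect_equal(d_c$ms_time, n * c0^2 / 2, tolerance = 1e-12)
  expect_equal(d_c$ms_between, 0, tolerance = 1e-12)
  expect_error(icc_two_way_mixed(d_c), "undefined")
  expect_error(anova_decompose(1, 2), "insufficient|at least")
})

test_that("the random-effects ICC matches the moment closed form on large samples", {
  d <- make_mvn_pairs(10000, seed = 21)
  icc <- icc_two_way_random(d$x, d$y)
  m1 <- mean(d$x); m2 <- mean(d$y); s1 <- sd(d$x); s2 <- sd(d$y)
  closed <- 2 * cor(d$x, d$y) * s1 * s2 / (s1^2 + s2^2 + (m1 - m2)^2)
  expect_equal(icc, closed, tolerance = 0.005)
})

test_that("mixed >= random when means differ; the two forms agree for equal means", {
  set.seed(31)
  for (i in 1:10) {
    n <- 500
    x <- rnorm(n); y <- 0.6 * x + rnorm(n, sd = 0.6) + runif(1, 0.2, 1)
    d <- anova_decompose(x, y)
    expect_gte(icc_two_way_mixed(d), icc_two_way_random(d))
  }
  d_eq <- make_mvn_pairs(20000, m1 = 0.5, m2 = 0.5, s1 = 0.2, s2 = 0.2,
                         r = 0.6, seed = 5, exact = TRUE)
  dd <- anova_decompose(d_eq$x, d_eq$y)
  expect_equal(icc_two_way_mixed(dd), icc_two_way_random(dd), tolerance = 1e-3)
})

test_that("independent columns give near-zero ICCs at large n", {
  set.seed(41)
  x <- rnorm(50000); y <- rnorm(50000)
  expect_lt(abs(icc_two_way_mixed(x, y)), 0.02)
  expect_lt(abs(icc_two_way_random(x, y)), 0.02)
})

test_that("NMAE matches hand computation and is scale invariant", {
  expect_equal(nmae(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 0)
  expect_equal(nmae(c(0, 2), c(1, 1)), 1 / sqrt(2), tolerance = 1e-12)
  set.seed(51)
  obs <- rnorm(50); pred <- obs + rnorm(50, sd = 0.4)
  expect_equal(nmae(obs, pred), nmae(3.7 * obs, 3.7 * pred), tolerance = 1e-12)
  expect_error(nmae(rep(1, 5), rnorm(5)), "zero SD")
})

test_that("Cohen d-to-r conversion reproduces the rule-of-thumb anchors", {
  expect_equal(round(cohen_d_to_r(0.5), 3), 0.243)
  expect_equal(round(cohen_d_to_r(0.8), 3), 0.371)
  expect_equal(round(cohen_d_to_r(0.2), 3), 0.100)
  expect_equal(cohen_d_to_r(0), 0)
  d <- seq(-3, 3, by = 0.25)
  expect_equal(cohen_d_to_r(-d), -cohen_d_to_r(d))   # odd in d
  expect_true(all(abs(cohen_d_to_r(d)) < 1))
  expect_error(cohen_d_to_r(NA), "finite")
})

test_that("correlation matrix: pairwise complete cases, p-values, degenerate flags", {
  set.seed(61)
  df <- data.frame(a = rnorm(40), b = rnorm(40))
  df$c <- -2 * df$a + 3            # exact linear, anti-monotone
  df$const <- 1
  df$b[1:4] <- NA
  cm <- correlation_matrix(df, c("a", "b", "c", "const"))
  expect_equal(cm$r["a", "a"], 1)
  expect_equal(cm$r["a", "c"], -1, tolerance = 1e-12)
  expect_true(cm$undefined["a", "const"])
  expect_true(is.na(cm$r["a", "const"]))
  expect_equal(cm$n["a", "b"], 36L)
  ct <- cor.test(df$a, df$b, use = "complete.obs")   # oracle for r and p
  expect_equal(cm$r["a", "b"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm$p["a", "b"], ct$p.value, tolerance = 1e-10)
})

test_that("agreement report aggregates the statistics consistently", {
  d <- make_mvn_pairs(2000, seed = 71)
  rep <- agreement_report(d$x, d$y, labels = c("EQ", "PROPr"))
  expect_equal(rep$pearson_r, cor(d$x, d$y))
  expect_equal(rep$mean_difference, mean(d$x) - mean(d$y))
  expect_equal(rep$icc_mixed, icc_two_way_mixed(d$x, d$y))
  expect_equal(rep$n, 2000L)
})
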