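test_that("EQ-5D-5L scoring matches anchor, published range and single decrements", {
  us <- eq5d5l_us()
  expect_equal(score_eq5d(c(1, 1, 1, 1, 1), us), 1)
  expect_equal(score_eq5d(c(5, 5, 5, 5, 5), us), -0.573, tolerance = 1e-12)
  expect_equal(us$minimum, -0.573)
  expect_equal(us$maximum, 1)
  fx <- make_fixture_value_set()
  expect_equal(score_eq5d(c(2, 1, 1, 1, 1), fx), 0.9)  # one 0.1 decrement
})

test_that("EQ-5D-5L scoring equals a brute-force lookup sum over all 3125 states", {
  fx <- make_fixture_value_set(c(0.07, 0.11, 0.05, 0.13, 0.09))
  states <- as.matrix(expand.grid(mobility = 1:5, self_care = 1:5,
                                  usual_activities = 1:5, pain_discomfort = 1:5,
                                  anxiety_depression = 1:5))
  # independent oracle: per-state loop over the raw decrement table
  lookup <- function(it, lv) {
    sub <- fx$decrements
    sub$decrement[sub$item == it & sub$level == lv]
  }
  expected <- apply(states, 1, function(s)
    fx$anchor - sum(mapply(lookup, colnames(states), s)))
  expect_equal(unname(score_eq5d(states, fx)), unname(expected), tolerance = 1e-12)
  expect_equal(min(expected), fx$minimum, tolerance = 1e-12)
})

test_that("worsening any single item never increases the EQ-5D-5L utility", {
  fx <- make_fixture_value_set()
  set.seed(42)
  for (i in 1:50) {
    s <- sample(1:5, 5, replace = TRUE)
    item <- sample(1:5, 1)
    if (s[item] == 5) next
    worse <- s; worse[item] <- worse[item] + 1
    expect_lte(score_eq5d(worse, fx), score_eq5d(s, fx))
  }
})

test_that("EQ-5D-5L scoring validates levels and rejects bad tables", {
  expect_error(score_eq5d(c(0, 1, 1, 1, 1)), "1\\.\\.5")
  expect_error(score_eq5d(c(1, 1, 6, 1, 1)), "1\\.\\.5")
  expect_error(score_eq5d(c(1.5, 1, 1, 1, 1)), "integer")
  bad <- data.frame(item = "mobility", level = 1:4, decrement = c(0, 1, 2, 3) / 10)
  expect_error(value_set_table(bad), "levels 1\\.\\.5")
  bad2 <- make_fixture_value_set()$decrements
  bad2$decrement[bad2$level == 1] <- 0.01
  expect_error(value_set_table(bad2), "level-1 decrement")
})

test_that("PROPr scoring attains the published extremes at all-best / all-worst", {
  sp <- propr_us_synthetic()
  best <- vapply(sp$domains, function(d) {
    cv <- sp$curves[[d]]; cv$score[which.min(cv$disutility)]
  }, numeric(1))
  worst <- vapply(sp$domains, function(d) {
    cv <- sp$curves[[d]]; cv$score[which.max(cv$disutility)]
  }, numeric(1))
  expect_equal(score_propr(best, sp), 0.954, tolerance = 1e-9)
  expect_equal(score_propr(worst, sp), -0.022, tolerance = 1e-9)
  # interior profiles stay inside the declared range
  set.seed(3)
  prof <- sapply(seq_along(best), function(j)
    runif(40, min(best[j], worst[j]), max(best[j], worst[j])))
  colnames(prof) <- sp$domains
  u <- score_propr(prof, sp)
  expect_true(all(u >= sp$minimum - 1e-12 & u <= sp$maximum + 1e-12))
})

test_that("two-domain toy spec matches the hand-expanded multiplicative form", {
  toy <- make_toy_maut(0.7, 0.6)
  expect_equal(toy$scale_c, -5 / 7, tolerance = 1e-10)
  # (1 + C a x1)(1 + C b x2) expands to C(a x1 + b x2 + C a b x1 x2) + 1,
  # so the aggregate disutility is a x1 + b x2 + C a b x1 x2
  for (x in list(c(0, 0), c(1, 1), c(0.5, 0.25), c(0.2, 0.9))) {
    expected_du <- 0.7 * x[1] + 0.6 * x[2] + (-5 / 7) * 0.42 * x[1] * x[2]
    expect_equal(score_propr(x, toy), 1 - expected_du, tolerance = 1e-12)
  }
  expect_error(score_propr(c(0.5, NA), toy), "finite")
})

test_that("value-set files round-trip and malformed files are configuration errors", {
  fx <- make_fixture_value_set()
  path <- tempfile(fileext = ".csv")
  write_value_set(fx, path)
  back <- read_value_set(path)
  expect_equal(back$decrements$decrement, fx$decrements$decrement)
  expect_equal(back$anchor, fx$anchor)
  expect_equal(back$minimum, fx$minimum)

  sp <- make_toy_maut()
  path2 <- tempfile(fileext = ".csv")
  write_value_set(sp, path2)
  back2 <- read_value_set(path2)
  expect_equal(back2$weights, sp$weights)
  expect_equal(back2$scale_c, sp$scale_c, tolerance = 1e-10)
  expect_equal(score_propr(c(0.3, 0.8), back2), score_propr(c(0.3, 0.8), sp),
               tolerance = 1e-10)

  # truncated / header-less file
  trunc <- tempfile(fileext = ".csv")
  writeLines(c("# anchor=1", "item,level"), trunc)
  expect_error(read_value_set(trunc), "configuration error")
  expect_error(read_value_set(tempfile()), "not found")
})

test_that("score_utilities appends utility columns to a person-level table", {
  df <- data.frame(eq5d_mo = c(1, 2), eq5d_sc = c(1, 3), eq5d_ua = c(1, 1),
                   eq5d_pd = c(1, 4), eq5d_ad = c(1, 5))
  out <- score_utilities(df)
  expect_equal(out$eq5d_utility[1], 1)
  expect_equal(out$eq5d_utility[2],
               1 - (0.096 + 0.107 + 0 + 0.318 + 0.321), tolerance = 1e-12)
  expect_error(score_utilities(data.frame(a = 1)), "no scorable columns")
})
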