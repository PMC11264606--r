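test_that("default calibration hits the printed moments on its calibration sample", {
  spec <- cohort_spec()
  cal <- calibrate_cohort(spec)
  expect_equal(cal$base$mode, "gamma")
  res <- abs(cal$achieved$target - cal$achieved$achieved)
  expect_true(all(res < 0.005))
})

test_that("generation is deterministic and respects instrument ranges", {
  spec <- cohort_spec()
  b1 <- generate_baseline(spec, n = 3000, seed = 401)
  b2 <- generate_baseline(spec, n = 3000, seed = 401)
  expect_identical(b1, b2)
  b3 <- generate_baseline(spec, n = 3000, seed = 402)
  expect_false(identical(b1$eq5d_utility, b3$eq5d_utility))
  expect_true(all(b1$eq5d_utility >= spec$eq_range[1] &
                    b1$eq5d_utility <= spec$eq_range[2]))
  expect_true(all(b1$propr_utility >= spec$propr_range[1] &
                    b1$propr_utility <= spec$propr_range[2]))
  f1 <- generate_followup(b1, spec, n = 500, seed = 403)
  f2 <- generate_followup(b1, spec, n = 500, seed = 403)
  expect_identical(f1, f2)
  expect_true(all(f1$person_id %in% b1$person_id[b1$back_pain == 1]))
})

test_that("generated baseline moments converge to the targets with n", {
  spec <- cohort_spec()
  gap <- function(n, seed) {
    b <- generate_baseline(spec, n = n, seed = seed)
    c(mean = abs(mean(b$eq5d_utility) - spec$eq_mean),
      sd = abs(sd(b$eq5d_utility) - spec$eq_sd),
      ceil = abs(mean(b$eq5d_utility == 1) - spec$eq_ceiling),
      prm = abs(mean(b$propr_utility) - spec$propr_mean),
      cor = abs(cor(b$eq5d_utility, b$propr_utility) - spec$cor_eq_propr))
  }
  g_small <- gap(2000, 411)
  g_large <- gap(50000, 412)
  expect_true(all(g_large < c(0.006, 0.006, 0.012, 0.008, 0.02)))
  # rough O(n^-1/2) convergence: the large sample is at least as close overall
  expect_lt(sum(g_large), sum(g_small) + 0.01)
  # condition prevalences match their targets
  b <- generate_baseline(spec, n = 50000, seed = 412)
  prev_hat <- colMeans(b[, spec$conditions$condition])
  expect_lt(max(abs(prev_hat - spec$conditions$prevalence)), 0.01)
})

test_that("follow-up reproduces zero mean change and the change-change correlation", {
  spec <- cohort_spec()
  b <- generate_baseline(spec, n = 60000, seed = 421)
  f <- generate_followup(b, spec, n = 15000, seed = 422)
  cc <- change_correlations(b, f)
  expect_lt(abs(cc$mean_change["eq5d"]), 0.01)
  expect_lt(abs(cc$mean_change["propr"]), 0.01)
  expect_lt(abs(cc$change_change_r - spec$change_cor), 0.04)
  # retrospective items: small positive correlations near their targets
  expect_true(all(abs(cc$table$r_change_propr - spec$retro$r_propr) < 0.05))
  expect_true(all(abs(cc$table$r_change_eq5d - spec$retro$r_eq) < 0.05))
})

test_that("back-pain instrument scores carry the intended correlation structure", {
  spec <- cohort_spec()
  b <- generate_baseline(spec, n = 40000, seed = 431)
  bp <- b[b$back_pain == 1, ]
  expect_true(all(is.na(b$odi[b$back_pain == 0])))
  expect_true(all(bp$odi >= 0 & bp$odi <= 100))
  expect_true(all(bp$chronic_pain %in% c(0, 1)))
  for (inst in c("odi", "rmdq", "peg")) {
    tgt <- spec$pain$r_eq[spec$pain$instrument == inst]
    expect_lt(abs(cor(bp$eq5d_utility, bp[[inst]]) - tgt), 0.12)
    expect_lt(cor(bp$eq5d_utility, bp[[inst]]), 0)   # higher score = worse
  }
})

test_that("uncensored specs use the closed-form Gaussian calibration", {
  spec <- make_linear_spec()
  cal <- calibrate_cohort(spec)
  expect_equal(cal$base$mode, "gaussian")
  expect_true(all(abs(cal$achieved$target - cal$achieved$achieved) < 1e-6))
  b <- generate_baseline(spec, n = 50000, seed = 441)
  expect_lt(abs(mean(b$eq5d_utility) - spec$eq_mean), 0.005)
  expect_lt(abs(sd(b$eq5d_utility) - spec$eq_sd), 0.005)
  expect_lt(abs(cor(b$eq5d_utility, b$propr_utility) - spec$cor_eq_propr), 0.02)
  expect_lt(mean(b$eq5d_utility == 1), 0.001)
})

test_that("contradictory or degenerate specs fail with calibration errors", {
  expect_error(calibrate_cohort(cohort_spec(eq_sd = 0, cor_eq_propr = 0.5)),
               "calibration error")
  expect_error(cohort_spec(eq_ceiling = 1.5), "fractions")
  expect_error(cohort_spec(cor_eq_propr = 1.2), "correlation targets")
  # zero change SDs: follow-up changes collapse, retro correlations undefined
  spec0 <- cohort_spec(change_sd_eq = 0, change_sd_propr = 0)
  b <- generate_baseline(spec0, n = 4000, seed = 451)
  f <- generate_followup(b, spec0, n = 800, seed = 452)
  cc <- change_correlations(b, f)
  expect_true(is.na(cc$change_change_r))
  expect_true(all(is.na(cc$table$r_change_propr)))
})

test_that("follow-up demands baseline latent state and back-pain members", {
  spec <- cohort_spec()
  b <- generate_baseline(spec, n = 2000, seed = 461)
  plain <- b; attr(plain, "latent") <- NULL
  expect_error(generate_followup(plain, spec, n = 100), "latent")
  expect_error(generate_followup(b, spec, n = 10000), "insufficient")
})
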