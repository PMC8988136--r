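# Unit behaviour of the MR estimator battery against independent oracles
# and closed-form cases.

test_that("IVW equals the WLS-through-origin oracle", {
  for (seed in 1:5) {
    h <- simulate_mr_summary(J = sample(3:40, 1), theta = 0.6,
                             pleio_sd = 0.05, seed = seed)
    expect_equal(mr_ivw(h)$beta_hat, ivw_wls_oracle(h), tolerance = 1e-10)
  }
})

test_that("IVW closed-form cases: constant ratios and symmetry", {
  h <- make_h(beta_exp = c(0.1, 0.2, 0.4), beta_out = c(0.05, 0.1, 0.2))
  e <- mr_ivw(h)
  expect_equal(e$beta_hat, 0.5, tolerance = 1e-12)
  expect_equal(e$Q, 0, tolerance = 1e-12)
  expect_equal(e$se, e$se_fixed)       # Q = 0: no inflation
  # theta = (1, -1) with equal weights averages to zero
  h2 <- make_h(beta_exp = c(0.1, 0.1), beta_out = c(0.1, -0.1))
  expect_equal(mr_ivw(h2)$beta_hat, 0, tolerance = 1e-12)
  expect_error(mr_ivw(h2[1, ]), ">= 2")
})

test_that("multiplicative random-effects SE is never below fixed SE", {
  for (seed in 1:20) {
    h <- simulate_mr_summary(J = 10, pleio_sd = 0.08, seed = seed)
    e <- mr_ivw(h)
    expect_gte(e$se, e$se_fixed)
  }
})

test_that("mr_estimate invariants hold", {
  h <- simulate_mr_summary(J = 10, seed = 2)
  e <- mr_ivw(h)
  expect_lte(e$ci_low, e$beta_hat)
  expect_gte(e$ci_high, e$beta_hat)
  expect_equal(e$or_hat, exp(e$beta_hat), tolerance = 1e-12)
})

test_that("weighted median matches the brute-force oracle and cases", {
  h <- make_h(beta_exp = rep(0.1, 3), beta_out = c(0.01, 0.02, 0.09))
  # equal weights, theta = (0.1, 0.2, 0.9) -> 0.2
  expect_equal(mr_weighted_median(h, boot_reps = 100)$beta_hat, 0.2)
  hc <- make_h(beta_exp = c(0.1, 0.2, 0.3), beta_out = c(0.04, 0.08, 0.12))
  expect_equal(mr_weighted_median(hc, boot_reps = 100)$beta_hat, 0.4,
               tolerance = 1e-10)
  for (seed in 1:10) {
    h <- simulate_mr_summary(J = sample(3:25, 1), pleio_sd = 0.05,
                             seed = 100 + seed)
    r <- ratio_estimates(h)
    est <- mr_weighted_median(h, boot_reps = 100, seed = seed)$beta_hat
    expect_equal(est, weighted_median_oracle(r$theta, r$w),
                 tolerance = 1e-10)
    expect_gte(est, min(r$theta))       # always inside the ratio range
    expect_lte(est, max(r$theta))
  }
  expect_warning(mr_weighted_median(h, boot_reps = 50), "boot_reps")
  expect_error(mr_weighted_median(h[1:2, ]), ">= 3")
})

test_that("bootstrap SE is reproducible under a fixed seed", {
  h <- simulate_mr_summary(J = 12, seed = 5)
  expect_identical(mr_weighted_median(h, seed = 9)$se,
                   mr_weighted_median(h, seed = 9)$se)
})

test_that("Egger recovers an exact line and is orientation-invariant", {
  h <- make_h(beta_exp = c(0.1, 0.2, 0.3, 0.5),
              beta_out = 0.5 * c(0.1, 0.2, 0.3, 0.5))
  e <- mr_egger(h)
  expect_equal(e$beta_hat, 0.5, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0, tolerance = 1e-10)
  # flipping one variant's coding leaves the fit unchanged
  h2 <- simulate_mr_summary(J = 15, pleio_sd = 0.03, pleio_mean = 0.02,
                            seed = 3)
  e2 <- mr_egger(h2)
  h2f <- h2
  h2f$beta_exp[4] <- -h2f$beta_exp[4]
  h2f$beta_out[4] <- -h2f$beta_out[4]
  e2f <- mr_egger(h2f)
  expect_equal(e2f$beta_hat, e2$beta_hat, tolerance = 1e-12)
  expect_equal(e2f$egger_intercept, e2$egger_intercept, tolerance = 1e-12)
  # degenerate design rejected
  hd <- make_h(beta_exp = rep(0.1, 4), beta_out = c(0.1, 0.2, 0.1, 0.3))
  expect_error(mr_egger(hd), "degenerate")
})

test_that("RAPS reduces to IVW as exposure error vanishes and fits exact data", {
  h <- simulate_mr_summary(J = 20, se_exp = 1e-10, seed = 3)
  expect_lt(abs(mr_raps(h)$beta_hat - mr_ivw(h)$beta_hat), 1e-6)
  # exact proportionality: with negligible exposure error the profile
  # likelihood's mode is the common ratio
  hx <- make_h(beta_exp = c(0.1, 0.2, 0.4), beta_out = c(0.06, 0.12, 0.24),
               se_exp = 1e-8)
  expect_equal(mr_raps(hx)$beta_hat, 0.6, tolerance = 1e-6)
})

test_that("RAPS with overdispersion absorbs balanced pleiotropy", {
  h <- simulate_mr_summary(J = 40, theta = 0.6, pleio_sd = 0.1,
                           se_out = 0.05, seed = 11)
  e <- mr_raps(h, overdispersion = TRUE)
  expect_gt(e$tau2, 0)
  expect_lt(abs(e$beta_hat - 0.6), 0.15)
})

test_that("RAPS recovers the causal effect across seeds", {
  est <- sapply(1:20, function(s)
    mr_raps(simulate_mr_summary(J = 50, theta = 0.6, seed = 400 + s))$beta_hat)
  expect_lt(abs(mean(est) - 0.6), 0.05)
})

test_that("PRESSO leaves clean data alone and is seed-reproducible", {
  h <- simulate_mr_summary(J = 15, theta = 0.6, seed = 7)
  pr <- mr_presso(h, n_sim = 500, seed = 2)
  expect_length(pr$outliers, 0)
  expect_equal(pr$beta_hat, pr$raw$beta_hat)   # identical instrument set
  expect_gt(pr$global_p, 0)
  expect_lte(pr$global_p, 1)
  pr2 <- mr_presso(h, n_sim = 500, seed = 2)
  expect_identical(pr$global_p, pr2$global_p)
  expect_error(mr_presso(h, n_sim = 100), "n_sim")
  expect_error(mr_presso(h[1:3, ]), ">= 4")
})

test_that("PRESSO flags a planted pleiotropic outlier", {
  found <- sapply(1:20, function(s) {
    h <- simulate_mr_summary(J = 20, theta = 0.6, seed = 300 + s)
    h$beta_out[5] <- h$beta_out[5] + 10 * h$se_out[5]
    pr <- mr_presso(h, n_sim = 1000, seed = s)
    h$variant_id[5] %in% pr$outliers
  })
  expect_gte(mean(found), 0.95)
})

test_that("Steiger direction, ties and antisymmetry behave", {
  h <- simulate_mr_summary(J = 20, theta = 0, gamma_mean = 0.1, seed = 5)
  st <- mr_steiger(h)
  expect_true(st$direction)
  expect_lt(st$pvalue, 0.05)
  # swapping roles flips the direction
  hs <- h
  hs$beta_exp <- h$beta_out; hs$se_exp <- h$se_out
  hs$beta_out <- h$beta_exp; hs$se_out <- h$se_exp
  expect_false(mr_steiger(hs)$direction)
  # exact tie: direction FALSE, p = 1
  ht <- make_h(beta_exp = c(0.1, 0.2, 0.3), beta_out = c(0.1, 0.2, 0.3),
               se_exp = 0.05, se_out = 0.05)
  stt <- mr_steiger(ht)
  expect_false(stt$direction)
  expect_equal(stt$pvalue, 1)
})

test_that("leave-one-out returns J rows and spots the planted outlier", {
  h <- simulate_mr_summary(J = 12, theta = 0.6, seed = 9)
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), 12)
  # homogeneous ratios: every row equals the full estimate
  hh <- make_h(beta_exp = c(0.1, 0.2, 0.4), beta_out = c(0.05, 0.1, 0.2))
  looh <- mr_leave_one_out(hh)
  expect_true(all(abs(looh$beta - 0.5) < 1e-10))
  # excluding a planted outlier moves the estimate toward truth
  ho <- simulate_mr_summary(J = 20, theta = 0.6, se_out = 0.02, seed = 10)
  ho$beta_out[3] <- ho$beta_out[3] + 12 * ho$se_out[3]
  looo <- mr_leave_one_out(ho)
  full_dev <- abs(mr_ivw(ho)$beta_hat - 0.6)
  expect_lt(abs(looo$beta[3] - 0.6), full_dev)
})

test_that("single-instrument exposures fall back to a labeled Wald ratio", {
  h <- make_h(beta_exp = 0.2, beta_out = 0.1)
  e <- mr_wald_ratio(h)
  expect_equal(e$method, "wald_ratio")
  expect_equal(e$beta_hat, 0.5)
  expect_equal(e$se, 0.05 / 0.2)
  tab <- mr_battery(h)
  expect_equal(tab$method, "wald_ratio")
})

test_that("second-order ratio SEs are available behind a flag", {
  h <- make_h(beta_exp = 0.2, beta_out = 0.1)
  r1 <- ratio_estimates(h)
  r2 <- ratio_estimates(h, second_order = TRUE)
  expect_equal(r1$se_theta, 0.25)
  expect_gt(r2$se_theta, r1$se_theta)
})

test_that("power formula: null level, study design point, monotonicity", {
  expect_equal(mr_power_binary(1e5, 0.2, 0.04, 1), 0.05, tolerance = 1e-10)
  # study design: N = 159208 with 26676 cases, r2 = 0.041, OR = 1.86
  expect_gte(mr_power_binary(159208, 26676 / 159208, 0.041, 1.86), 0.99)
  expect_gt(mr_power_binary(2e4, 0.2, 0.04, 1.5),
            mr_power_binary(1e4, 0.2, 0.04, 1.5))
  expect_gt(mr_power_binary(1e4, 0.2, 0.04, 1.8),
            mr_power_binary(1e4, 0.2, 0.04, 1.5))
  # symmetric in the direction of effect
  expect_equal(mr_power_binary(1e4, 0.2, 0.04, 1.5),
               mr_power_binary(1e4, 0.2, 0.04, 1 / 1.5), tolerance = 1e-12)
})

test_that("the battery returns a study-shaped table", {
  h <- simulate_mr_summary(J = 20, theta = 0.6, seed = 21)
  tab <- mr_battery(h, seed = 3, boot_reps = 200, presso_n_sim = 500)
  expect_setequal(tab$method, c("ivw", "weighted_median", "egger", "raps",
                                "presso_raw", "presso_corrected"))
  expect_true(all(c("beta", "or", "se", "pvalue", "het_pvalue",
                    "intercept_pvalue", "steiger_pvalue", "significant")
                  %in% names(tab)))
  expect_true(tab$significant[tab$method == "ivw"])
})
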