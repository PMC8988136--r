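# Cross-trait stages: SHet meta-analysis, genome scan, LD-score
# genetic correlation, colocalization, TWAS statistic.

test_that("SHet reduces to z^2 for one trait and maximizes over subsets", {
  s1 <- shet(2.5, 1e5)
  expect_equal(s1$S_het, 6.25)
  expect_equal(s1$p, pchisq(6.25, 1, lower.tail = FALSE))
  # R = I, equal n: full-subset statistic is the sample-size-weighted
  # meta z, and the max dominates it
  z <- c(2, 1.2); n <- c(5e4, 5e4)
  s <- shet(z, n, n_mc = 2000, seed = 1)
  s_full <- sum(sqrt(n) * abs(z)) ^ 2 / sum(n)
  expect_gte(s$S_het + 1e-12, s_full)
  expect_equal(max(s$per_subset), s$S_het)
  expect_equal(unname(s$per_subset["1+2"]), s_full)
})

test_that("SHet is invariant to trait reordering and sign flips", {
  n <- c(1e5, 3e5)
  a <- shet(c(3.2, -1.4), n, n_mc = 2000, seed = 2)
  b <- shet(c(-1.4, 3.2), rev(n), n_mc = 2000, seed = 2)
  expect_equal(a$S_het, b$S_het, tolerance = 1e-12)
  c_ <- shet(c(-3.2, 1.4), n, n_mc = 2000, seed = 2)
  expect_equal(a$S_het, c_$S_het, tolerance = 1e-12)
})

test_that("SHet Monte-Carlo p is reproducible and in range", {
  z <- c(2.5, 2.1); n <- c(1e5, 2e5)
  p1 <- shet(z, n, n_mc = 5000, seed = 3)$p
  p2 <- shet(z, n, n_mc = 5000, seed = 3)$p
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lte(p1, 1)
  expect_error(shet(c(1, 1), n, R = matrix(1, 2, 2)), "singular")
})

test_that("SHet null rejection at 5% stays within the binomial band", {
  null <- shet_null(diag(2), c(1e5, 2e5), n_mc = 1e4, seed = 99)
  set.seed(42)
  rej <- replicate(2000, {
    shet(rnorm(2), c(1e5, 2e5), null = null)$p < 0.05
  })
  rate <- mean(rej)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("the strongest shared index variant clears genome-wide stringency", {
  # z-scores implied by the reported effects at the top shared locus
  # (T2D p = 1.5e-9, TV p = 3.6e-7; cohorts 159208 and 422218, R = I):
  # the meta p must beat 2.5e-8 (bound check; the tail is the fitted
  # gamma beyond Monte-Carlo resolution)
  z <- c(qnorm(1.5e-9 / 2, lower.tail = FALSE),
         qnorm(3.6e-7 / 2, lower.tail = FALSE))
  s <- shet(z, c(159208, 422218), n_mc = 5e4, seed = 10)
  expect_lt(s$p, 2.5e-8)
  expect_equal(s$tail, "gamma")
})

test_that("the cross-trait scan filter applies both thresholds", {
  cfg <- sim_config(M = 100, block_size = 10, h2_x = 0, h2_y = 0,
                    n_x = 1e5, n_y = 1e5, seed = 4)
  p <- make_ld_panel(cfg)
  sim <- simulate_pair_sumstats(p, cfg, mode = "zscore")
  x <- sim$x; y <- sim$y
  fix <- function(s, j, zval) {
    s$z[j] <- zval; s$beta[j] <- zval * s$se[j]
    s$pvalue[j] <- 2 * pnorm(-abs(zval)); s
  }
  # variant 5: hugely significant in x only (meta p tiny, y p ~ 1e-4)
  x <- fix(x, 5, 9); y <- fix(y, 5, 3.9)
  # variant 55: strong in both
  x <- fix(x, 55, 6); y <- fix(y, 55, 6)
  sc <- cross_trait_scan(x, y, p, n_mc = 5e4, seed = 5)
  expect_false("snp00005" %in% sc$hits$variant_id)  # y p above 1e-5
  expect_true("snp00055" %in% sc$hits$variant_id)
  expect_equal(sc$index$variant_id, "snp00055")
})

test_that("null scans yield at most an occasional index locus", {
  cfg0 <- function(seed) sim_config(M = 1000, block_size = 10, h2_x = 0,
                                    h2_y = 0, rg = 0, n_x = 2e5, n_y = 2e5,
                                    seed = seed)
  p <- make_ld_panel(cfg0(1))
  hits <- sum(sapply(1:20, function(s) {
    sim <- simulate_pair_sumstats(p, cfg0(600 + s), mode = "zscore")
    nrow(cross_trait_scan(sim$x, sim$y, p, n_mc = 2e4, seed = s)$index)
  }))
  expect_lte(hits, 1)
})

test_that("a planted shared causal locus is recovered in most seeds", {
  cfg0 <- function(seed) sim_config(M = 1000, block_size = 10, h2_x = 0,
                                    h2_y = 0, n_x = 2e5, n_y = 2e5,
                                    seed = seed)
  p <- make_ld_panel(cfg0(1))
  rec <- sapply(1:20, function(s) {
    sim <- simulate_pair_sumstats(p, cfg0(700 + s), mode = "zscore")
    x <- sim$x; y <- sim$y
    j <- 55
    for (nm in c("x", "y")) {
      ss <- get(nm)
      ss$z[j] <- 5.3; ss$beta[j] <- 5.3 * ss$se[j]
      ss$pvalue[j] <- 2 * pnorm(-5.3)
      assign(nm, ss)
    }
    sc <- cross_trait_scan(x, y, p, n_mc = 2e4, seed = s)
    blk <- p$map$block[match(sc$index$variant_id, p$map$variant_id)]
    any(blk == p$map$block[j])
  })
  expect_gte(mean(rec), 0.8)
})

test_that("genetic correlation of a trait with itself approaches 1", {
  cfg <- ldsc_panel_config(13, n_x = 1e5, n_y = 1e5)
  p <- make_ld_panel(cfg)
  sim <- simulate_pair_sumstats(p, cfg, mode = "zscore")
  r <- ldsc_rg(sim$x, sim$x, p)
  expect_lt(abs(r$rg - 1), 2 * r$rg_se + 1e-8)
  expect_error(ldsc_rg(sim$x[1:50, ], sim$y, p), ">= 200")
})

test_that("rg = 0 traits are recovered as null in most seeds", {
  p <- make_ld_panel(ldsc_panel_config(13))
  ok <- sapply(1:20, function(s) {
    sim <- simulate_pair_sumstats(p, ldsc_panel_config(800 + s, rg = 0),
                                  mode = "zscore")
    r <- ldsc_rg(sim$x, sim$y, p)
    !is.na(r$rg) && abs(r$rg) <= 2 * r$rg_se
  })
  expect_gte(mean(ok), 0.9)
})

test_that("rg is recovered at the study design point in most seeds", {
  # heritabilities 0.13 / 0.05, rg 0.26, cohorts 422218 / 159208
  p <- make_ld_panel(ldsc_panel_config(13))
  ok <- sapply(1:20, function(s) {
    sim <- simulate_pair_sumstats(p, ldsc_panel_config(100 + s),
                                  mode = "zscore")
    r <- ldsc_rg(sim$x, sim$y, p)
    !is.na(r$rg) && abs(r$rg - 0.26) <= 2 * r$rg_se
  })
  expect_gte(mean(ok), 0.9)
})

test_that("colocalization posteriors are a proper distribution", {
  M <- 100; se <- rep(0.02, M); ids <- sprintf("v%03d", 1:M)
  mk <- function(z) data.frame(variant_id = ids, beta = z * se, se = se)
  # all-null region: H0 dominates
  c0 <- coloc_abf(mk(rep(0, M)), mk(rep(0, M)))
  expect_equal(sum(c0$pp), 1, tolerance = 1e-10)
  expect_gt(c0$pp["PP0"], 0.95)
  # shared causal variant: H4 dominates
  set.seed(4)
  z1 <- rnorm(M, 0, 0.5); z2 <- rnorm(M, 0, 0.5)
  z1[10] <- 8; z2[10] <- 8
  c4 <- coloc_abf(mk(z1), mk(z2))
  expect_equal(sum(c4$pp), 1, tolerance = 1e-10)
  expect_gt(c4$pp["PP4"], 0.9)
  # distinct causal variants in linkage equilibrium: H3 dominates
  z3 <- rnorm(M, 0, 0.5); z4 <- rnorm(M, 0, 0.5)
  z3[10] <- 8; z4[80] <- 8
  c3 <- coloc_abf(mk(z3), mk(z4))
  expect_equal(which.max(c3$pp), c(PP3 = 4))
  expect_error(coloc_abf(mk(z1)[1:50, ], mk(z2)), "mismatch")
})

test_that("raising a shared signal never decreases PP4", {
  M <- 60; se <- rep(0.02, M); ids <- sprintf("v%03d", 1:M)
  set.seed(9)
  base <- rnorm(M, 0, 0.4)
  pp4 <- sapply(c(3, 5, 7, 9), function(zshare) {
    z <- base; z[30] <- zshare
    mk <- function(zz) data.frame(variant_id = ids, beta = zz * se, se = se)
    coloc_abf(mk(z), mk(z))$pp["PP4"]
  })
  expect_true(all(diff(pp4) >= -1e-12))
})

test_that("TWAS statistic reduces correctly and is calibrated", {
  # single-variant weight: z_twas equals that variant's z
  expect_equal(twas_assoc(c(1, 0, 0), c(2.5, 1, -1), diag(3))$z_twas, 2.5)
  # identity LD, normalized weights: z_twas = w'z
  w <- c(0.6, 0.8); z <- c(1, 2)
  expect_equal(twas_assoc(w, z, diag(2))$z_twas, sum(w * z))
  expect_error(twas_assoc(c(0, 0), z, diag(2)), "> 0")
  # null calibration and power under LD
  p <- make_ld_panel(sim_config(M = 200, block_size = 10, seed = 8))
  blk <- which(p$map$block == 3)
  Sg <- p$r[blk, blk]
  L <- chol(Sg)
  set.seed(11)
  w <- rnorm(10)
  lam <- 5 * drop(Sg %*% w) / sqrt(drop(crossprod(w, Sg %*% w)))
  res <- replicate(1000, {
    noise <- drop(crossprod(L, rnorm(10)))
    c(null = twas_assoc(w, noise, Sg)$pvalue < 0.05,
      alt = twas_assoc(w, lam + noise, Sg)$pvalue < 0.05)
  })
  expect_lt(abs(mean(res["null", ]) - 0.05), 0.02)
  expect_gt(mean(res["alt", ]), 0.8)
  # Bonferroni gate
  expect_false(twas_assoc(c(1, 0), c(3, 0), diag(2),
                          n_tests = 1000)$significant)
})
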