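## Synthetic GWAS generator: block-LD genotypes in disjoint cohorts,
## polygenic bivariate effect sizes, and a mediation DAG with a binary
## (liability-threshold) outcome. Everything is reproducible from one
## master seed; per-stage streams use fixed offsets.

#' Simulation configuration
#'
#' Holds the design of a synthetic two-sample GWAS study. Defaults mirror
#' the study conditions the package's analyses target: per-trait
#' heritabilities 0.13 and 0.05, genetic correlation 0.26, case fraction
#' 26676/159208 for the binary outcome, and mediation coefficients
#' a = 0.315, b = 0.581, c' = 0.446 (so the indirect effect a*b = 0.183
#' and the total effect c' + a*b = 0.629). Cohort sizes and variant counts
#' are desk-scale: 20,000 individuals per cohort and 2,000 variants in
#' LD blocks of 10 with within-block decay rho = 0.5.
#'
#' @param M number of variants.
#' @param block_size LD block size.
#' @param rho within-block adjacent-variant LD correlation, in \[0, 1).
#' @param h2_x,h2_y per-trait heritabilities in \[0, 1\].
#' @param rg genetic correlation of causal effects, |rg| <= 1.
#' @param n_x,n_y cohort sizes (disjoint cohorts by construction).
#' @param causal_frac fraction of variants carrying causal effects
#'   (1 = infinitesimal model).
#' @param a,b,c_prime mediation coefficients: exposure->mediator,
#'   mediator->outcome, and the direct exposure->outcome effect.
#' @param h2_med heritability of the mediator's own (direct) genetic
#'   component, independent of the exposure path.
#' @param K case fraction of the binary outcome.
#' @param maf_range range for per-block minor-allele frequencies.
#' @param seed master seed; all stages derive their streams from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(M = 2000, block_size = 10, rho = 0.5,
                       h2_x = 0.13, h2_y = 0.05, rg = 0.26,
                       n_x = 20000, n_y = 20000, causal_frac = 1,
                       a = 0.315, b = 0.581, c_prime = 0.446,
                       h2_med = 0.1, K = 26676 / 159208,
                       maf_range = c(0.1, 0.5), seed = 1) {
  stop_if(h2_x < 0 || h2_x > 1 || h2_y < 0 || h2_y > 1, "h2 must be in [0, 1]")
  stop_if(abs(rg) > 1, "|rg| must be <= 1")
  stop_if(any(rho < 0 | rho >= 1), "rho must be in [0, 1)")
  stop_if(causal_frac <= 0 || causal_frac > 1, "causal_frac must be in (0, 1]")
  structure(list(M = M, block_size = block_size, rho = rho,
                 h2_x = h2_x, h2_y = h2_y, rg = rg, n_x = n_x, n_y = n_y,
                 causal_frac = causal_frac, a = a, b = b, c_prime = c_prime,
                 h2_med = h2_med, K = K, maf_range = maf_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Haplotypes as binary Markov chains along each block: adjacent-site
## correlation rho, so corr(site j, site k) = rho^|j-k| exactly (binary
## chains have linear conditional expectations, correlations multiply).
## Genotype = sum of two independent haplotypes; E[g] = 2*maf.
simulate_genotypes <- function(panel, n, seed) {
  set.seed(seed)
  M <- panel$M
  G <- matrix(0L, n, M)
  blocks <- split(seq_len(M), panel$map$block)
  for (idx in blocks) {
    p <- panel$map$maf[idx[1]]
    rho <- panel$map$rho[idx[1]]
    for (h in 1:2) {
      prev <- as.integer(runif(n) < p)
      G[, idx[1]] <- G[, idx[1]] + prev
      for (k in idx[-1]) {
        prev <- as.integer(runif(n) < (p + rho * (prev - p)))
        G[, k] <- G[, k] + prev
      }
    }
  }
  G
}

## Marginal per-variant OLS of y on each genotype column (per-allele scale).
marginal_gwas <- function(G, y) {
  n <- length(y)
  gm <- colMeans(G)
  yc <- y - mean(y)
  Sxx <- colSums(G ^ 2) - n * gm ^ 2
  Sxy <- drop(crossprod(G, yc))
  beta <- Sxy / Sxx
  sse <- pmax(sum(yc ^ 2) - beta * Sxy, 0)
  se <- sqrt(sse / (n - 2) / Sxx)
  z <- beta / se
  data.frame(beta = beta, se = se, z = z,
             pvalue = 2 * pnorm(-abs(z)), eaf = gm / 2)
}

sumstats_from_marginal <- function(panel, mg, n, label, n_case = NULL,
                                   n_control = NULL) {
  df <- data.frame(
    variant_id = panel$map$variant_id, chrom = panel$map$chrom,
    pos = panel$map$pos, effect_allele = panel$map$effect_allele,
    other_allele = panel$map$other_allele,
    eaf = mg$eaf, beta = mg$beta, se = mg$se, pvalue = mg$pvalue, n = n,
    stringsAsFactors = FALSE
  )
  if (!is.null(n_case)) { df$n_case <- n_case; df$n_control <- n_control }
  sumstats(df, trait_label = label)
}

## Bivariate causal effects on the standardized-genotype scale.
draw_effects <- function(config, seed) {
  set.seed(seed)
  M <- config$M
  Mc <- max(1L, round(config$causal_frac * M))
  causal <- sort(sample.int(M, Mc))
  sx <- sqrt(config$h2_x / Mc); sy <- sqrt(config$h2_y / Mc)
  r <- config$rg
  z1 <- rnorm(Mc); z2 <- rnorm(Mc)
  bx <- sx * z1
  by <- sy * (r * z1 + sqrt(max(0, 1 - r ^ 2)) * z2)
  beta_x <- numeric(M); beta_y <- numeric(M)
  beta_x[causal] <- bx; beta_y[causal] <- by
  list(causal = causal, beta_x = beta_x, beta_y = beta_y)
}

scale_cols <- function(G) {
  s <- scale(G)
  s[, attr(s, "scaled:scale") == 0] <- 0
  s
}

#' Simulate two-sample GWAS summary statistics for a trait pair
#'
#' Draws causal effects for a shared causal set from a bivariate normal
#' with per-trait variance `h2/Mc` and covariance `rg*sqrt(h2_x*h2_y)/Mc`,
#' then either (mode `"individual"`) simulates genotypes for two disjoint
#' cohorts and computes per-variant marginal regressions, or (mode
#' `"zscore"`) draws marginal z-scores directly from their large-sample
#' distribution `z ~ MVN(sqrt(n) * Sigma beta, Sigma)` block-wise — the
#' fast path for LD-score-regression and meta-analysis calibration at
#' larger M.
#'
#' @param panel an [make_ld_panel()] panel (its `M`, blocks and MAFs are
#'   the variant universe).
#' @param config a [sim_config()].
#' @param mode `"individual"` (exact end-to-end, n <= ~30k) or `"zscore"`.
#' @param labels trait labels for the two summary-statistics sets.
#' @return list with `x`, `y` (two `sumstats`) and `truth` (per-variant
#'   true effects, causal set, realized heritabilities and effect-vector
#'   correlation, and the disjoint cohort index ranges).
#' @export
simulate_pair_sumstats <- function(panel, config,
                                   mode = c("individual", "zscore"),
                                   labels = c("trait_x", "trait_y")) {
  stopifnot(inherits(panel, "ld_panel"), inherits(config, "sim_config"))
  mode <- match.arg(mode)
  eff <- draw_effects(config, derive_seed(config$seed, 21L))

  if (mode == "individual") {
    stop_if(config$n_x < 50 || config$n_y < 50,
            "cohort size < 50: marginal regressions unstable, refusing")
    sim_one <- function(n, beta, h2, seed, label) {
      G <- simulate_genotypes(panel, n, seed)
      Xs <- scale_cols(G)
      gvals <- drop(Xs[, eff$causal, drop = FALSE] %*% beta[eff$causal])
      y <- gvals + rnorm(n, 0, sqrt(max(1e-12, 1 - h2)))
      mg <- marginal_gwas(G, y)
      list(ss = sumstats_from_marginal(panel, mg, n, label),
           realized_h2 = var(gvals) / var(y))
    }
    rx <- sim_one(config$n_x, eff$beta_x, config$h2_x,
                  derive_seed(config$seed, 22L), labels[1])
    ry <- sim_one(config$n_y, eff$beta_y, config$h2_y,
                  derive_seed(config$seed, 23L), labels[2])
    ss_x <- rx$ss; ss_y <- ry$ss
    h2x_real <- rx$realized_h2; h2y_real <- ry$realized_h2
  } else {
    zs <- simulate_zscores(panel, cbind(eff$beta_x, eff$beta_y),
                           c(config$n_x, config$n_y),
                           derive_seed(config$seed, 24L))
    mk <- function(z, n, label) {
      se <- rep(1 / sqrt(n), panel$M)
      mg <- data.frame(beta = z * se, se = se, z = z,
                       pvalue = 2 * pnorm(-abs(z)), eaf = panel$map$maf)
      sumstats_from_marginal(panel, mg, n, label)
    }
    ss_x <- mk(zs[, 1], config$n_x, labels[1])
    ss_y <- mk(zs[, 2], config$n_y, labels[2])
    h2x_real <- sum(eff$beta_x ^ 2); h2y_real <- sum(eff$beta_y ^ 2)
  }

  truth <- list(
    beta_x = eff$beta_x, beta_y = eff$beta_y, causal = eff$causal,
    realized_h2_x = h2x_real, realized_h2_y = h2y_real,
    realized_rg = if (length(eff$causal) > 1 &&
                        sd(eff$beta_x[eff$causal]) > 0 &&
                        sd(eff$beta_y[eff$causal]) > 0)
      cor(eff$beta_x[eff$causal], eff$beta_y[eff$causal]) else NA_real_,
    cohort_x = c(1L, config$n_x),
    cohort_y = c(config$n_x + 1L, config$n_x + config$n_y)
  )
  list(x = ss_x, y = ss_y, truth = truth)
}

## z ~ MVN(sqrt(n) * Sigma beta, Sigma), block-diagonal Sigma, independent
## noise across traits (non-overlapping cohorts).
simulate_zscores <- function(panel, beta_mat, n_vec, seed) {
  set.seed(seed)
  K <- ncol(beta_mat)
  Z <- matrix(0, panel$M, K)
  for (idx in split(seq_len(panel$M), panel$map$block)) {
    Rb <- panel$r[idx, idx, drop = FALSE]
    L <- chol(Rb)
    mu <- Rb %*% beta_mat[idx, , drop = FALSE]
    noise <- crossprod(L, matrix(rnorm(length(idx) * K), length(idx), K))
    Z[idx, ] <- mu %*% diag(sqrt(n_vec), K) + noise
  }
  Z
}

#' Simulate a three-cohort mediation study
#'
#' Structural model on standardized scales, with three disjoint cohorts
#' (exposure GWAS, mediator GWAS, outcome GWAS) drawn from the same LD
#' panel: `X = G gamma + e_x`; `Mdtr = a X + G delta + e_m`; liability
#' `L = c' X + b Mdtr + e_L` rescaled to unit variance and thresholded at
#' case fraction `K` to give the binary outcome. The outcome cohort's 0/1
#' marginal regressions are rescaled by `1/phi(qnorm(1-K))` so reported
#' effects are approximately on the liability scale (documented in the
#' methods vignette). The exposure's causal set carries `h2_x` via
#' `causal_frac`; the mediator receives an independent direct genetic
#' component with heritability `h2_med` on a disjoint causal set.
#'
#' @param panel an `ld_panel`.
#' @param config a [sim_config()]; uses `a`, `b`, `c_prime`, `h2_x`,
#'   `h2_med`, `K`, cohort sizes and `causal_frac`.
#' @return list with `exposure`, `mediator`, `outcome` (`sumstats`) and
#'   `truth` (gamma, delta, a, b, c', indirect `a*b`, total `c' + a*b`,
#'   cohort index ranges).
#' @export
simulate_mediation_sumstats <- function(panel, config) {
  stopifnot(inherits(panel, "ld_panel"), inherits(config, "sim_config"))
  stop_if(config$K <= 0 || config$K >= 1, "case fraction K must be in (0, 1)")
  stop_if(!all(is.finite(c(config$a, config$b, config$c_prime))),
          "mediation coefficients must be finite")
  stop_if(config$n_x < 50 || config$n_y < 50, "cohort size < 50, refusing")
  M <- panel$M
  a <- config$a; b <- config$b; cp <- config$c_prime; K <- config$K

  set.seed(derive_seed(config$seed, 31L))
  Mc <- max(1L, round(config$causal_frac * M))
  causal_x <- sort(sample.int(M, Mc))
  ## mediator's direct genetic component lives on LD blocks disjoint from
  ## the exposure's, so instruments for each trait tag a single path
  pool <- which(!(panel$map$block %in% panel$map$block[causal_x]))
  stop_if(length(pool) < 1,
          "no LD blocks left for the mediator's causal set; lower causal_frac")
  Mm <- max(1L, min(length(pool), Mc))
  causal_m <- sort(sample(pool, Mm))
  gamma <- numeric(M); delta <- numeric(M)
  gamma[causal_x] <- rnorm(Mc, 0, sqrt(config$h2_x / Mc))
  delta[causal_m] <- rnorm(Mm, 0, sqrt(config$h2_med / Mm))

  draw_cohort <- function(n, seed) {
    G <- simulate_genotypes(panel, n, seed)
    Xs <- scale_cols(G)
    x <- drop(Xs %*% gamma) + rnorm(n, 0, sqrt(max(1e-12, 1 - config$h2_x)))
    m_str <- a * x + drop(Xs %*% delta)
    m <- m_str + rnorm(n, 0, sqrt(max(0.02, 1 - var(m_str))))
    l_str <- cp * x + b * m
    l <- l_str + rnorm(n, 0, sqrt(max(0.02, 1 - var(l_str))))
    l <- l / sd(l)
    yb <- as.integer(l > quantile(l, 1 - K))
    list(G = G, x = x, m = m, yb = yb)
  }

  nx <- config$n_x; nm <- config$n_x; ny <- config$n_y
  cx <- draw_cohort(nx, derive_seed(config$seed, 32L))
  exposure <- sumstats_from_marginal(panel, marginal_gwas(cx$G, cx$x), nx,
                                     "exposure")
  rm(cx)
  cm <- draw_cohort(nm, derive_seed(config$seed, 33L))
  mediator <- sumstats_from_marginal(panel, marginal_gwas(cm$G, cm$m), nm,
                                     "mediator")
  rm(cm)
  cy <- draw_cohort(ny, derive_seed(config$seed, 34L))
  mg <- marginal_gwas(cy$G, cy$yb)
  liab <- dnorm(qnorm(1 - K))     # 0/1 slope -> liability-scale rescale
  mg$beta <- mg$beta / liab
  mg$se <- mg$se / liab
  n_case <- sum(cy$yb)
  outcome <- sumstats_from_marginal(panel, mg, ny, "outcome",
                                    n_case = n_case, n_control = ny - n_case)
  rm(cy)

  truth <- list(gamma = gamma, delta = delta, causal_x = causal_x,
                causal_m = causal_m, a = a, b = b, c_prime = cp,
                indirect = a * b, total = cp + a * b,
                cohort_exposure = c(1L, nx),
                cohort_mediator = c(nx + 1L, nx + nm),
                cohort_outcome = c(nx + nm + 1L, nx + nm + ny))
  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Simulate summary-level two-sample MR data
#'
#' Direct summary-level generator for estimator calibration: per-variant
#' true instrument effects `gamma_j`, observed exposure effects
#' `N(gamma_j, se_exp^2)`, observed outcome effects
#' `N(theta * gamma_j + alpha_j, se_out^2)` with optional directional or
#' balanced pleiotropy `alpha_j`.
#'
#' @param J number of instruments.
#' @param theta true causal effect.
#' @param gamma_mean,gamma_sd distribution of true instrument strengths.
#' @param se_exp,se_out per-variant standard errors (recycled).
#' @param pleio_sd SD of balanced pleiotropic effects (0 = none).
#' @param pleio_mean mean pleiotropic (directional) effect.
#' @param n_exp,n_out nominal sample sizes recorded in the output.
#' @param seed RNG seed.
#' @return a `harmonized_set` ready for the MR estimators, with the truth
#'   in attribute `truth`.
#' @export
simulate_mr_summary <- function(J = 50, theta = 0.6, gamma_mean = 0.08,
                                gamma_sd = 0.02, se_exp = 0.005,
                                se_out = 0.05, pleio_sd = 0, pleio_mean = 0,
                                n_exp = 20000, n_out = 20000, seed = 1) {
  set.seed(seed)
  gamma <- rnorm(J, gamma_mean, gamma_sd)
  se_exp <- rep_len(se_exp, J); se_out <- rep_len(se_out, J)
  alpha <- rnorm(J, pleio_mean, pleio_sd)
  bx <- rnorm(J, gamma, se_exp)
  by <- rnorm(J, theta * gamma + alpha, se_out)
  h <- data.frame(
    variant_id = sprintf("iv%03d", seq_len(J)),
    chrom = "1", pos = seq_len(J) * 1e6,
    effect_allele = "A", other_allele = "G",
    beta_exp = bx, se_exp = se_exp, f_exp = 0.3, n_exp = n_exp,
    beta_out = by, se_out = se_out, f_out = 0.3, n_out = n_out,
    pval_exp = 2 * pnorm(-abs(bx / se_exp)),
    pval_out = 2 * pnorm(-abs(by / se_out)),
    flipped = FALSE, stringsAsFactors = FALSE
  )
  structure(h, exposure_trait = "sim_exposure", outcome_trait = "sim_outcome",
            exclusion_log = data.frame(variant_id = character(0),
                                       reason = character(0)),
            truth = list(theta = theta, gamma = gamma, alpha = alpha),
            class = c("harmonized_set", "data.frame"))
}
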