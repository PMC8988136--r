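## Two-sample MR estimator battery. All estimators consume a
## `harmonized_set` (see harmonize()) and return an `mr_estimate`.
## Per-variant ratio estimates use first-order delta-method SEs by
## default (se_out / |beta_exp|); second-order available behind a flag.

#' Per-variant ratio (Wald) estimates
#'
#' @param h a `harmonized_set`.
#' @param second_order use second-order delta SEs
#'   `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#' @return data.frame with `variant_id`, `theta`, `se_theta`, `w = 1/se^2`.
#' @export
ratio_estimates <- function(h, second_order = FALSE) {
  stop_if(any(h$beta_exp == 0), "ratio undefined where beta_exp == 0")
  theta <- h$beta_out / h$beta_exp
  se <- if (second_order) {
    sqrt(h$se_out ^ 2 / h$beta_exp ^ 2 +
           h$beta_out ^ 2 * h$se_exp ^ 2 / h$beta_exp ^ 4)
  } else {
    h$se_out / abs(h$beta_exp)
  }
  data.frame(variant_id = h$variant_id, theta = theta, se_theta = se,
             w = 1 / se ^ 2, stringsAsFactors = FALSE)
}

new_mr_estimate <- function(method, beta_hat, se, n_snp, level = 0.95, ...) {
  zq <- qnorm(1 - (1 - level) / 2)
  z <- beta_hat / se
  out <- c(list(method = method, beta_hat = beta_hat, se = se,
                pvalue = 2 * pnorm(-abs(z)),
                ci_low = beta_hat - zq * se, ci_high = beta_hat + zq * se,
                or_hat = exp(beta_hat),
                or_ci_low = exp(beta_hat - zq * se),
                or_ci_high = exp(beta_hat + zq * se),
                n_snp = n_snp),
           list(...))
  structure(out, class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.4f (SE %.4f), OR = %.3f (%.3f, %.3f), p = %.3g, J = %d\n",
              x$method, x$beta_hat, x$se, x$or_hat, x$or_ci_low,
              x$or_ci_high, x$pvalue, x$n_snp))
  if (!is.null(x$Q)) cat(sprintf("  Q = %.3f (p = %.3g)\n", x$Q, x$Q_pvalue))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  intercept = %.4f (p = %.3g)\n", x$egger_intercept,
                x$intercept_pvalue))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta_hat,
             or = x$or_hat, ci_low = x$ci_low, ci_high = x$ci_high,
             or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high, se = x$se,
             pvalue = x$pvalue,
             het_pvalue = x$Q_pvalue %||% NA_real_,
             intercept_pvalue = x$intercept_pvalue %||% NA_real_,
             stringsAsFactors = FALSE)
}

#' Wald ratio estimate for a single instrument
#'
#' Fallback for single-instrument exposures, labeled distinctly.
#' @param h a `harmonized_set` with exactly one instrument.
#' @export
mr_wald_ratio <- function(h) {
  stop_if(nrow(h) != 1, "mr_wald_ratio requires exactly one instrument")
  r <- ratio_estimates(h)
  new_mr_estimate("wald_ratio", r$theta, r$se_theta, 1L)
}

#' Inverse-variance-weighted MR (multiplicative random effects)
#'
#' Weighted mean of per-variant ratios with weights `1/se_theta^2`:
#' `beta = sum(w theta) / sum(w)`, fixed-effect SE `(sum w)^-1/2`,
#' Cochran's `Q = sum w (theta - beta)^2`, and the multiplicative
#' random-effects SE `fixed SE * max(1, sqrt(Q / (J - 1)))` (never below
#' the fixed-effect SE). P-values are two-sided normal; the heterogeneity
#' p comes from a chi-square with J - 1 df.
#'
#' @param h a `harmonized_set` with at least 2 instruments.
#' @param random use the multiplicative random-effects SE (default).
#' @export
mr_ivw <- function(h, random = TRUE) {
  stop_if(nrow(h) < 2,
          "IVW requires >= 2 instruments; use mr_wald_ratio() for one")
  r <- ratio_estimates(h)
  sw <- sum(r$w)
  beta <- sum(r$w * r$theta) / sw
  se_fixed <- sqrt(1 / sw)
  Q <- sum(r$w * (r$theta - beta) ^ 2)
  J <- nrow(r)
  phi <- max(1, sqrt(Q / (J - 1)))
  se <- if (random) se_fixed * phi else se_fixed
  new_mr_estimate("ivw", beta, se, J,
                  Q = Q, Q_pvalue = pchisq(Q, J - 1, lower.tail = FALSE),
                  se_fixed = se_fixed)
}

## interpolated weighted median of theta with weights w
weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(theta[1])
  if (0.5 >= s[length(s)]) return(theta[length(theta)])
  approx(s, theta, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR
#'
#' Consistent when at least half the weight comes from valid instruments.
#' Point estimate by linear interpolation of the weighted empirical
#' quantile function at 0.5 with standardized cumulative weights
#' `(cumsum(w) - w/2) / sum(w)`; SE by seeded parametric bootstrap
#' (resampling `theta_j ~ N(theta_j, se_theta_j)`).
#'
#' @param h a `harmonized_set` with >= 3 instruments.
#' @param boot_reps bootstrap replicates (warning below 100).
#' @param seed bootstrap seed.
#' @export
mr_weighted_median <- function(h, boot_reps = 1000, seed = 1) {
  stop_if(nrow(h) < 3, "weighted median requires >= 3 instruments")
  if (boot_reps < 100)
    warning("boot_reps < 100: bootstrap SE will be unstable", call. = FALSE)
  r <- ratio_estimates(h)
  beta <- weighted_median_point(r$theta, r$w)
  set.seed(seed)
  J <- nrow(r)
  boots <- vapply(seq_len(boot_reps), function(i) {
    th <- rnorm(J, r$theta, r$se_theta)
    weighted_median_point(th, r$w)
  }, numeric(1))
  new_mr_estimate("weighted_median", beta, sd(boots), J)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`), after orienting every variant so
#' `beta_exp >= 0` (both signs flipped otherwise, so the fit is invariant
#' to allele recoding). The slope is the causal estimate; a non-zero
#' intercept indicates directional pleiotropy. SEs carry multiplicative
#' scale inflation floored at 1 (`max(1, sqrt(RSS_w / (J - 2)))`), normal
#' p-values by default (`use_t = TRUE` for t-distribution with J - 2 df).
#'
#' @param h a `harmonized_set` with >= 3 instruments.
#' @param use_t use t reference instead of normal.
#' @export
mr_egger <- function(h, use_t = FALSE) {
  stop_if(nrow(h) < 3, "Egger regression requires >= 3 instruments")
  s <- sign1(h$beta_exp)
  bx <- h$beta_exp * s
  by <- h$beta_out * s
  stop_if(max(bx) - min(bx) < .Machine$double.eps ^ 0.5 * max(abs(bx), 1),
          "degenerate design: all beta_exp equal")
  w <- 1 / h$se_out ^ 2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  infl <- max(1, sigma) / sigma
  est <- coef(sm)[, "Estimate"]
  se <- coef(sm)[, "Std. Error"] * infl
  J <- nrow(h)
  pfun <- if (use_t) function(z) 2 * pt(-abs(z), J - 2) else
    function(z) 2 * pnorm(-abs(z))
  Q <- sum(w * fit$residuals ^ 2)
  out <- new_mr_estimate("egger", unname(est["bx"]), unname(se["bx"]), J,
                  egger_intercept = unname(est["(Intercept)"]),
                  intercept_se = unname(se["(Intercept)"]),
                  intercept_pvalue = pfun(est["(Intercept)"] / se["(Intercept)"]),
                  Q = Q, Q_pvalue = pchisq(Q, J - 2, lower.tail = FALSE))
  out$pvalue <- pfun(out$beta_hat / out$se)
  out
}

huber_rho <- function(t, delta) {
  ifelse(abs(t) <= delta, t ^ 2 / 2, delta * abs(t) - delta ^ 2 / 2)
}

#' Robust adjusted profile score (RAPS) MR
#'
#' Maximizes the profile likelihood of the causal effect with standardized
#' residuals `t_j = (beta_out - theta beta_exp) / sqrt(se_out^2 +
#' theta^2 se_exp^2 + tau2)`; accounts for measurement error in the
#' exposure effects, so it stays unbiased with many weak instruments.
#' Optional Huber loss (`delta = 1.345`) gives robustness to idiosyncratic
#' pleiotropy; the overdispersion variance `tau2 >= 0` absorbs systematic
#' pleiotropy (the Huber consistency factor `2*Phi(delta) - 1` keeps its
#' estimate calibrated). Solved by bounded scalar optimization over
#' successively widened brackets (3 restarts); SE from a numeric sandwich
#' (observed information and score outer product).
#'
#' @param h a `harmonized_set` with >= 3 instruments.
#' @param loss `"plain"` or `"huber"`.
#' @param overdispersion estimate `tau2` (floored at 0)?
#' @param delta Huber threshold.
#' @export
mr_raps <- function(h, loss = c("plain", "huber"), overdispersion = FALSE,
                    delta = 1.345) {
  stop_if(nrow(h) < 3, "RAPS requires >= 3 instruments")
  loss <- match.arg(loss)
  bx <- h$beta_exp; by <- h$beta_out
  sx2 <- h$se_exp ^ 2; sy2 <- h$se_out ^ 2
  cdelta <- if (loss == "huber") 2 * pnorm(delta) - 1 else 1
  rho <- if (loss == "huber") function(t) huber_rho(t, delta) else
    function(t) t ^ 2 / 2

  obj_terms <- function(theta, tau2) {
    v <- sy2 + theta ^ 2 * sx2 + tau2
    rho((by - theta * bx) / sqrt(v)) + cdelta * log(v) / 2
  }
  obj <- function(theta, tau2) sum(obj_terms(theta, tau2))

  theta0 <- median(by / ifelse(bx == 0, .Machine$double.eps, bx))
  spread <- max(abs(theta0), mad(by / bx, constant = 1.4826), 1)
  best <- NULL
  for (mult in c(2, 10, 50)) {            # 3 restarts over widening brackets
    o <- optimize(function(t) obj(t, 0), theta0 + c(-1, 1) * mult * spread,
                  tol = 1e-10)
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  theta_hat <- best$minimum
  tau2 <- 0
  if (overdispersion) {
    resid_var <- var(by - theta_hat * bx)
    tau_max <- max(10 * median(sy2 + theta_hat ^ 2 * sx2),
                   2 * resid_var, 1e-8)
    prof <- function(tau2)
      optimize(function(t) obj(t, tau2),
               theta_hat + c(-1, 1) * 10 * spread, tol = 1e-9)$objective
    ot <- optimize(prof, c(0, tau_max), tol = 1e-9)
    tau2 <- max(0, ot$minimum)
    theta_hat <- optimize(function(t) obj(t, tau2),
                          theta_hat + c(-1, 1) * 10 * spread,
                          tol = 1e-10)$minimum
  }

  ## numeric sandwich: A = sum of curvatures, B = sum of squared scores
  eps <- 1e-5 * max(abs(theta_hat), 1)
  g_plus <- obj_terms(theta_hat + eps, tau2)
  g_minus <- obj_terms(theta_hat - eps, tau2)
  g_mid <- obj_terms(theta_hat, tau2)
  scores <- (g_plus - g_minus) / (2 * eps)
  A <- sum(g_plus + g_minus - 2 * g_mid) / eps ^ 2
  stop_if(!is.finite(A) || A <= 0,
          "RAPS did not converge to an interior maximum (best iterate: ",
          signif(theta_hat, 6), ")")
  se <- sqrt(sum(scores ^ 2)) / A
  new_mr_estimate("raps", theta_hat, se, nrow(h), tau2 = tau2, loss = loss)
}

#' Pleiotropy residual sum and outlier (PRESSO-style) test
#'
#' Detects anomalous instruments. The observed residual sum of squares is
#' `sum_j (beta_out_j - theta_(-j) beta_exp_j)^2` with leave-one-out IVW
#' fits; its null distribution is simulated by redrawing effects from
#' normal distributions centred on the fitted means with the observed SEs
#' (`n_sim` times, seeded). The global p is `(1 + #{RSS* >= RSS}) /
#' (n_sim + 1)`; per-variant outlier p-values are Bonferroni-gated at
#' `alpha_outlier`. The outlier-corrected estimate is IVW on the retained
#' instruments; the raw (all-instrument) IVW estimate is kept in `$raw`.
#'
#' @param h a `harmonized_set` with >= 4 instruments.
#' @param n_sim simulation replicates (>= 500).
#' @param seed RNG seed. @param alpha_outlier outlier-test level.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1, alpha_outlier = 0.05) {
  J <- nrow(h)
  stop_if(J < 4, "PRESSO requires >= 4 instruments")
  stop_if(n_sim < 500, "n_sim must be >= 500")
  x <- h$beta_exp; y <- h$beta_out
  sx <- h$se_exp; sy <- h$se_out
  w <- 1 / sy ^ 2

  loo_theta <- function(xx, yy) {
    S1 <- sum(w * xx * yy); S2 <- sum(w * xx ^ 2)
    (S1 - w * xx * yy) / (S2 - w * xx ^ 2)
  }
  th_loo <- loo_theta(x, y)
  res_obs <- (y - th_loo * x) ^ 2
  rss_obs <- sum(res_obs)

  set.seed(seed)
  Xs <- matrix(rnorm(J * n_sim, x, sx), J, n_sim)
  Ys <- matrix(rnorm(J * n_sim, th_loo * x, sy), J, n_sim)
  S1s <- colSums(w * Xs * Ys)
  S2s <- colSums(w * Xs ^ 2)
  ThL <- (rep(S1s, each = J) - w * Xs * Ys) / (rep(S2s, each = J) - w * Xs ^ 2)
  Res <- (Ys - ThL * Xs) ^ 2
  rss_sim <- colSums(Res)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_var <- (1 + rowSums(Res >= res_obs)) / (n_sim + 1)
  outliers <- h$variant_id[p_var * J < alpha_outlier]

  keep <- !(h$variant_id %in% outliers)
  stop_if(!any(keep), "all instruments flagged as outliers")
  raw <- mr_ivw(h)
  raw$method <- "presso_raw"
  corrected <- if (sum(keep) >= 2) mr_ivw(h[keep, , drop = FALSE]) else
    mr_wald_ratio(h[keep, , drop = FALSE])
  corrected$method <- "presso_corrected"
  corrected$global_p <- global_p
  corrected$outliers <- outliers
  corrected$outlier_pvalues <- setNames(p_var, h$variant_id)
  corrected$raw <- raw
  corrected
}
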