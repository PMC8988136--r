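## Directionality, influence and power diagnostics for the MR battery.

#' Steiger directionality test
#'
#' Compares the instrument-explained variance in the exposure and the
#' outcome: `r2_trait = sum_j z_j^2 / (z_j^2 + n - 2)` over instruments.
#' The assumed direction (exposure -> outcome) is supported when
#' `r2_exp > r2_out` (ties resolve to FALSE); the p-value is a two-sample
#' z-test on Fisher-transformed `sqrt(r2)` values.
#'
#' @param h a `harmonized_set` (needs per-variant `n_exp`, `n_out`).
#' @param n_exp,n_out optional scalar sample sizes overriding the columns.
#' @return list with `direction`, `pvalue`, `r2_exp`, `r2_out`.
#' @export
mr_steiger <- function(h, n_exp = NULL, n_out = NULL) {
  ne <- n_exp %||% median(h$n_exp)
  no <- n_out %||% median(h$n_out)
  stop_if(!is.finite(ne) || !is.finite(no), "missing sample sizes")
  z_e <- h$beta_exp / h$se_exp
  z_o <- h$beta_out / h$se_out
  r2_exp <- sum(z_e ^ 2 / (z_e ^ 2 + ne - 2))
  r2_out <- sum(z_o ^ 2 / (z_o ^ 2 + no - 2))
  re <- sqrt(min(r2_exp, 1 - 1e-12))
  ro <- sqrt(min(r2_out, 1 - 1e-12))
  zstat <- (atanh(re) - atanh(ro)) / sqrt(1 / (ne - 3) + 1 / (no - 3))
  list(direction = r2_exp > r2_out,
       pvalue = 2 * pnorm(-abs(zstat)),
       r2_exp = r2_exp, r2_out = r2_out)
}

#' Leave-one-out IVW analysis
#'
#' Refits IVW excluding one instrument at a time; the full-set estimate is
#' robust when no single exclusion moves it outside any row's CI.
#'
#' @param h a `harmonized_set` with >= 3 instruments.
#' @return data.frame with one row per excluded variant (beta, se, ci) and
#'   attribute `influential` (TRUE when some row's CI excludes the full
#'   estimate).
#' @export
mr_leave_one_out <- function(h) {
  stop_if(nrow(h) < 3, "leave-one-out requires >= 3 instruments")
  full <- mr_ivw(h)
  rows <- lapply(seq_len(nrow(h)), function(j) {
    e <- mr_ivw(h[-j, , drop = FALSE])
    data.frame(excluded = h$variant_id[j], beta = e$beta_hat, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_beta") <- full$beta_hat
  attr(out, "influential") <-
    any(full$beta_hat < out$ci_low | full$beta_hat > out$ci_high)
  out
}

#' Analytic power of binary-outcome two-sample MR
#'
#' Exact two-sided power of the IVW z-test for a binary outcome:
#' with non-centrality `ncp = |log OR| * sqrt(n r2 K (1 - K))`,
#' `power = Phi(ncp - z_{1-alpha/2}) + Phi(-ncp - z_{1-alpha/2})`.
#' At OR = 1 this equals alpha; away from the null the second term
#' vanishes and the expression reduces to the familiar one-term formula.
#'
#' @param n total outcome sample size.
#' @param K case fraction, in (0, 1).
#' @param r2 exposure variance explained by the instruments, in (0, 1).
#' @param or true odds ratio per SD of exposure (> 0).
#' @param alpha two-sided significance level.
#' @return power in \[alpha, 1\].
#' @export
mr_power_binary <- function(n, K, r2, or, alpha = 0.05) {
  stop_if(K <= 0 || K >= 1, "K must be in (0, 1)")
  stop_if(r2 <= 0 || r2 >= 1, "r2 must be in (0, 1)")
  stop_if(or <= 0, "or must be > 0")
  zq <- qnorm(1 - alpha / 2)
  ncp <- abs(log(or)) * sqrt(n * r2 * K * (1 - K))
  pnorm(ncp - zq) + pnorm(-ncp - zq)
}

#' Run the full MR estimator battery
#'
#' Applies the requested estimators to one harmonized exposure-outcome
#' pair and returns a table shaped like the study reports: one row per
#' method with beta, OR, CI, SE, p, heterogeneity p, Egger-intercept p and
#' the Steiger directionality p. Exposures with a single instrument fall
#' back to the Wald ratio; two instruments allow IVW only.
#'
#' @param h a `harmonized_set`.
#' @param methods subset of
#'   `c("ivw", "weighted_median", "egger", "raps", "presso")`.
#' @param seed seed for the seeded components (median bootstrap, PRESSO).
#' @param boot_reps weighted-median bootstrap replicates.
#' @param presso_n_sim PRESSO simulation replicates.
#' @param alpha_mr Bonferroni-corrected significance threshold for the
#'   `significant` column (default 0.05/6, for six trait-pair analyses;
#'   p < 0.05 is conventionally only suggestive).
#' @return data.frame; the `mr_estimate` objects are in attribute
#'   `"estimates"`, the Steiger result in `"steiger"`.
#' @export
mr_battery <- function(h, methods = c("ivw", "weighted_median", "egger",
                                      "raps", "presso"),
                       seed = 1, boot_reps = 1000, presso_n_sim = 1000,
                       alpha_mr = 0.05 / 6) {
  J <- nrow(h)
  est <- list()
  if (J == 1) {
    est$wald_ratio <- mr_wald_ratio(h)
  } else {
    if ("ivw" %in% methods) est$ivw <- mr_ivw(h)
    if (J >= 3 && "weighted_median" %in% methods)
      est$weighted_median <- mr_weighted_median(h, boot_reps = boot_reps,
                                                seed = derive_seed(seed, 1L))
    if (J >= 3 && "egger" %in% methods) est$egger <- mr_egger(h)
    if (J >= 3 && "raps" %in% methods) est$raps <- mr_raps(h)
    if (J >= 4 && "presso" %in% methods) {
      pres <- mr_presso(h, n_sim = presso_n_sim,
                        seed = derive_seed(seed, 2L))
      est$presso_raw <- pres$raw
      est$presso_corrected <- pres
    }
  }
  steiger <- mr_steiger(h)
  tab <- do.call(rbind, lapply(est, as.data.frame))
  tab$steiger_pvalue <- steiger$pvalue
  tab$steiger_direction <- steiger$direction
  tab$significant <- tab$pvalue < alpha_mr
  rownames(tab) <- NULL
  attr(tab, "estimates") <- est
  attr(tab, "steiger") <- steiger
  tab
}
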