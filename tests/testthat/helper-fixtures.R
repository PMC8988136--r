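# Shared fixtures and independent oracles, built in code at test time.

# small well-formed summary-statistics table
toy_sumstats_df <- function() {
  data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    chrom = c("1", "1", "2"),
    pos = c(1000, 2000, 5000),
    effect_allele = c("A", "G", "T"),
    other_allele = c("G", "C", "C"),
    eaf = c(0.3, 0.5, 0.84),
    beta = c(0.1, -0.05, 0.110),
    se = c(0.02, 0.01, 0.0182),
    pvalue = c(2 * pnorm(-5), 2 * pnorm(-5), 1.5e-9),
    n = c(10000, 10000, 159208),
    stringsAsFactors = FALSE
  )
}

toy_sumstats <- function(label = "toy") sumstats(toy_sumstats_df(), label)

# harmonized set built directly from effect vectors (equal-length numerics)
make_h <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.05,
                   n_exp = 20000, n_out = 20000, f = 0.3) {
  J <- length(beta_exp)
  structure(data.frame(
    variant_id = sprintf("iv%02d", seq_len(J)),
    chrom = "1", pos = seq_len(J) * 1e6,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = rep_len(se_exp, J), f_exp = f,
    n_exp = n_exp,
    beta_out = beta_out, se_out = rep_len(se_out, J), f_out = f,
    n_out = n_out,
    pval_exp = 2 * pnorm(-abs(beta_exp / rep_len(se_exp, J))),
    pval_out = 2 * pnorm(-abs(beta_out / rep_len(se_out, J))),
    flipped = FALSE, stringsAsFactors = FALSE
  ), exposure_trait = "x", outcome_trait = "y",
  exclusion_log = data.frame(variant_id = character(0),
                             reason = character(0)),
  class = c("harmonized_set", "data.frame"))
}

# independent WLS-through-origin oracle for IVW (QR route via lm)
ivw_wls_oracle <- function(h) {
  fit <- lm(beta_out ~ 0 + beta_exp, data = as.data.frame(h),
            weights = 1 / h$se_out ^ 2)
  unname(coef(fit)[1])
}

# independent interpolated weighted-median oracle (index arithmetic, no
# approx())
weighted_median_oracle <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]; ww <- w[o]
  s <- (cumsum(ww) - ww / 2) / sum(ww)
  if (0.5 <= s[1]) return(th[1])
  J <- length(th)
  if (0.5 >= s[J]) return(th[J])
  j <- max(which(s <= 0.5))
  th[j] + (th[j + 1] - th[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

# brute-force greedy clumping oracle: literal restatement of the rule,
# nested loops over every pair
clump_oracle <- function(df, panel, p1, p2, r2, kb) {
  df <- df[df$variant_id %in% panel$map$variant_id, , drop = FALSE]
  ord <- order(df$pvalue, as.numeric(df$chrom), df$pos)
  df <- df[ord, , drop = FALSE]
  assigned <- character(0)
  clumps <- list()
  repeat {
    idx_row <- NULL
    for (i in seq_len(nrow(df))) {
      if (!(df$variant_id[i] %in% assigned) && df$pvalue[i] < p1) {
        idx_row <- i; break
      }
    }
    if (is.null(idx_row)) break
    index_id <- df$variant_id[idx_row]
    assigned <- c(assigned, index_id)
    members <- character(0)
    for (i in seq_len(nrow(df))) {
      id <- df$variant_id[i]
      if (id %in% assigned) next
      if (df$pvalue[i] >= p2) next
      if (df$chrom[i] != df$chrom[idx_row]) next
      if (abs(df$pos[i] - df$pos[idx_row]) > kb * 1000) next
      rr <- ld_r2(panel, index_id, id)[1, 1]
      if (rr < r2) next
      members <- c(members, id)
    }
    assigned <- c(assigned, members)
    clumps[[length(clumps) + 1]] <- list(index = index_id,
                                         members = members)
  }
  clumps
}

# panel with wide LD-score spread, for LD-score-regression tests
ldsc_panel_config <- function(seed = 7, n_x = 422218, n_y = 159208, ...) {
  sim_config(M = 2500, block_size = 25, rho = seq(0, 0.95, length.out = 100),
             n_x = n_x, n_y = n_y, seed = seed, ...)
}

# mediation study design with discoverable, path-separated instruments
mediation_config <- function(seed, ...) {
  sim_config(M = 800, block_size = 10, n_x = 20000, n_y = 20000,
             h2_x = 0.25, h2_med = 0.2, causal_frac = 0.08,
             a = 0.3, b = 0.6, c_prime = 0.4, seed = seed, ...)
}
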