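## LD-score-regression heritability and genetic correlation with
## block-jackknife standard errors.
##
## Model: E[z_j^2] = 1 + n h2 ell_j / M (per trait, free intercept
## absorbing confounding/overlap), and for two traits measured in
## non-overlapping cohorts E[z_aj z_bj] = sqrt(n_a n_b) rho_g ell_j / M
## with a free intercept. rg = gencov / sqrt(h2_a h2_b).

## weighted simple linear regression via block-summable sufficient stats
wls_blocks <- function(y, x, w, blk) {
  agg <- function(v) rowsum(v, blk)[, 1]
  cbind(sw = agg(w), swx = agg(w * x), swx2 = agg(w * x ^ 2),
        swy = agg(w * y), swxy = agg(w * x * y))
}

wls_solve <- function(s) {
  ## s: named vector of summed sufficient statistics
  det <- s["sw"] * s["swx2"] - s["swx"] ^ 2
  slope <- (s["sw"] * s["swxy"] - s["swx"] * s["swy"]) / det
  intercept <- (s["swy"] - slope * s["swx"]) / s["sw"]
  c(slope = unname(slope), intercept = unname(intercept))
}

ldsc_weights_h2 <- function(ell, x, h2_0) {
  1 / (pmax(ell, 1) * 2 * (1 + pmax(h2_0, 0) * x) ^ 2)
}

#' LD-score-regression genetic correlation
#'
#' Estimates per-trait SNP heritability by weighted regression of `z^2` on
#' `n * ell / M` (free intercept), the genetic covariance by weighted
#' regression of `z_a * z_b` on `sqrt(n_a n_b) * ell / M` (free
#' intercept), and `rg = gencov / sqrt(h2_a h2_b)`. Standard errors come
#' from a delete-one block jackknife over `n_blocks` contiguous variant
#' blocks (regression weights held fixed across deletions); the p-value is
#' a normal approximation. Weights follow the usual two-pass scheme:
#' 1/max(ell,1) in the first pass, then heteroskedasticity weights from
#' the first-pass fit.
#'
#' @param a,b `sumstats` objects sharing >= 200 variants covered by the
#'   panel's LD scores.
#' @param panel `ld_panel` supplying per-variant LD scores and `M`.
#' @param n_blocks jackknife blocks (default 200).
#' @return An `rg_estimate` list: `rg`, `rg_se`, `rg_pvalue`, per-trait
#'   `h2` with SEs, regression intercepts, `n_blocks`, `n_snp`, and a
#'   `note` when rg is undefined (non-positive heritability).
#' @export
ldsc_rg <- function(a, b, panel, n_blocks = 200) {
  shared <- intersect(intersect(a$variant_id, b$variant_id),
                      panel$map$variant_id)
  stop_if(length(shared) < 200, "need >= 200 shared variants, have ",
          length(shared))
  ai <- a[match(shared, a$variant_id), ]
  bi <- b[match(shared, b$variant_id), ]
  ell <- panel$ld_scores[match(shared, panel$map$variant_id)]
  M <- panel$M
  J <- length(shared)
  blk <- ceiling(seq_len(J) / (J / min(n_blocks, floor(J / 2))))
  B <- max(blk)

  za <- ai$z; zb <- bi$z
  na <- median(ai$n); nb <- median(bi$n)
  xa <- na * ell / M; xb <- nb * ell / M; xab <- sqrt(na * nb) * ell / M

  fit_jk <- function(y, x, w) {
    s <- wls_blocks(y, x, w, blk)
    tot <- colSums(s)
    names(tot) <- colnames(s)
    full <- wls_solve(tot)
    del <- vapply(seq_len(B), function(i) {
      si <- tot - s[i, ]
      names(si) <- colnames(s)
      wls_solve(si)
    }, numeric(2))
    list(full = full, del = del)   # del: 2 x B (slope, intercept)
  }

  ## first pass: 1/ell weights, second pass: heteroskedasticity weights
  w0 <- 1 / pmax(ell, 1)
  h2a_0 <- wls_solve(colSums(wls_blocks(za ^ 2, xa, w0, blk)))["slope"]
  h2b_0 <- wls_solve(colSums(wls_blocks(zb ^ 2, xb, w0, blk)))["slope"]
  wa <- ldsc_weights_h2(ell, xa, h2a_0)
  wb <- ldsc_weights_h2(ell, xb, h2b_0)
  fa <- fit_jk(za ^ 2, xa, wa)
  fb <- fit_jk(zb ^ 2, xb, wb)

  gcov_0 <- wls_solve(colSums(wls_blocks(za * zb, xab, w0, blk)))["slope"]
  vab <- (1 + pmax(h2a_0, 0) * xa) * (1 + pmax(h2b_0, 0) * xb) +
    (gcov_0 * xab) ^ 2
  wab <- 1 / (pmax(ell, 1) * vab)
  fab <- fit_jk(za * zb, xab, wab)

  h2_a <- unname(fa$full["slope"]); h2_b <- unname(fb$full["slope"])
  gcov <- unname(fab$full["slope"])
  jk_se <- function(est) sqrt((B - 1) / B * sum((est - mean(est)) ^ 2))

  out <- list(h2_a = h2_a, h2_a_se = jk_se(fa$del[1, ]),
              h2_b = h2_b, h2_b_se = jk_se(fb$del[1, ]),
              gencov = gcov, gencov_se = jk_se(fab$del[1, ]),
              intercept_a = unname(fa$full["intercept"]),
              intercept_b = unname(fb$full["intercept"]),
              intercept_ab = unname(fab$full["intercept"]),
              n_blocks = B, n_snp = J,
              trait_a = attr(a, "trait_label"),
              trait_b = attr(b, "trait_label"))
  if (h2_a <= 0 || h2_b <= 0) {
    out$rg <- NA_real_; out$rg_se <- NA_real_; out$rg_pvalue <- NA_real_
    out$note <- "non-positive heritability estimate: rg undefined"
  } else {
    rg_del <- fab$del[1, ] / sqrt(pmax(fa$del[1, ], 1e-12) *
                                    pmax(fb$del[1, ], 1e-12))
    out$rg <- gcov / sqrt(h2_a * h2_b)
    out$rg_se <- jk_se(rg_del)
    out$rg_pvalue <- 2 * pnorm(-abs(out$rg / out$rg_se))
  }
  structure(out, class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("<rg_estimate> %s vs %s over %d SNPs (%d jackknife blocks)\n",
              x$trait_a %||% "a", x$trait_b %||% "b", x$n_snp, x$n_blocks))
  if (is.na(x$rg)) {
    cat(" ", x$note, "\n")
  } else {
    cat(sprintf("  rg = %.3f (SE %.3f, p = %.3g)\n", x$rg, x$rg_se,
                x$rg_pvalue))
  }
  cat(sprintf("  h2_a = %.4f (SE %.4f), h2_b = %.4f (SE %.4f)\n",
              x$h2_a, x$h2_a_se, x$h2_b, x$h2_b_se))
  invisible(x)
}
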