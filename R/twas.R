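## TWAS weighted-burden association: genetically predicted expression
## versus trait, from GWAS z-scores and precomputed expression weights.

#' TWAS association statistic
#'
#' Association between a trait and the cis-genetic component of a gene's
#' expression: `z_twas = (w' z) / sqrt(w' Sigma w)` where `w` are the
#' expression weights, `z` the trait GWAS z-scores over the weight
#' support, and `Sigma` the LD matrix of those variants. Expression-weight
#' training is out of scope: weights are an input.
#'
#' @param weights numeric weight vector (named by variant or aligned with
#'   `z`).
#' @param z trait z-scores over the same variants.
#' @param Sigma LD correlation sub-matrix of the variants.
#' @param gene,tissue labels carried through to the result.
#' @param n_tests number of gene-tissue pairs tested (Bonferroni flag at
#'   0.05 / n_tests).
#' @return A `twas_result`: `z_twas`, `pvalue`, `significant`, labels.
#' @export
twas_assoc <- function(weights, z, Sigma, gene = "gene", tissue = "tissue",
                       n_tests = 1) {
  stopifnot(length(weights) == length(z),
            nrow(Sigma) == length(z), ncol(Sigma) == length(z))
  denom2 <- drop(crossprod(weights, Sigma %*% weights))
  stop_if(denom2 <= 0, "w' Sigma w must be > 0")
  zt <- sum(weights * z) / sqrt(denom2)
  p <- 2 * pnorm(-abs(zt))
  structure(list(gene = gene, tissue = tissue, z_twas = zt, pvalue = p,
                 significant = p < 0.05 / n_tests, n_tests = n_tests,
                 weights = weights),
            class = "twas_result")
}

#' @export
print.twas_result <- function(x, ...) {
  cat(sprintf("<twas_result> %s / %s: z = %.3f, p = %.3g%s\n", x$gene,
              x$tissue, x$z_twas, x$pvalue,
              if (x$significant) " (Bonferroni-significant)" else ""))
  invisible(x)
}
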