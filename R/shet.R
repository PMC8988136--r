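## Cross-phenotype meta-analysis: subset-maximized, sample-size-weighted
## heterogeneous statistic over per-trait z-scores.

subset_list <- function(K) {
  unlist(lapply(seq_len(K), function(k)
    utils::combn(K, k, simplify = FALSE)), recursive = FALSE)
}

## S(T) = (w_T' R_T^-1 |z_T|)^2 / (w_T' R_T^-1 w_T): within a subset,
## z-scores are sign-aligned to the first trait's direction, which (after
## squaring) is equivalent to using |z|.
shet_stat <- function(zabs, w, R, subsets = subset_list(length(zabs))) {
  vals <- vapply(subsets, function(T) {
    u <- solve(R[T, T, drop = FALSE], w[T])
    sum(u * zabs[T]) ^ 2 / sum(u * w[T])
  }, numeric(1))
  list(S = max(vals),
       per_subset = setNames(vals, vapply(subsets, paste, "", collapse = "+")))
}

#' Null distribution of the heterogeneous cross-phenotype statistic
#'
#' Simulates `z* ~ MVN(0, R)` and evaluates the subset-maximized statistic,
#' returning the sorted Monte-Carlo sample together with a moment-matched
#' gamma fit of its distribution for tail evaluation beyond Monte-Carlo
#' resolution.
#'
#' @param R trait correlation matrix (identity for non-overlapping
#'   cohorts). @param n per-trait sample sizes (weights are `sqrt(n)`).
#' @param n_mc Monte-Carlo replicates. @param seed RNG seed.
#' @return A `shet_null` list: sorted `sample`, gamma `shape`/`rate`, `R`,
#'   `w`.
#' @export
shet_null <- function(R, n, n_mc = 1e4, seed = 1) {
  K <- nrow(R)
  stop_if(length(n) != K, "length(n) must match nrow(R)")
  L <- tryCatch(chol(R), error = function(e)
    stop("singular trait correlation matrix", call. = FALSE))
  set.seed(seed)
  Z <- abs(matrix(rnorm(n_mc * K), n_mc, K) %*% L)
  w <- sqrt(n)
  subsets <- subset_list(K)
  vals <- matrix(NA_real_, n_mc, length(subsets))
  for (i in seq_along(subsets)) {
    T <- subsets[[i]]
    u <- solve(R[T, T, drop = FALSE], w[T])
    vals[, i] <- (Z[, T, drop = FALSE] %*% u) ^ 2 / sum(u * w[T])
  }
  s <- apply(vals, 1, max)
  m <- mean(s); v <- var(s)
  structure(list(sample = sort(s), shape = m ^ 2 / v, rate = m / v,
                 R = R, w = w, n_mc = n_mc),
            class = "shet_null")
}

null_pvalue <- function(null, S) {
  n_mc <- length(null$sample)
  exceed <- n_mc - findInterval(S, null$sample)
  p_mc <- (1 + exceed) / (n_mc + 1)
  ifelse(exceed == 0,
         pmin(p_mc, pgamma(S, null$shape, null$rate, lower.tail = FALSE)),
         p_mc)
}

#' Heterogeneous cross-phenotype association statistic (SHet)
#'
#' Sample-size-weighted fixed-effect meta-analysis maximized over all
#' non-empty trait subsets, powered when only a subset of traits carries
#' the effect. For each subset `T`,
#' `S(T) = (w_T' R_T^-1 z_T)^2 / (w_T' R_T^-1 w_T)` with weights
#' `w = sqrt(n)` and subset z-scores sign-aligned to the first trait;
#' `S_Het = max_T S(T)` (direct enumeration; exact for small numbers of
#' traits). For a single trait this reduces to `z^2` with an analytic
#' chi-square p. Otherwise the p-value is Monte-Carlo
#' (`(1 + #{max* >= S}) / (n_mc + 1)`), switching to the fitted gamma
#' tail when the statistic exceeds Monte-Carlo resolution.
#'
#' @param z per-trait z-scores at one variant.
#' @param n per-trait sample sizes.
#' @param R trait correlation matrix (default identity: non-overlapping
#'   cohorts).
#' @param n_mc Monte-Carlo replicates for the null (ignored when `null`
#'   supplied). @param seed RNG seed.
#' @param null optional precomputed [shet_null()] (reused across variants).
#' @return list with `S_het`, `p`, per-subset statistics and the tail
#'   method used (`"chisq"`, `"mc"` or `"gamma"`).
#' @export
shet <- function(z, n, R = diag(length(z)), n_mc = 1e4, seed = 1,
                 null = NULL) {
  K <- length(z)
  stop_if(length(n) != K || nrow(R) != K || ncol(R) != K,
          "dimensions of z, n, R must agree")
  if (K == 1) {
    S <- z ^ 2
    return(list(S_het = S, p = pchisq(S, 1, lower.tail = FALSE),
                per_subset = c("1" = S), tail = "chisq"))
  }
  st <- shet_stat(abs(z), sqrt(n), R)
  if (is.null(null)) null <- shet_null(R, n, n_mc = n_mc, seed = seed)
  n_samp <- length(null$sample)
  exceed <- n_samp - findInterval(st$S, null$sample)
  p <- null_pvalue(null, st$S)
  list(S_het = st$S, p = unname(p), per_subset = st$per_subset,
       tail = if (exceed == 0) "gamma" else "mc")
}

#' Genome-wide cross-trait meta-analysis scan
#'
#' Computes the SHet statistic for every variant shared between two
#' summary-statistics sets, keeps variants with meta-analysis p below
#' `p_meta` AND both trait-specific p below `p_single`, and clumps the
#' survivors (on the meta p-value) into independent index loci.
#'
#' @param a,b `sumstats` objects for the two traits.
#' @param panel LD panel for clumping.
#' @param R trait correlation matrix (identity for non-overlapping
#'   cohorts).
#' @param p_meta genome-wide meta-analysis threshold (default 2.5e-8,
#'   i.e. 5e-8 / 2 for two meta-analyses).
#' @param p_single trait-specific threshold.
#' @param clump_r2,clump_kb clumping parameters for index loci.
#' @param n_mc Monte-Carlo size for the shared null distribution.
#' @param seed RNG seed.
#' @return list with `meta` (per-variant table: z's, S_het, p_meta),
#'   `hits` (the filtered survivors), `clumps` (a `clump_result`) and
#'   `index` (table of index loci, one per clump).
#' @export
cross_trait_scan <- function(a, b, panel, R = diag(2), p_meta = 2.5e-8,
                             p_single = 1e-5, clump_r2 = 0.4,
                             clump_kb = 500, n_mc = 1e5, seed = 1) {
  shared <- intersect(a$variant_id, b$variant_id)
  stop_if(length(shared) < 1, "no shared variants")
  ai <- a[match(shared, a$variant_id), , drop = FALSE]
  bi <- b[match(shared, b$variant_id), , drop = FALSE]
  n_tr <- c(median(ai$n), median(bi$n))
  w <- sqrt(n_tr)

  null <- shet_null(R, n_tr, n_mc = n_mc, seed = seed)
  za <- abs(ai$z); zb <- abs(bi$z)
  subsets <- subset_list(2)
  smat <- vapply(subsets, function(T) {
    u <- solve(R[T, T, drop = FALSE], w[T])
    Zt <- cbind(za, zb)[, T, drop = FALSE]
    drop(Zt %*% u) ^ 2 / sum(u * w[T])
  }, numeric(length(shared)))
  S <- apply(matrix(smat, ncol = length(subsets)), 1, max)
  pm <- null_pvalue(null, S)

  meta <- data.frame(
    variant_id = shared, chrom = ai$chrom, pos = ai$pos,
    effect_allele = ai$effect_allele, other_allele = ai$other_allele,
    eaf = ai$eaf,
    beta_a = ai$beta, p_a = ai$pvalue, beta_b = bi$beta, p_b = bi$pvalue,
    S_het = S, pvalue = pm, stringsAsFactors = FALSE
  )
  hits <- meta[meta$pvalue < p_meta & meta$p_a < p_single &
                 meta$p_b < p_single, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(list(meta = meta, hits = hits, clumps = NULL,
                index = hits))
  }
  cr <- clump(hits, panel, p1 = p_meta, p2 = p_single, r2 = clump_r2,
              kb = clump_kb)
  idx <- hits[match(index_variants(cr), hits$variant_id), , drop = FALSE]
  rownames(idx) <- NULL
  list(meta = meta, hits = hits, clumps = cr, index = idx)
}
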