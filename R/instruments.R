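## Instrument selection: greedy LD clumping, strength diagnostics
## (variance explained, F statistic), confounder-based exclusion.

#' Greedy LD clumping of an association scan
#'
#' PLINK-style greedy clumping: repeatedly take the smallest-p unassigned
#' variant with `p < p1` as an index; assign to its clump every unassigned
#' variant with `p < p2`, LD r-squared >= `r2` with the index, and within
#' `kb` kilobases on the same chromosome; repeat until no index candidates
#' remain. Ties in p are broken by (chromosome, position) ascending, so the
#' result is deterministic. Variants not covered by the panel are logged
#' and skipped (conservative: unknown LD is not assumed to be absent).
#'
#' @param s a `sumstats` object or any data.frame with columns
#'   `variant_id`, `chrom`, `pos`, `pvalue` (e.g. a meta-analysis table).
#' @param panel an [make_ld_panel()] panel covering the variants.
#' @param p1 index-variant p-value threshold.
#' @param p2 member p-value threshold.
#' @param r2 LD r-squared threshold for clump membership.
#' @param kb distance window in kilobases.
#' @return A `clump_result`: list of clumps (each with `index`, `members`,
#'   `index_pvalue`), the parameters used, and the ids skipped for lack of
#'   panel coverage.
#' @export
clump <- function(s, panel, p1 = 5e-8, p2 = 5e-8, r2 = 0.001, kb = 10000) {
  stop_if(kb <= 0, "kb must be > 0")
  stop_if(r2 < 0 || r2 > 1, "r2 must be in [0, 1]")
  df <- as.data.frame(s)[, c("variant_id", "chrom", "pos", "pvalue")]
  covered <- df$variant_id %in% panel$map$variant_id
  skipped <- df$variant_id[!covered]
  df <- df[covered, , drop = FALSE]
  df <- df[order(df$pvalue, chrom_rank(df$chrom), df$pos), , drop = FALSE]

  pidx <- match(df$variant_id, panel$map$variant_id)
  assigned <- rep(FALSE, nrow(df))
  clumps <- list()
  repeat {
    cand <- which(!assigned & df$pvalue < p1)
    if (length(cand) == 0) break
    i <- cand[1]
    assigned[i] <- TRUE
    mem <- which(!assigned & df$pvalue < p2 & df$chrom == df$chrom[i] &
                   abs(df$pos - df$pos[i]) <= kb * 1000)
    if (length(mem) > 0) {
      ld <- panel$r[pidx[i], pidx[mem]] ^ 2
      mem <- mem[ld >= r2]
    }
    assigned[mem] <- TRUE
    clumps[[length(clumps) + 1L]] <- list(
      index = df$variant_id[i],
      index_pvalue = df$pvalue[i],
      members = df$variant_id[mem]
    )
  }
  structure(list(clumps = clumps,
                 params = list(p1 = p1, p2 = p2, r2 = r2, kb = kb),
                 skipped = skipped),
            class = "clump_result")
}

#' Index variants of a clump result
#' @param cr a `clump_result`.
#' @export
index_variants <- function(cr) {
  vapply(cr$clumps, `[[`, character(1), "index")
}

#' @export
print.clump_result <- function(x, ...) {
  cat("<clump_result>", length(x$clumps), "clumps | params: p1 =",
      x$params$p1, "p2 =", x$params$p2, "r2 =", x$params$r2, "kb =",
      x$params$kb, "\n")
  invisible(x)
}

#' Select independent genetic instruments
#'
#' Instruments are the index variants of a strict clump at
#' `p < p_threshold` with LD pruning at r-squared `< r2` (any variant in
#' LD at or above `r2` with a stronger one is absorbed into its clump and
#' removed). The distance window default (10,000 kb) makes LD alone govern
#' the pruning; it is configurable since strict-pruning window conventions
#' vary.
#'
#' @param s a `sumstats` object for the exposure trait.
#' @param panel LD panel covering the candidates.
#' @param p_threshold genome-wide significance threshold for instruments.
#' @param r2 LD pruning threshold.
#' @param kb distance window (kilobases).
#' @return An `instrument_set`: ids, the per-variant association records,
#'   per-variant variance-explained terms, their sum `r2_total`, the
#'   instrument count `k`, the sample size `n` used, and the F statistic.
#' @export
select_instruments <- function(s, panel, p_threshold = 5e-8, r2 = 0.001,
                               kb = 10000) {
  cr <- clump(s, panel, p1 = p_threshold, p2 = p_threshold, r2 = r2, kb = kb)
  ids <- index_variants(cr)
  if (length(ids) == 0) {
    near <- sum(s$pvalue < p_threshold * 100, na.rm = TRUE)
    stop("no instruments at p < ", p_threshold, " (", near,
         " near-misses at p < ", p_threshold * 100, ")", call. = FALSE)
  }
  instrument_set(s[match(ids, s$variant_id), , drop = FALSE], clump_result = cr)
}

#' Construct an instrument set from association records
#'
#' @param records data.frame of instrument rows (beta, se, eaf, n, ...).
#' @param clump_result optional provenance.
#' @export
instrument_set <- function(records, clump_result = NULL) {
  records <- as.data.frame(records)
  terms <- r2_terms(records)
  r2_total <- sum(terms, na.rm = TRUE)
  k <- nrow(records)
  n <- round(median(records$n))
  structure(list(ids = records$variant_id, records = records,
                 r2_terms = terms, r2_total = r2_total, k = k, n = n,
                 F = f_statistic(n, k, r2_total),
                 clump_result = clump_result,
                 removed = data.frame(variant_id = character(0),
                                      trait = character(0))),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set> k =", x$k, "| r2_total =", signif(x$r2_total, 4),
      "| F =", round(x$F, 2), "| n =", x$n, "\n")
  invisible(x)
}

## per-variant contribution to instrument variance explained:
## beta^2 2f(1-f) / (beta^2 2f(1-f) + se^2 2 n f(1-f))
r2_terms <- function(records) {
  f <- records$eaf
  bad <- !is.finite(f) | f <= 0 | f >= 1
  if (any(bad))
    warning(sum(bad), " variant(s) with eaf missing or in {0,1} skipped in ",
            "variance explained", call. = FALSE)
  v <- 2 * f * (1 - f)
  num <- records$beta ^ 2 * v
  den <- num + records$se ^ 2 * 2 * records$n * f * (1 - f)
  out <- ifelse(bad, NA_real_, num / den)
  setNames(out, records$variant_id)
}

#' Variance in the exposure explained by a set of instruments
#'
#' Per-variant terms
#' `beta^2 * 2f(1-f) / (beta^2 * 2f(1-f) + se^2 * 2n * f(1-f))`
#' summed over instruments; invariant to allele recoding
#' (beta -> -beta, f -> 1-f). Variants with `f` in \{0, 1\} or missing are
#' skipped with a warning (zero genotypic variance).
#'
#' @param records data.frame with `beta`, `se`, `eaf`, `n` (and
#'   `variant_id` for the term names), e.g. `instrument_set$records`.
#' @return the summed r-squared, with per-variant terms in attribute
#'   `"terms"`.
#' @export
variance_explained <- function(records) {
  terms <- r2_terms(as.data.frame(records))
  structure(sum(terms, na.rm = TRUE), terms = terms)
}

#' Instrument-strength F statistic
#'
#' `F = ((n - k - 1) / k) * (r2 / (1 - r2))`; values above 10
#' conventionally indicate little weak-instrument bias.
#'
#' @param n sample size. @param k instrument count.
#' @param r2 variance explained by the instruments, in \[0, 1).
#' @export
f_statistic <- function(n, k, r2) {
  stop_if(r2 >= 1 || r2 < 0, "r2 must be in [0, 1)")
  stop_if(n <= k + 1, "need n > k + 1")
  ((n - k - 1) / k) * (r2 / (1 - r2))
}

#' Drop instruments associated with potential confounder traits
#'
#' Removes instruments annotated at genome-wide significance to any
#' blocklisted trait, using a user-supplied variant-to-trait annotation
#' table (no live catalogue query). Strength diagnostics are recomputed on
#' the retained set; removals are logged in `$removed`.
#'
#' @param ivs an `instrument_set`.
#' @param annotation data.frame with `variant_id`, `trait`, `pvalue`.
#' @param blocklist character vector of confounder trait names.
#' @param p_threshold annotation significance threshold.
#' @return the filtered `instrument_set`.
#' @export
exclude_confounder_snps <- function(ivs, annotation, blocklist,
                                    p_threshold = 5e-8) {
  stopifnot(inherits(ivs, "instrument_set"))
  if (is.null(annotation) || nrow(annotation) == 0 || length(blocklist) == 0)
    return(ivs)
  hits <- annotation[annotation$trait %in% blocklist &
                       annotation$pvalue < p_threshold &
                       annotation$variant_id %in% ivs$ids, , drop = FALSE]
  drop_ids <- unique(hits$variant_id)
  keep <- !(ivs$ids %in% drop_ids)
  stop_if(!any(keep), "all instruments removed by confounder exclusion")
  out <- instrument_set(ivs$records[keep, , drop = FALSE],
                        clump_result = ivs$clump_result)
  out$removed <- hits[, c("variant_id", "trait")]
  out
}
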