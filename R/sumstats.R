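## GWAS summary statistics: construction, validation, IO, harmonization.
##
## A `sumstats` object is a plain data.frame (one row per variant) carrying
## trait metadata and a validation exclusion log as attributes. Columns:
## variant_id, chrom, pos, effect_allele, other_allele, eaf, beta, se,
## pvalue, n (+ optional n_case, n_control) and the derived z = beta/se.

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue", "n")

#' Build a validated summary-statistics object
#'
#' Validates one GWAS summary-statistics table row-wise and returns a
#' `sumstats` data.frame. Rows violating the record invariants (`se > 0`,
#' `eaf` in \[0,1\] or missing, `pvalue` in (0,1\], single-base alleles with
#' `effect_allele != other_allele`, positive position, unique `variant_id`)
#' are dropped and recorded in the exclusion log, available via
#' [exclusion_log()]. A z-score column `z = beta/se` is added; when it
#' disagrees with the z implied by the reported p-value by more than
#' `z_tol`, a validation warning is raised (the row is kept: the reported
#' beta and se are taken as authoritative).
#'
#' @param df data.frame with at least the columns `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, `n`;
#'   `eaf`, `n_case`, `n_control` optional (`eaf` filled with `NA` if absent).
#' @param trait_label character scalar naming the trait.
#' @param genome_build genome build label (positions are 1-based).
#' @param z_tol tolerance for the beta/se vs p-value z-score consistency check.
#' @return A `sumstats` object (data.frame) with attributes `trait_label`,
#'   `genome_build` and `exclusion_log`.
#' @seealso [read_sumstats()], [harmonize()], [detect_palindromes()]
#' @export
sumstats <- function(df, trait_label, genome_build = "GRCh37", z_tol = 0.05) {
  stopifnot(is.data.frame(df), is.character(trait_label), length(trait_label) == 1L)
  missing_cols <- setdiff(setdiff(SUMSTATS_COLS, "eaf"), names(df))
  stop_if(length(missing_cols) > 0,
          "missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_

  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n"))
    df[[col]] <- as.numeric(df[[col]])

  bases <- c("A", "C", "G", "T")
  reason <- rep(NA_character_, nrow(df))
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(!is.finite(df$se) | df$se <= 0, "bad_se")
  flag(is.finite(df$eaf) & (df$eaf < 0 | df$eaf > 1), "bad_eaf")
  flag(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1, "bad_pvalue")
  flag(!(df$effect_allele %in% bases) | !(df$other_allele %in% bases) |
         df$effect_allele == df$other_allele, "bad_alleles")
  flag(!is.finite(df$pos) | df$pos < 0, "bad_pos")
  flag(!is.finite(df$beta), "bad_beta")
  flag(!is.finite(df$n) | df$n <= 0, "bad_n")
  flag(duplicated(df$variant_id), "duplicate_id")

  log <- data.frame(variant_id = df$variant_id[!is.na(reason)],
                    reason = reason[!is.na(reason)],
                    stringsAsFactors = FALSE)
  keep <- df[is.na(reason), , drop = FALSE]
  rownames(keep) <- NULL
  keep$z <- keep$beta / keep$se

  z_p <- z_from_p(keep$pvalue, keep$beta)
  off <- is.finite(z_p) & abs(keep$z - z_p) > z_tol
  if (any(off))
    warning(sum(off), " variant(s) with |z(beta/se) - z(p)| > ", z_tol,
            " (e.g. ", keep$variant_id[which(off)[1]], ")", call. = FALSE)

  structure(keep,
            trait_label = trait_label,
            genome_build = genome_build,
            exclusion_log = log,
            class = c("sumstats", "data.frame"))
}

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Reads a header-bearing tab-delimited table, optionally renaming consortium
#' column dialects via `column_map`, and validates it with [sumstats()].
#'
#' @param path path to a tab-delimited file with a header row.
#' @param trait_label trait name; defaults to the file name.
#' @param column_map optional named character vector mapping standard names to
#'   file column names, e.g. `c(variant_id = "SNP", pvalue = "P")`.
#' @param ... passed to [sumstats()] (e.g. `genome_build`).
#' @return A `sumstats` object; rows failing validation are dropped and
#'   logged (see [exclusion_log()]), input row order is preserved.
#' @export
read_sumstats <- function(path, trait_label = NULL, column_map = NULL, ...) {
  stop_if(!file.exists(path), "file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  stop_if(nrow(dt) == 0, "empty summary-statistics file: ", path)
  if (!is.null(column_map)) {
    missing_src <- setdiff(unname(column_map), names(dt))
    stop_if(length(missing_src) > 0,
            "mapped column(s) not in file: ", paste(missing_src, collapse = ", "))
    for (std in names(column_map)) names(dt)[names(dt) == column_map[[std]]] <- std
  }
  sumstats(dt, trait_label = trait_label %||% basename(path), ...)
}

#' Write summary statistics (and their exclusion log) as TSV
#'
#' @param s a `sumstats` object.
#' @param path output path; the exclusion log, if non-empty, is written next
#'   to it with suffix `.exclusions.tsv`.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  stopifnot(inherits(s, "sumstats"))
  cols <- intersect(c(SUMSTATS_COLS, "n_case", "n_control"), names(s))
  data.table::fwrite(as.data.frame(s)[, cols], path, sep = "\t")
  log <- exclusion_log(s)
  if (!is.null(log) && nrow(log) > 0)
    data.table::fwrite(log, paste0(path, ".exclusions.tsv"), sep = "\t")
  invisible(path)
}

#' Exclusion log of a sumstats or harmonized object
#'
#' @param x a `sumstats` or `harmonized_set` object.
#' @return data.frame with columns `variant_id`, `reason`.
#' @export
exclusion_log <- function(x) attr(x, "exclusion_log")

#' Trait label of a sumstats object
#' @param s a `sumstats` object.
#' @export
trait_label <- function(s) attr(s, "trait_label")

#' @export
print.sumstats <- function(x, ...) {
  cat("<sumstats> trait:", attr(x, "trait_label"),
      "| build:", attr(x, "genome_build"),
      "|", nrow(x), "variants |", nrow(exclusion_log(x) %||% data.frame()),
      "dropped at validation\n")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Detect palindromic (strand-ambiguous) variants
#'
#' A variant is palindromic when its allele pair is \{A,T\} or \{C,G\}:
#' the strand cannot be resolved from alleles alone. All palindromes are
#' flagged regardless of allele frequency.
#'
#' @param s a `sumstats` object (or data.frame with `effect_allele`,
#'   `other_allele`, `variant_id`).
#' @return named logical vector, TRUE for palindromic variants.
#' @export
detect_palindromes <- function(s) {
  pal <- is_palindromic(s$effect_allele, s$other_allele)
  setNames(pal, s$variant_id)
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  unname(comp[a1] == a2)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure's effect allele for a set of
#' instruments. Variants absent from the outcome are excluded (`missing`),
#' palindromic variants are excluded unconditionally (`palindromic`), and
#' variants whose allele sets disagree between the two studies are excluded
#' (`allele_mismatch`; no strand flipping is attempted). When the outcome's
#' effect allele equals the exposure's other allele, the outcome beta sign
#' and effect-allele frequency are flipped simultaneously
#' (beta -> -beta, f -> 1 - f). Harmonizing an already-aligned pair is a
#' no-op (idempotence).
#'
#' @param exposure,outcome `sumstats` objects.
#' @param iv_ids character vector of instrument ids; must all be present in
#'   `exposure`.
#' @param freq_warn warn when |f_exp - f_out(aligned)| exceeds this (allele
#'   frequency sanity check; warning only, never an exclusion).
#' @return A `harmonized_set` data.frame with per-variant columns
#'   `beta_exp`, `se_exp`, `f_exp`, `n_exp`, `beta_out`, `se_out`, `f_out`,
#'   `n_out`, `flipped`, plus allele/position bookkeeping; the exclusion log
#'   (variant -> reason) is available via [exclusion_log()].
#' @export
harmonize <- function(exposure, outcome, iv_ids, freq_warn = 0.2) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  iv_ids <- as.character(iv_ids)
  stop_if(!all(iv_ids %in% exposure$variant_id),
          "iv_ids not all present in exposure: ",
          paste(head(setdiff(iv_ids, exposure$variant_id), 3), collapse = ", "))

  ex <- exposure[match(iv_ids, exposure$variant_id), , drop = FALSE]
  out_idx <- match(iv_ids, outcome$variant_id)
  stop_if(all(is.na(out_idx)), "no overlapping instruments")
  ou <- outcome[out_idx, , drop = FALSE]

  reason <- rep(NA_character_, length(iv_ids))
  reason[is.na(out_idx)] <- "missing"
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)
  reason[is.na(reason) & pal] <- "palindromic"
  same <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swap <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  same[is.na(same)] <- FALSE
  swap[is.na(swap)] <- FALSE
  reason[is.na(reason) & !(same | swap)] <- "allele_mismatch"

  keep <- is.na(reason)
  stop_if(!any(keep), "no overlapping instruments")
  flip <- swap[keep]
  h <- data.frame(
    variant_id = iv_ids[keep],
    chrom = ex$chrom[keep], pos = ex$pos[keep],
    effect_allele = ex$effect_allele[keep], other_allele = ex$other_allele[keep],
    beta_exp = ex$beta[keep], se_exp = ex$se[keep],
    f_exp = ex$eaf[keep], n_exp = ex$n[keep],
    beta_out = ifelse(flip, -ou$beta[keep], ou$beta[keep]),
    se_out = ou$se[keep],
    f_out = ifelse(flip, 1 - ou$eaf[keep], ou$eaf[keep]),
    n_out = ou$n[keep],
    pval_exp = ex$pvalue[keep], pval_out = ou$pvalue[keep],
    flipped = flip,
    stringsAsFactors = FALSE
  )
  rownames(h) <- NULL

  big <- is.finite(h$f_exp) & is.finite(h$f_out) & abs(h$f_exp - h$f_out) > freq_warn
  if (any(big))
    warning(sum(big), " variant(s) with |f_exp - f_out| > ", freq_warn,
            " after alignment", call. = FALSE)

  structure(h,
            exposure_trait = attr(exposure, "trait_label"),
            outcome_trait = attr(outcome, "trait_label"),
            exclusion_log = data.frame(variant_id = iv_ids[!keep],
                                       reason = reason[!keep],
                                       stringsAsFactors = FALSE),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("<harmonized_set>", attr(x, "exposure_trait"), "->",
      attr(x, "outcome_trait"), "|", nrow(x), "instruments retained,",
      nrow(exclusion_log(x)), "excluded\n")
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
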