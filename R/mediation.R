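## Two-step MR mediation: product-of-coefficients decomposition of a
## total causal effect into indirect (through a mediator) and direct parts.

#' Two-step MR mediation decomposition
#'
#' Given the exposure->mediator effect `a` (step 1), the mediator->outcome
#' effect `b` (step 2) and the total exposure->outcome effect `c`,
#' computes the indirect effect `a*b`, the direct effect `c' = c - a*b`
#' (so indirect + direct = c exactly), the proportion mediated
#' `a*b / c`, and the adjusted odds ratio `exp(c')`. The mediation is
#' declared significant only when both step p-values pass the Bonferroni
#' threshold `alpha_bonf`.
#'
#' Two table-view conventions for the proportion are exposed: `proportion`
#' uses the unrounded indirect effect, `proportion_table` divides the
#' 3-decimal-rounded indirect effect by `c` (the reporting convention of
#' the tables this decomposition reproduces; the two can differ in the
#' final digit). Unrounded values are always retained.
#'
#' @param est_xm step-1 estimate (exposure -> mediator): an `mr_estimate`
#'   or any list with `beta_hat`, `pvalue` and optionally
#'   `intercept_pvalue`.
#' @param est_my step-2 estimate (mediator -> outcome), same form.
#' @param total_c total causal effect of exposure on outcome.
#' @param alpha_bonf Bonferroni significance threshold for both steps
#'   (default 0.05/11, for eleven candidate mediators).
#' @param mediator mediator label.
#' @return A `mediation_result` list.
#' @export
two_step_mediation <- function(est_xm, est_my, total_c,
                               alpha_bonf = 0.05 / 11, mediator = "mediator") {
  stop_if(!is.finite(total_c), "total_c must be finite")
  a <- est_xm$beta_hat; b <- est_my$beta_hat
  indirect <- a * b
  direct <- total_c - indirect
  structure(list(
    mediator = mediator,
    a = a, a_pvalue = est_xm$pvalue,
    a_intercept_pvalue = est_xm$intercept_pvalue %||% NA_real_,
    b = b, b_pvalue = est_my$pvalue,
    b_intercept_pvalue = est_my$intercept_pvalue %||% NA_real_,
    total = total_c,
    indirect = indirect,
    direct = direct,
    proportion = indirect / total_c,
    proportion_table = round(indirect, 3) / total_c,
    adjusted_or = exp(direct),
    significant = isTRUE(est_xm$pvalue < alpha_bonf &&
                           est_my$pvalue < alpha_bonf),
    alpha_bonf = alpha_bonf
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s: a = %.3f (p = %.3g), b = %.3f (p = %.3g)\n",
              x$mediator, x$a, x$a_pvalue, x$b, x$b_pvalue))
  cat(sprintf("  indirect = %.3f, direct = %.3f, adjusted OR = %.2f, proportion = %.2f%%%s\n",
              round(x$indirect, 3), round(x$direct, 3),
              round(x$adjusted_or, 2), 100 * x$proportion_table,
              if (x$significant) "" else " (not significant)"))
  invisible(x)
}

#' @export
as.data.frame.mediation_result <- function(x, ...) {
  data.frame(mediator = x$mediator, a = x$a, a_pvalue = x$a_pvalue,
             a_intercept_pvalue = x$a_intercept_pvalue,
             b = x$b, b_pvalue = x$b_pvalue,
             b_intercept_pvalue = x$b_intercept_pvalue,
             indirect = x$indirect, direct = x$direct,
             adjusted_or = x$adjusted_or,
             proportion = x$proportion,
             proportion_table = x$proportion_table,
             significant = x$significant, stringsAsFactors = FALSE)
}

#' Combine significant mediators
#'
#' Sums the unrounded indirect effects of the significant members (only
#' mediators whose both MR steps passed the Bonferroni gate contribute),
#' then decomposes the total as in [two_step_mediation()]: combined direct
#' `= c - sum`, combined adjusted OR `= exp(direct)`, with the table-view
#' proportion using the 3-dp-rounded combined indirect. With no
#' significant member an empty combined result (zero members, NA fields)
#' is returned, not an error.
#'
#' @param results list of `mediation_result`s.
#' @param total_c total causal effect.
#' @return A `combined_mediation` list.
#' @export
combine_mediators <- function(results, total_c) {
  sig <- Filter(function(r) isTRUE(r$significant), results)
  members <- vapply(sig, `[[`, character(1), "mediator")
  if (length(sig) == 0) {
    return(structure(list(members = character(0), n_members = 0L,
                          indirect = NA_real_, direct = NA_real_,
                          proportion = NA_real_, proportion_table = NA_real_,
                          adjusted_or = NA_real_, total = total_c),
                     class = "combined_mediation"))
  }
  indirect <- sum(vapply(sig, `[[`, numeric(1), "indirect"))
  direct <- total_c - indirect
  structure(list(members = members, n_members = length(sig),
                 indirect = indirect, direct = direct,
                 proportion = indirect / total_c,
                 proportion_table = round(indirect, 3) / total_c,
                 adjusted_or = exp(direct), total = total_c),
            class = "combined_mediation")
}

#' @export
print.combined_mediation <- function(x, ...) {
  if (x$n_members == 0) {
    cat("<combined_mediation> no significant mediators\n")
    return(invisible(x))
  }
  cat(sprintf("<combined_mediation> %s: indirect = %.3f, direct = %.3f, OR = %.2f, proportion = %.2f%%\n",
              paste(x$members, collapse = "+"), round(x$indirect, 3),
              round(x$direct, 3), round(x$adjusted_or, 2),
              100 * x$proportion_table))
  invisible(x)
}
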