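# Diagnostic screening arithmetic: likelihood ratios and prevalence-
# conditional post-test probabilities.

#' Likelihood ratios of a screening test
#'
#' Computes the positive and negative likelihood ratios from sensitivity and
#' specificity on the percent scale: `L+ = sens / (100 - spec)` and
#' `L- = spec / (100 - sens)`. A perfect sensitivity or specificity yields
#' an infinite ratio (flagged with a warning).
#'
#' @param sens,spec Sensitivity and specificity in percent (0-100) by
#'   default, or as proportions with `scale = "proportion"`.
#' @param scale Input scale.
#' @return Named numeric: L_plus, L_minus.
#' @examples
#' likelihood_ratios(93.8, 94.6)  # L+ ~ 17.37, L- ~ 15.26
#' @export
likelihood_ratios <- function(sens, spec, scale = c("percent", "proportion")) {
  scale <- match.arg(scale)
  if (scale == "proportion") { sens <- 100 * sens; spec <- 100 * spec }
  stopifnot(sens > 0, sens <= 100, spec > 0, spec <= 100)
  if (sens == 100 || spec == 100)
    warning("perfect sensitivity or specificity: infinite likelihood ratio")
  c(L_plus = sens / (100 - spec), L_minus = spec / (100 - sens))
}

#' Post-test probabilities of a screening test
#'
#' Converts a prior prevalence into post-test probabilities through the
#' likelihood ratios: the positive posterior odds of disease are
#' `L+ * prevalence/(1-prevalence)`, giving `P(D|+)`; the negative posterior
#' odds of non-disease are `L- * (1-prevalence)/prevalence`, giving
#' `P(N|-)`. The odds-form computation agrees with direct Bayes inversion to
#' machine precision.
#'
#' @param prevalence Prior disease probability in (0, 1).
#' @inheritParams likelihood_ratios
#' @return Object of class `screening_report` with fields prevalence,
#'   sensitivity, specificity (percent), L_plus, L_minus, r_prior_plus,
#'   r_post_plus, p_disease_given_pos, r_prior_minus, r_post_minus,
#'   p_nondisease_given_neg.
#' @examples
#' post_test(0.10, 93.8, 94.6)
#' @export
post_test <- function(prevalence, sens, spec,
                      scale = c("percent", "proportion")) {
  scale <- match.arg(scale)
  if (scale == "proportion") { sens <- 100 * sens; spec <- 100 * spec }
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly between 0 and 1")
  lr <- likelihood_ratios(sens, spec)
  r_prior_plus <- prevalence / (1 - prevalence)
  odds_to_p <- function(o) if (is.infinite(o)) 1 else o / (1 + o)
  r_post_plus <- lr[["L_plus"]] * r_prior_plus
  p_pos <- odds_to_p(r_post_plus)
  r_prior_minus <- (1 - prevalence) / prevalence
  r_post_minus <- lr[["L_minus"]] * r_prior_minus
  p_neg <- odds_to_p(r_post_minus)
  structure(list(prevalence = prevalence, sensitivity = sens,
                 specificity = spec,
                 L_plus = lr[["L_plus"]], L_minus = lr[["L_minus"]],
                 r_prior_plus = r_prior_plus, r_post_plus = r_post_plus,
                 p_disease_given_pos = p_pos,
                 r_prior_minus = r_prior_minus, r_post_minus = r_post_minus,
                 p_nondisease_given_neg = p_neg),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Screening report (prevalence %.1f%%, sensitivity %.1f%%, specificity %.1f%%)\n",
              100 * x$prevalence, x$sensitivity, x$specificity))
  cat(sprintf("  L+ = %.2f, L- = %.2f\n", x$L_plus, x$L_minus))
  cat(sprintf("  positive result: prior odds %.3f -> posterior odds %.2f -> P(affected | +) = %.3f\n",
              x$r_prior_plus, x$r_post_plus, x$p_disease_given_pos))
  cat(sprintf("  negative result: prior odds %.2f -> posterior odds %.2f -> P(unaffected | -) = %.3f\n",
              x$r_prior_minus, x$r_post_minus, x$p_nondisease_given_neg))
  invisible(x)
}
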