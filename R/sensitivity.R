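#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum_j w_j (\hat\theta_j - \theta_{ref})^2} over per-variant Wald
#' ratios with weights \eqn{w_j = se(\hat\theta_j)^{-2}}; p-value from the
#' chi-square distribution with J - 1 degrees of freedom.  By convention the
#' reference is the fixed-effect IVW estimate.
#'
#' @param instruments harmonized instruments (at least 2 rows).
#' @param theta_ref reference causal effect; default fixed-effect IVW.
#' @return list with \code{q}, \code{df}, \code{p}.
#' @export
cochran_q <- function(instruments, theta_ref = NULL) {
  .check_insts(instruments, 2, "cochran_q")
  if (is.null(theta_ref)) theta_ref <- ivw(instruments)$theta
  rs <- .ratio_stats(instruments)
  q <- sum(rs$se^-2 * (rs$ratio - theta_ref)^2)
  df <- nrow(instruments) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression with its standard error and
#' t-based p-value (J - 2 df).  p > 0.05 is read downstream as no evidence of
#' unbalanced horizontal pleiotropy.
#'
#' @param instruments harmonized instruments (at least 3 rows).
#' @return list with \code{intercept}, \code{se}, \code{p}.
#' @export
egger_intercept_test <- function(instruments) {
  est <- mr_egger(instruments)
  list(intercept = est$intercept, se = est$intercept_se, p = est$intercept_p)
}

#' Steiger directionality test for an instrument set
#'
#' Aggregates per-variant variance explained (\code{\link{variant_r2}}) over
#' the instruments for exposure and outcome; the causal direction is called
#' exposure-to-outcome iff the aggregate exposure R-squared exceeds the
#' outcome's.  The p-value applies the Fisher z-transformation two-correlation
#' z-test to the aggregate correlations \eqn{r = \sqrt{R^2}}, using the
#' harmonic-mean sample size per trait.
#'
#' @param instruments harmonized instruments with eaf and n for both traits.
#' @return list with \code{correct_direction}, \code{r2_exp}, \code{r2_out},
#'   \code{p}.
#' @export
steiger_directionality <- function(instruments) {
  x <- instruments
  if (any(is.na(x$eaf_exp)) || any(is.na(x$eaf_out)) ||
      any(is.na(x$n_exp)) || any(is.na(x$n_out)))
    stop("steiger_directionality requires eaf and n for both traits")
  r2_exp <- sum(variant_r2(x$beta_exp, pmin(x$eaf_exp, 1 - x$eaf_exp)))
  r2_out <- sum(variant_r2(x$beta_out, pmin(x$eaf_out, 1 - x$eaf_out)))
  hmean <- function(n) length(n) / sum(1 / n)
  st <- .steiger_test(min(r2_exp, 1), min(r2_out, 1),
                      hmean(x$n_exp), hmean(x$n_out))
  list(correct_direction = r2_exp > r2_out, r2_exp = r2_exp,
       r2_out = r2_out, p = st$p)
}

#' Leave-one-out analysis
#'
#' Refits the fixed-effect IVW estimate dropping each instrument in turn; a
#' single variant whose removal moves the estimate far flags single-variant
#' dominance.
#'
#' @param instruments harmonized instruments (at least 3 rows).
#' @return data frame with one row per dropped variant (\code{variant_id},
#'   \code{theta}, \code{se}, \code{pvalue}), in input order.
#' @export
leave_one_out <- function(instruments) {
  .check_insts(instruments, 3, "leave_one_out")
  rows <- lapply(seq_len(nrow(instruments)), function(i) {
    est <- ivw(instruments[-i, , drop = FALSE])
    data.frame(variant_id = instruments$variant_id[i], theta = est$theta,
               se = est$se, pvalue = est$pvalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sensitivity diagnostics for an instrument set
#'
#' Bundles Cochran's Q (at the fixed-effect IVW estimate), the MR-Egger
#' intercept test, the Steiger directionality test, and the leave-one-out
#' table, each computed when the instrument count permits.
#'
#' @param instruments harmonized instruments (at least 2 rows).
#' @param theta_ref reference effect for Q; default fixed-effect IVW.
#' @return object of class \code{mr_sensitivity}: \code{q}, \code{q_df},
#'   \code{q_p}; \code{egger_intercept}, \code{egger_intercept_se},
#'   \code{egger_intercept_p} (NA below 3 instruments);
#'   \code{steiger_correct_direction}, \code{steiger_p}; \code{loo_table}
#'   (NULL below 3 instruments).
#' @export
mr_sensitivity <- function(instruments, theta_ref = NULL) {
  .check_insts(instruments, 2, "mr_sensitivity")
  J <- nrow(instruments)
  q <- cochran_q(instruments, theta_ref)
  eg <- if (J >= 3) egger_intercept_test(instruments)
        else list(intercept = NA_real_, se = NA_real_, p = NA_real_)
  st <- tryCatch(steiger_directionality(instruments),
                 error = function(e) list(correct_direction = NA, p = NA_real_))
  loo <- if (J >= 3) leave_one_out(instruments) else NULL
  structure(list(q = q$q, q_df = q$df, q_p = q$p,
                 egger_intercept = eg$intercept,
                 egger_intercept_se = eg$se, egger_intercept_p = eg$p,
                 steiger_correct_direction = st$correct_direction,
                 steiger_p = st$p, loo_table = loo, n_snps = J),
            class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("Sensitivity diagnostics\n")
  cat(sprintf("  Cochran Q = %.3f (df %d), p = %.3g\n", x$q, x$q_df, x$q_p))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  Egger intercept = %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  cat(sprintf("  Steiger: correct direction = %s, p = %.3g\n",
              x$steiger_correct_direction, x$steiger_p))
  if (!is.null(x$loo_table))
    cat(sprintf("  Leave-one-out: theta range [%.4f, %.4f] over %d refits\n",
                min(x$loo_table$theta), max(x$loo_table$theta),
                nrow(x$loo_table)))
  invisible(x)
}

#' @export
as.data.frame.mr_sensitivity <- function(x, ...) {
  data.frame(n_snps = x$n_snps, q = x$q, q_df = x$q_df, q_p = x$q_p,
             egger_intercept = x$egger_intercept,
             egger_intercept_se = x$egger_intercept_se,
             egger_intercept_p = x$egger_intercept_p,
             steiger_correct_direction = x$steiger_correct_direction,
             steiger_p = x$steiger_p, stringsAsFactors = FALSE)
}
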