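new_mr_estimate <- function(method, theta, se, n_snps, df = NULL,
                            intercept = NULL, intercept_se = NULL,
                            intercept_p = NULL) {
  crit <- if (is.null(df)) stats::qnorm(0.975) else stats::qt(0.975, df)
  p <- if (is.null(df)) 2 * stats::pnorm(-abs(theta / se))
       else 2 * stats::pt(-abs(theta / se), df)
  est <- list(method = method, theta = theta, se = se,
              ci_low = theta - crit * se, ci_high = theta + crit * se,
              or_point = exp(theta), or_low = exp(theta - crit * se),
              or_high = exp(theta + crit * se),
              pvalue = max(p, .Machine$double.xmin), n_snps = n_snps,
              intercept = intercept, intercept_se = intercept_se,
              intercept_p = intercept_p)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNP%s): theta = %.4f (se %.4f), OR %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
              x$theta, x$se, x$or_point, x$or_low, x$or_high, x$pvalue))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, theta = x$theta,
             se = x$se, ci_low = x$ci_low, ci_high = x$ci_high,
             or = x$or_point, or_low = x$or_low, or_high = x$or_high,
             pvalue = x$pvalue,
             intercept = if (is.null(x$intercept)) NA_real_ else x$intercept,
             intercept_se = if (is.null(x$intercept_se)) NA_real_ else x$intercept_se,
             intercept_p = if (is.null(x$intercept_p)) NA_real_ else x$intercept_p,
             stringsAsFactors = FALSE)
}

.check_insts <- function(instruments, min_n, fun) {
  stopifnot(is.data.frame(instruments))
  if (nrow(instruments) < min_n)
    stop(fun, " requires at least ", min_n, " instrument",
         if (min_n > 1) "s" else "")
  if (any(instruments$se_exp <= 0) || any(instruments$se_out <= 0))
    stop("instrument standard errors must be positive")
}

#' Wald ratio estimate from a single instrument
#'
#' \eqn{\hat\theta = \hat\beta_Y / \hat\beta_X} with approximate standard
#' error \eqn{|se(\hat\beta_Y) / \hat\beta_X|} (first order, exposure effect
#' treated as fixed).
#'
#' @param instrument a one-row harmonized instrument data frame.
#' @return an \code{mr_estimate}.
#' @export
wald_ratio <- function(instrument) {
  .check_insts(instrument, 1, "wald_ratio")
  if (nrow(instrument) != 1L) stop("wald_ratio takes exactly one instrument")
  bx <- instrument$beta_exp
  if (bx == 0) stop("wald_ratio undefined for beta_exp = 0")
  new_mr_estimate("wald_ratio", instrument$beta_out / bx,
                  abs(instrument$se_out / bx), 1L)
}

.ratio_stats <- function(instruments) {
  bx <- instruments$beta_exp
  if (any(bx == 0)) stop("ratio undefined for beta_exp = 0")
  list(ratio = instruments$beta_out / bx,
       se = abs(instruments$se_out / bx))
}

#' Inverse-variance-weighted estimate
#'
#' Fixed-effect meta-analysis of per-variant Wald ratios with weights
#' \eqn{se(\hat\beta_{Yj})^{-2}}:
#' \deqn{\hat\theta_{IVW} = \frac{\sum_j \hat\beta_{Yj}\hat\beta_{Xj}
#'   se(\hat\beta_{Yj})^{-2}}{\sum_j \hat\beta_{Xj}^2 se(\hat\beta_{Yj})^{-2}},
#'   \quad se = \Big(\sum_j \hat\beta_{Xj}^2 se(\hat\beta_{Yj})^{-2}\Big)^{-1/2}.}
#' The multiplicative random-effects variant inflates the standard error by
#' \eqn{\sqrt{\max(1, Q/(J-1))}} where Q is Cochran's statistic at the fixed
#' estimate.
#'
#' @param instruments harmonized instruments (at least 2 rows).
#' @param model \code{"fixed"} (default, the primary analysis) or
#'   \code{"multiplicative_random"}.
#' @return an \code{mr_estimate}.
#' @export
ivw <- function(instruments, model = c("fixed", "multiplicative_random")) {
  model <- match.arg(model)
  .check_insts(instruments, 2, "ivw")
  bx <- instruments$beta_exp
  by <- instruments$beta_out
  w <- instruments$se_out^-2
  if (any(bx == 0)) stop("ivw requires all beta_exp != 0")
  denom <- sum(bx^2 * w)
  theta <- sum(by * bx * w) / denom
  se <- 1 / sqrt(denom)
  if (model == "multiplicative_random") {
    rs <- .ratio_stats(instruments)
    q <- sum(rs$se^-2 * (rs$ratio - theta)^2)
    se <- se * sqrt(max(1, q / (nrow(instruments) - 1)))
  }
  new_mr_estimate(if (model == "fixed") "ivw_fixed" else "ivw_mre",
                  theta, se, nrow(instruments))
}

#' Weighted-median estimate
#'
#' Orders the per-variant Wald ratios and takes the value at which the
#' cumulative normalized inverse-variance weight (percentile convention:
#' cumulative weight minus half each variant's own weight) crosses 0.5,
#' linearly interpolating between the bracketing ratios.  Consistent when
#' instruments carrying at least half of the weight are valid.  The standard
#' error comes from a parametric bootstrap: exposure and outcome betas are
#' resampled from normal distributions centred on the estimates with their
#' standard errors, the weighted median recomputed, and the SD taken over
#' \code{n_boot} replicates.
#'
#' @param instruments harmonized instruments (at least 3 rows).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; mandatory for reproducibility.
#' @return an \code{mr_estimate}.
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed) {
  .check_insts(instruments, 3, "weighted_median")
  if (missing(seed)) stop("weighted_median requires an explicit seed")
  point <- .weighted_median_point(instruments$beta_exp, instruments$beta_out,
                                  instruments$se_out)
  boot <- with_preserved_seed(seed, {
    J <- nrow(instruments)
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(J, instruments$beta_exp, instruments$se_exp)
      by <- stats::rnorm(J, instruments$beta_out, instruments$se_out)
      .weighted_median_point(bx, by, instruments$se_out)
    }, numeric(1))
  })
  new_mr_estimate("weighted_median", point, stats::sd(boot),
                  nrow(instruments))
}

.weighted_median_point <- function(bx, by, se_out) {
  if (any(bx == 0)) bx[bx == 0] <- .Machine$double.eps
  ratio <- by / bx
  w <- (se_out / bx)^-2
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(ratio[1])
  if (s[length(s)] < 0.5) return(ratio[length(s)])
  below <- max(which(s < 0.5))
  ratio[below] + (ratio[below + 1] - ratio[below]) *
    (0.5 - s[below]) / (s[below + 1] - s[below])
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects with
#' an unconstrained intercept, weights \eqn{se(\hat\beta_{Yj})^{-2}}, after
#' orienting each instrument so its exposure effect is non-negative.  The
#' slope estimates the causal effect under the InSIDE assumption; a nonzero
#' intercept indicates directional horizontal pleiotropy.  Inference uses the
#' t distribution with J - 2 degrees of freedom.
#'
#' @param instruments harmonized instruments (at least 3 rows).
#' @return an \code{mr_estimate} with slope as \code{theta} and the intercept
#'   fields filled in.
#' @export
mr_egger <- function(instruments) {
  .check_insts(instruments, 3, "mr_egger")
  s <- ifelse(instruments$beta_exp < 0, -1, 1)
  bx <- s * instruments$beta_exp
  by <- s * instruments$beta_out
  if (stats::var(bx) == 0) stop("mr_egger degenerate: no variance in beta_exp")
  fit <- stats::lm(by ~ bx, weights = instruments$se_out^-2)
  cf <- summary(fit)$coefficients
  df <- nrow(instruments) - 2L
  new_mr_estimate("mr_egger", cf["bx", 1], cf["bx", 2],
                  nrow(instruments), df = df,
                  intercept = cf["(Intercept)", 1],
                  intercept_se = cf["(Intercept)", 2],
                  intercept_p = max(2 * stats::pt(-abs(cf["(Intercept)", 1] /
                                                       cf["(Intercept)", 2]), df),
                                    .Machine$double.xmin))
}

#' Method-selection rule for the primary estimate
#'
#' One instrument: Wald ratio.  Two or more: fixed-effect IVW.
#'
#' @param instruments harmonized instruments (at least 1 row).
#' @return an \code{mr_estimate}.
#' @export
estimate_auto <- function(instruments) {
  .check_insts(instruments, 1, "estimate_auto")
  if (nrow(instruments) == 1L) wald_ratio(instruments) else ivw(instruments)
}
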