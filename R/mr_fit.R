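#' Fit two-sample Mendelian randomization estimators
#'
#' The central model-fitting function.  Given a set of harmonized
#' instruments, computes the primary causal-effect estimate (Wald ratio for a
#' single instrument, fixed-effect IVW otherwise) together with the
#' weighted-median and MR-Egger estimates where the instrument count permits
#' (3 or more), and sensitivity diagnostics (Cochran's Q, Egger intercept,
#' Steiger directionality, leave-one-out) where applicable.
#'
#' @param instruments harmonized instruments from \code{\link{harmonize}} or
#'   \code{\link{select_instruments}}.
#' @param methods character vector of estimators to fit; default picks the
#'   primary rule plus all alternatives the instrument count supports.
#'   Recognised: \code{"auto"}, \code{"wald_ratio"}, \code{"ivw"},
#'   \code{"ivw_mre"}, \code{"weighted_median"}, \code{"mr_egger"}.
#' @param seed RNG seed for the weighted-median bootstrap.
#' @param n_boot weighted-median bootstrap replicates.
#' @param sensitivity compute diagnostics (default \code{TRUE} when the
#'   instrument count allows any).
#' @return object of class \code{mr_fit}: list with \code{estimates} (named
#'   list of \code{mr_estimate}), \code{table} (one row per estimator),
#'   \code{instruments}, \code{sensitivity} (an \code{mr_sensitivity} or
#'   \code{NULL}), and \code{call}.
#' @seealso \code{\link{wald_ratio}}, \code{\link{ivw}},
#'   \code{\link{weighted_median}}, \code{\link{mr_egger}},
#'   \code{\link{mr_sensitivity}}
#' @examples
#' sim <- simulate_two_sample(simulation_config(n_snps = 10, seed = 1))
#' h <- harmonize(sim$exposure, sim$outcome)
#' fit <- mr_fit(h$instruments, seed = 1)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
mr_fit <- function(instruments, methods = NULL, seed = 1, n_boot = 1000,
                   sensitivity = TRUE) {
  .check_insts(instruments, 1, "mr_fit")
  J <- nrow(instruments)
  if (is.null(methods)) {
    methods <- "auto"
    if (J >= 3) methods <- c(methods, "weighted_median", "mr_egger")
  }
  ests <- list()
  for (m in methods) {
    est <- switch(m,
      auto = estimate_auto(instruments),
      wald_ratio = wald_ratio(instruments),
      ivw = ivw(instruments, "fixed"),
      ivw_mre = ivw(instruments, "multiplicative_random"),
      weighted_median = weighted_median(instruments, n_boot = n_boot,
                                        seed = derive_seed(seed, 1L)),
      mr_egger = mr_egger(instruments),
      stop("unknown method: ", m))
    ests[[est$method]] <- est
  }
  sens <- NULL
  if (isTRUE(sensitivity) && J >= 2) {
    sens <- tryCatch(mr_sensitivity(instruments), error = function(e) NULL)
  }
  out <- list(estimates = ests,
              table = do.call(rbind, lapply(ests, as.data.frame)),
              instruments = instruments, sensitivity = sens,
              call = match.call())
  rownames(out$table) <- NULL
  class(out) <- "mr_fit"
  out
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat("Two-sample Mendelian randomization fit\n")
  cat(sprintf("Instruments: %d\n\n", nrow(x$instruments)))
  tab <- x$table
  tab$or_ci <- sprintf(paste0("%.", digits, "f [%.", digits, "f, %.", digits, "f]"),
                       tab$or, tab$or_low, tab$or_high)
  show <- data.frame(method = tab$method, n_snps = tab$n_snps,
                     theta = round(tab$theta, 4), se = round(tab$se, 4),
                     `OR [95% CI]` = tab$or_ci,
                     p = signif(tab$pvalue, 3), check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object, sensitivity = object$sensitivity),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$sensitivity)) {
    cat("\n")
    print(x$sensitivity)
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$table$theta, object$table$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  tab <- object$table
  out <- cbind(tab$ci_low, tab$ci_high)
  rownames(out) <- tab$method
  colnames(out) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Scatter plot of instrument effects with fitted slopes
#'
#' Outcome effects against exposure effects (oriented to non-negative
#' exposure effect) with one line per fitted estimator: through the origin
#' for Wald/IVW/weighted-median slopes, with intercept for MR-Egger.
#'
#' @param x an \code{mr_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.mr_fit <- function(x, ...) {
  s <- ifelse(x$instruments$beta_exp < 0, -1, 1)
  bx <- s * x$instruments$beta_exp
  by <- s * x$instruments$beta_out
  graphics::plot(bx, by, xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", pch = 19, ...)
  graphics::segments(bx, by - 1.96 * x$instruments$se_out,
                     bx, by + 1.96 * x$instruments$se_out, col = "grey60")
  cols <- stats::setNames(seq_along(x$estimates) + 1, names(x$estimates))
  for (m in names(x$estimates)) {
    est <- x$estimates[[m]]
    a <- if (is.null(est$intercept)) 0 else est$intercept
    graphics::abline(a = a, b = est$theta, col = cols[[m]], lwd = 2)
  }
  graphics::legend("topleft", legend = names(x$estimates), col = cols,
                   lwd = 2, bty = "n")
  invisible(x)
}

#' @export
residuals.mr_fit <- function(object, method = NULL, ...) {
  if (is.null(method)) method <- object$table$method[1]
  est <- object$estimates[[method]]
  a <- if (is.null(est$intercept)) 0 else est$intercept
  s <- ifelse(object$instruments$beta_exp < 0, -1, 1)
  s * object$instruments$beta_out -
    (a + est$theta * s * object$instruments$beta_exp)
}
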