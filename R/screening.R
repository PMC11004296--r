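#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone-enforced, capped at 1), order matching
#' the input.  Thin wrapper over \code{stats::p.adjust(method = "BH")} with
#' input validation.
#'
#' @param pvalues numeric vector, each in (0, 1].
#' @return adjusted p-values.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Apply the candidate-selection criteria to screening rows
#'
#' A screened exposure is a candidate when all applicable criteria hold
#' (strict inequalities): FDR-adjusted p below \code{fdr}; Egger intercept p
#' above \code{egger_alpha} (not applicable, flag \code{NA}, below 3
#' instruments); correct Steiger causal direction with Steiger p below
#' \code{steiger_alpha}; Cochran Q p above \code{q_alpha} (not applicable
#' below 2 instruments).
#'
#' @param rows screening table from \code{\link{screen_exposures}}.
#' @param fdr,egger_alpha,steiger_alpha,q_alpha thresholds.
#' @return \code{rows} with the flag columns (\code{fdr_pass},
#'   \code{egger_ok}, \code{direction_ok}, \code{steiger_ok}, \code{q_ok};
#'   \code{NA} = not applicable) and \code{candidate} recomputed.
#' @export
flag_candidates <- function(rows, fdr = 0.05, egger_alpha = 0.05,
                            steiger_alpha = 0.05, q_alpha = 0.05) {
  rows$fdr_pass <- !is.na(rows$p_adj) & rows$p_adj < fdr
  rows$egger_ok <- ifelse(is.na(rows$egger_intercept_p), NA,
                          rows$egger_intercept_p > egger_alpha)
  rows$direction_ok <- rows$steiger_correct_direction
  rows$steiger_ok <- !is.na(rows$steiger_p) & rows$steiger_p < steiger_alpha
  rows$q_ok <- ifelse(is.na(rows$q_p), NA, rows$q_p > q_alpha)
  ok <- function(flag) is.na(flag) | flag
  rows$candidate <- rows$fdr_pass &
    ok(rows$egger_ok) &
    !is.na(rows$direction_ok) & rows$direction_ok &
    rows$steiger_ok &
    ok(rows$q_ok)
  rows$candidate[is.na(rows$candidate)] <- FALSE
  rows
}

.screen_one <- function(exposure_id, exposure, outcome, ld, config, locus,
                        panel_id, seed) {
  row <- data.frame(exposure_id = exposure_id, panel_id = panel_id,
                    status = "ok", n_snps = 0L, method = NA_character_,
                    theta = NA_real_, se = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, or = NA_real_, or_low = NA_real_,
                    or_high = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                    q = NA_real_, q_p = NA_real_,
                    egger_intercept = NA_real_, egger_intercept_p = NA_real_,
                    steiger_correct_direction = NA, steiger_p = NA_real_,
                    stringsAsFactors = FALSE)
  sel <- tryCatch(select_instruments(exposure, outcome, ld, config, locus),
                  error = function(e) NULL)
  if (is.null(sel) || nrow(sel$instruments) == 0L) {
    row$status <- "no_valid_iv"
    return(row)
  }
  inst <- sel$instruments
  est <- estimate_auto(inst)
  row$n_snps <- nrow(inst)
  row$method <- est$method
  row$theta <- est$theta; row$se <- est$se
  row$ci_low <- est$ci_low; row$ci_high <- est$ci_high
  row$or <- est$or_point; row$or_low <- est$or_low; row$or_high <- est$or_high
  row$p_raw <- est$pvalue
  if (nrow(inst) >= 2) {
    sens <- mr_sensitivity(inst)
    row$q <- sens$q; row$q_p <- sens$q_p
    row$egger_intercept <- sens$egger_intercept
    row$egger_intercept_p <- sens$egger_intercept_p
    row$steiger_correct_direction <- sens$steiger_correct_direction
    row$steiger_p <- sens$steiger_p
  } else {
    st <- tryCatch(steiger_directionality(inst), error = function(e) NULL)
    if (!is.null(st)) {
      row$steiger_correct_direction <- st$correct_direction
      row$steiger_p <- st$p
    }
  }
  row
}

#' Screen many exposures against one outcome
#'
#' Runs the full single-exposure pipeline (instrument selection, primary
#' estimate by the 1-IV Wald / multi-IV IVW rule, sensitivity diagnostics)
#' for every exposure in the panel, then applies Benjamini-Hochberg FDR
#' within the panel across the exposures with at least one valid instrument
#' (exposures with none are reported with status \code{no_valid_iv} and
#' excluded from the FDR denominator) and the candidate-selection criteria.
#'
#' @param exposures named list of exposure variant-record tables, or a
#'   manifest data frame with columns \code{exposure_id}, \code{path} and
#'   optionally \code{chromosome}, \code{gene_start} (cis locus).
#' @param outcome outcome variant records.
#' @param ld optional \code{ld_table}.
#' @param config \code{\link{selection_config}}.
#' @param panel_id label recorded on every row; FDR is always within one
#'   call (one panel) only.
#' @param loci optional named list (by exposure id) of gene loci for cis
#'   filtering.
#' @param seed top-level seed (per-exposure seeds derived deterministically).
#' @return data frame of class \code{mr_screen}, one row per exposure.
#' @export
screen_exposures <- function(exposures, outcome, ld = NULL,
                             config = selection_config(), panel_id = "panel",
                             loci = NULL, seed = 1) {
  if (is.data.frame(exposures)) {
    manifest <- exposures
    stopifnot(all(c("exposure_id", "path") %in% names(manifest)))
    loci <- loci %||% .manifest_loci(manifest)
    exposures <- stats::setNames(
      lapply(manifest$path, read_sumstats), manifest$exposure_id)
  }
  if (length(exposures) == 0L) stop("empty exposure panel")
  ids <- names(exposures)
  if (is.null(ids)) stop("exposures must be named by exposure_id")
  rows <- lapply(seq_along(ids), function(i) {
    .screen_one(ids[i], exposures[[i]], outcome, ld, config,
                if (!is.null(loci)) loci[[ids[i]]] else NULL,
                panel_id, derive_seed(seed, i))
  })
  out <- do.call(rbind, rows)
  tested <- out$status == "ok"
  out$p_adj <- NA_real_
  if (any(tested)) out$p_adj[tested] <- adjust_fdr(out$p_raw[tested])
  out <- flag_candidates(out)
  rownames(out) <- NULL
  class(out) <- c("mr_screen", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.manifest_loci <- function(manifest) {
  if (!all(c("chromosome", "gene_start") %in% names(manifest))) return(NULL)
  loci <- lapply(seq_len(nrow(manifest)), function(i) {
    if (is.na(manifest$chromosome[i]) || is.na(manifest$gene_start[i])) NULL
    else list(chromosome = as.character(manifest$chromosome[i]),
              start_position = manifest$gene_start[i])
  })
  stats::setNames(loci, manifest$exposure_id)
}

#' @export
print.mr_screen <- function(x, ...) {
  cat(sprintf("Screening panel '%s': %d exposures (%d with valid IVs, %d candidates)\n",
              x$panel_id[1], nrow(x), sum(x$status == "ok"),
              sum(x$candidate)))
  if (any(x$candidate)) {
    cand <- x[x$candidate, c("exposure_id", "method", "n_snps", "or",
                             "p_raw", "p_adj")]
    cand$or <- round(cand$or, 3)
    cand$p_raw <- signif(cand$p_raw, 3)
    cand$p_adj <- signif(cand$p_adj, 3)
    print(as.data.frame(cand), row.names = FALSE)
  }
  invisible(x)
}
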