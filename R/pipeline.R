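# Result-bundle writers for the command-line verbs.  Numbers are written at
# full precision so identical seeds give byte-identical files; the rounded
# 3-decimal OR/CI columns in estimates.tsv follow the conventional reporting
# style.

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    s <- formatC(v, digits = 15, format = "g")
    s[is.na(v)] <- NA
    trimws(s)
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}

#' Run the single-exposure analysis and write a results bundle
#'
#' Reads exposure and outcome summary statistics (and optionally an LD
#' table), selects instruments, fits the primary IVW (or Wald-ratio)
#' estimate with weighted-median and MR-Egger alongside, computes sensitivity
#' diagnostics, and writes tab-delimited outputs to \code{out_dir}:
#' \code{instruments.tsv}, \code{estimates.tsv}, \code{sensitivity.tsv},
#' \code{leave_one_out.tsv}, \code{scatter_data.tsv},
#' \code{selection_report.tsv} and \code{config.tsv} (the fully resolved
#' configuration, for reproducibility).  Inputs are validated before any
#' output is created, so failures leave no partial bundle.
#'
#' @param exposure_path,outcome_path summary-statistics file paths.
#' @param out_dir output directory (created if needed).
#' @param ld_path optional LD-table path.
#' @param config \code{\link{selection_config}}.
#' @param seed top-level seed controlling the weighted-median bootstrap.
#' @param n_boot bootstrap replicates.
#' @return invisibly, a list with the fit, instruments, sensitivity and the
#'   output paths.  Signals a condition of class \code{mrscreen_no_iv} when
#'   no instrument survives selection and \code{mrscreen_io} for input
#'   problems.
#' @export
run_estimate <- function(exposure_path, outcome_path, out_dir,
                         ld_path = NULL, config = selection_config(),
                         seed = 1, n_boot = 1000) {
  io_fail <- function(msg) stop(structure(
    class = c("mrscreen_io", "error", "condition"),
    list(message = msg, call = sys.call(-1))))
  for (p in c(exposure_path, outcome_path, ld_path))
    if (!file.exists(p)) io_fail(paste0("input file not found: ", p))
  exposure <- read_sumstats(exposure_path)
  outcome <- read_sumstats(outcome_path)
  ld <- if (!is.null(ld_path)) read_ld_table(ld_path) else NULL

  sel <- select_instruments(exposure, outcome, ld, config)
  if (nrow(sel$instruments) == 0L)
    stop(structure(class = c("mrscreen_no_iv", "error", "condition"),
                   list(message = "no valid instruments survived selection",
                        call = sys.call())))
  fit <- mr_fit(sel$instruments, seed = seed, n_boot = n_boot)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    instruments = file.path(out_dir, "instruments.tsv"),
    estimates = file.path(out_dir, "estimates.tsv"),
    sensitivity = file.path(out_dir, "sensitivity.tsv"),
    leave_one_out = file.path(out_dir, "leave_one_out.tsv"),
    scatter = file.path(out_dir, "scatter_data.tsv"),
    selection = file.path(out_dir, "selection_report.tsv"),
    config = file.path(out_dir, "config.tsv"))

  .write_tsv(fit$instruments, paths$instruments)
  est <- fit$table
  for (col in c("or", "or_low", "or_high")) est[[col]] <- round(est[[col]], 3)
  .write_tsv(est, paths$estimates)
  if (!is.null(fit$sensitivity))
    .write_tsv(as.data.frame(fit$sensitivity), paths$sensitivity)
  if (!is.null(fit$sensitivity) && !is.null(fit$sensitivity$loo_table))
    .write_tsv(fit$sensitivity$loo_table, paths$leave_one_out)
  s <- ifelse(fit$instruments$beta_exp < 0, -1, 1)
  .write_tsv(data.frame(variant_id = fit$instruments$variant_id,
                        beta_exp = s * fit$instruments$beta_exp,
                        se_exp = fit$instruments$se_exp,
                        beta_out = s * fit$instruments$beta_out,
                        se_out = fit$instruments$se_out,
                        stringsAsFactors = FALSE), paths$scatter)
  .write_tsv(sel$report, paths$selection)
  cfgdf <- data.frame(key = names(unclass(config)),
                      value = vapply(unclass(config), function(v)
                        paste(format(v), collapse = ","), character(1)),
                      stringsAsFactors = FALSE)
  cfgdf <- rbind(cfgdf, data.frame(key = c("seed", "n_boot"),
                                   value = c(format(seed), format(n_boot))))
  .write_tsv(cfgdf, paths$config)
  invisible(list(fit = fit, selection = sel, paths = paths))
}

#' Screen a manifest of exposures and write a screening bundle
#'
#' Reads a tab-delimited manifest (columns \code{exposure_id}, \code{path},
#' optional \code{chromosome} and \code{gene_start} for cis loci), screens
#' every exposure against the outcome, and writes \code{screening.tsv} (all
#' rows), \code{candidates.tsv} (rows with \code{candidate = TRUE}) and a
#' stage-count summary to \code{out_dir}.  Per-exposure results are saved
#' under \code{out_dir/progress/} as they complete; with
#' \code{resume = TRUE} (default) a re-run skips completed exposures, so an
#' interrupted screen restarts where it stopped.  FDR and candidate flags
#' are always recomputed over the assembled panel.
#'
#' @param manifest_path manifest file path.
#' @param outcome_path outcome summary-statistics path.
#' @param out_dir output directory.
#' @param ld_path optional LD-table path.
#' @param config \code{\link{selection_config}}.
#' @param panel_id panel label (FDR family).
#' @param seed top-level seed.
#' @param resume skip exposures with a completed progress file.
#' @return invisibly, the screening table.
#' @export
run_screen <- function(manifest_path, outcome_path, out_dir, ld_path = NULL,
                       config = selection_config(), panel_id = "panel",
                       seed = 1, resume = TRUE) {
  if (!file.exists(manifest_path)) stop(structure(
    class = c("mrscreen_io", "error", "condition"),
    list(message = paste0("manifest not found: ", manifest_path), call = NULL)))
  manifest <- utils::read.delim(manifest_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  stopifnot(all(c("exposure_id", "path") %in% names(manifest)))
  if (nrow(manifest) == 0L) stop("empty manifest")
  outcome <- read_sumstats(outcome_path)
  ld <- if (!is.null(ld_path)) read_ld_table(ld_path) else NULL
  loci <- .manifest_loci(manifest)

  prog_dir <- file.path(out_dir, "progress")
  dir.create(prog_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$exposure_id[i]
    prog <- file.path(prog_dir, paste0(id, ".tsv"))
    if (resume && file.exists(prog)) {
      rows[[i]] <- utils::read.delim(prog, stringsAsFactors = FALSE,
                                     colClasses = .screen_col_classes)
      next
    }
    exposure <- read_sumstats(manifest$path[i])
    row <- .screen_one(id, exposure, outcome, ld, config,
                       if (!is.null(loci)) loci[[id]] else NULL,
                       panel_id, derive_seed(seed, i))
    .write_tsv(row, prog)
    rows[[i]] <- utils::read.delim(prog, stringsAsFactors = FALSE,
                                   colClasses = .screen_col_classes)
  }
  out <- do.call(rbind, rows)
  tested <- out$status == "ok"
  out$p_adj <- NA_real_
  if (any(tested)) out$p_adj[tested] <- adjust_fdr(out$p_raw[tested])
  out <- flag_candidates(out)
  class(out) <- c("mr_screen", "data.frame")

  .write_tsv(out, file.path(out_dir, "screening.tsv"))
  .write_tsv(out[out$candidate, , drop = FALSE],
             file.path(out_dir, "candidates.tsv"))
  summary_df <- data.frame(
    metric = c("n_exposures", "n_with_valid_iv", "n_no_valid_iv",
               "n_fdr_pass", "n_candidates"),
    value = c(nrow(out), sum(tested), sum(!tested),
              sum(out$fdr_pass, na.rm = TRUE), sum(out$candidate)),
    stringsAsFactors = FALSE)
  .write_tsv(summary_df, file.path(out_dir, "summary.tsv"))
  invisible(out)
}

.screen_col_classes <- c(
  exposure_id = "character", panel_id = "character", status = "character",
  n_snps = "integer", method = "character", theta = "numeric",
  se = "numeric", ci_low = "numeric", ci_high = "numeric", or = "numeric",
  or_low = "numeric", or_high = "numeric", p_raw = "numeric",
  p_adj = "numeric", q = "numeric", q_p = "numeric",
  egger_intercept = "numeric", egger_intercept_p = "numeric",
  steiger_correct_direction = "logical", steiger_p = "numeric")
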