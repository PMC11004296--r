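#' Variance explained by a single variant
#'
#' R-squared of a variant under the standard per-allele model,
#' \eqn{R^2 = 2 \beta^2 \mathrm{MAF} (1 - \mathrm{MAF})}, with beta on the
#' standardized (SD-unit, or log-odds for binary traits) scale.
#'
#' @param beta per-allele effect estimate.
#' @param maf minor-allele frequency in [0, 0.5]; compute as
#'   \code{pmin(eaf, 1 - eaf)} upstream.
#' @return variance explained (vectorized).
#' @export
variant_r2 <- function(beta, maf) {
  if (any(is.na(maf)) || any(maf < 0) || any(maf > 0.5))
    stop("maf must lie in [0, 0.5]")
  2 * beta^2 * maf * (1 - maf)
}

#' Instrument-strength F statistic
#'
#' \eqn{F = \frac{N - K - 1}{K} \cdot \frac{R^2}{1 - R^2}} for \code{k}
#' instruments jointly explaining \code{r2_total} of the exposure variance in
#' a sample of \code{n}.  With \code{k = 1} and a single variant's R-squared
#' this is the per-SNP weak-instrument statistic (F > 10 conventional bar).
#'
#' @param n exposure GWAS sample size.
#' @param k number of instruments.
#' @param r2_total variance explained jointly, in [0, 1).
#' @return F statistic (vectorized over \code{n} and \code{r2_total}).
#' @export
f_statistic <- function(n, k = 1, r2_total) {
  if (any(r2_total < 0) || any(r2_total >= 1)) stop("r2_total must lie in [0, 1)")
  if (any(k < 1)) stop("k must be >= 1")
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  ((n - k - 1) / k) * (r2_total / (1 - r2_total))
}

#' Read a pairwise LD table
#'
#' Three tab-delimited columns: \code{id_a}, \code{id_b}, \code{r2}.  Absent
#' pairs are treated as r-squared 0 (independent) by consumers.
#'
#' @param path file path.
#' @return data frame of class \code{ld_table}.
#' @export
read_ld_table <- function(path) {
  x <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(x)[1:3] <- c("id_a", "id_b", "r2")
  as_ld_table(x)
}

#' Construct an LD table from pair data
#'
#' @param pairs data frame with columns \code{id_a}, \code{id_b}, \code{r2};
#'   may be empty or \code{NULL} (no LD, all pairs independent).
#' @return data frame of class \code{ld_table}.
#' @export
as_ld_table <- function(pairs = NULL) {
  if (is.null(pairs))
    pairs <- data.frame(id_a = character(), id_b = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  stopifnot(all(c("id_a", "id_b", "r2") %in% names(pairs)))
  if (any(pairs$r2 < 0 | pairs$r2 > 1)) stop("r2 must lie in [0, 1]")
  structure(pairs, class = c("ld_table", "data.frame"))
}

# symmetric lookup environment keyed "min|max"
.ld_env <- function(ld) {
  e <- new.env(hash = TRUE, parent = emptyenv())
  if (!is.null(ld) && nrow(ld)) {
    key <- paste(pmin(ld$id_a, ld$id_b), pmax(ld$id_a, ld$id_b), sep = "|")
    for (i in seq_along(key)) assign(key[i], ld$r2[i], envir = e)
  }
  e
}

.ld_r2 <- function(env, a, b) {
  if (a == b) return(1)
  v <- get0(paste(min(a, b), max(a, b), sep = "|"), envir = env)
  if (is.null(v)) 0 else v
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unprocessed variant with the smallest p-value (ties
#' broken by lexicographic \code{variant_id}), keeps it as an index, and
#' removes every unprocessed variant on the same chromosome within
#' \code{window_kb} kilobases whose pairwise r-squared with the index exceeds
#' \code{r2_threshold}.  Pairs absent from the LD table count as independent.
#'
#' @param records variant records with \code{chromosome}, \code{position},
#'   \code{pvalue} columns.
#' @param ld \code{ld_table} (or \code{NULL} for no LD).
#' @param r2_threshold pairwise r-squared above which variants are pruned.
#' @param window_kb maximum pairwise distance, in kilobases, at which pruning
#'   applies.
#' @return the kept records, in input order.
#' @export
ld_clump <- function(records, ld = NULL, r2_threshold = 0.001,
                     window_kb = 10000) {
  if (nrow(records) == 0L) return(records)
  env <- .ld_env(ld)
  p <- records$pvalue
  # recompute from beta/se when the p column is absent
  if (all(is.na(p))) p <- 2 * stats::pnorm(-abs(records$beta / records$se))
  ord <- order(p, records$variant_id)
  alive <- rep(TRUE, nrow(records))
  kept <- logical(nrow(records))
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & records$chromosome == records$chromosome[i] &
                  abs(records$position - records$position[i]) <= window_kb * 1000)
    for (j in cand) {
      if (.ld_r2(env, records$variant_id[i], records$variant_id[j]) > r2_threshold)
        alive[j] <- FALSE
    }
  }
  out <- records[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Fisher z-test comparing two variance-explained correlations.
# Two-sided p; z > 0 when r_exp > r_out.
.steiger_test <- function(r2_exp, r2_out, n_exp, n_out) {
  r_exp <- sqrt(pmin(r2_exp, 1 - 1e-12))
  r_out <- sqrt(pmin(r2_out, 1 - 1e-12))
  z <- (atanh(r_exp) - atanh(r_out)) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(z = z, p = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin))
}

#' Steiger directionality filter
#'
#' Retains instruments that explain substantially more variance in the
#' exposure than in the outcome: per variant, exposure and outcome R-squared
#' are computed from the (standardized) betas and allele frequencies via
#' \code{\link{variant_r2}}; the direction is correct iff
#' \eqn{R^2_{exp} > R^2_{out}}, and the p-value comes from a Fisher
#' z-transformation z-test comparing the two correlations \eqn{r = \sqrt{R^2}}
#' at the two sample sizes.  Variants with correct direction and
#' \code{p < alpha} are kept.
#'
#' @param instruments harmonized instruments (from \code{\link{harmonize}}).
#' @param alpha significance level (default 0.05).
#' @return list with \code{instruments} (kept rows) and \code{detail}
#'   (per-variant R-squareds, direction, p, kept flag).
#' @export
steiger_filter <- function(instruments, alpha = 0.05) {
  x <- instruments
  if (any(is.na(x$eaf_exp)) || any(is.na(x$eaf_out)) ||
      any(is.na(x$n_exp)) || any(is.na(x$n_out)))
    stop("steiger_filter requires eaf and n for both traits")
  r2_exp <- variant_r2(x$beta_exp, pmin(x$eaf_exp, 1 - x$eaf_exp))
  r2_out <- variant_r2(x$beta_out, pmin(x$eaf_out, 1 - x$eaf_out))
  st <- .steiger_test(r2_exp, r2_out, x$n_exp, x$n_out)
  correct <- r2_exp > r2_out
  kept <- correct & st$p < alpha
  detail <- data.frame(variant_id = x$variant_id, r2_exp = r2_exp,
                       r2_out = r2_out, correct_direction = correct,
                       steiger_p = st$p, kept = kept,
                       stringsAsFactors = FALSE)
  out <- x[kept, , drop = FALSE]
  rownames(out) <- NULL
  list(instruments = out, detail = detail)
}

#' Instrument-selection configuration
#'
#' Defaults follow standard two-sample MR practice: genome-wide significance
#' 5e-8, clumping at pairwise r-squared 0.001 within 10,000 kb, per-SNP
#' F > 10, Steiger filtering at p < 0.05, and a 1 Mb cis window when cis
#' filtering is requested.
#'
#' @param p_threshold exposure p-value threshold.
#' @param clump_r2,clump_window_kb LD-clumping parameters.
#' @param f_min minimum per-variant F statistic.
#' @param steiger_alpha Steiger filter significance level; values >= 1
#'   disable the filter.
#' @param cis_mode \code{"all"} (no positional filter), \code{"cis_only"}
#'   (keep variants within \code{cis_window_bp} of the gene start), or
#'   \code{"cis_and_trans"} (no positional filter; both used, as for cytokine
#'   panels).
#' @param cis_window_bp cis window half-width in base pairs.
#' @param exclusion_list character vector of variant_ids to remove (e.g.
#'   confounder-associated variants identified externally).
#' @param palindromic_policy,af_window,infer_strand passed to
#'   \code{\link{harmonize}}.
#' @return list of class \code{selection_config}.
#' @export
selection_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                             clump_window_kb = 10000, f_min = 10,
                             steiger_alpha = 0.05,
                             cis_mode = c("all", "cis_only", "cis_and_trans"),
                             cis_window_bp = 1e6,
                             exclusion_list = character(),
                             palindromic_policy = "drop_intermediate_af",
                             af_window = 0.08, infer_strand = TRUE) {
  cis_mode <- match.arg(cis_mode)
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1, f_min >= 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min,
                 steiger_alpha = steiger_alpha, cis_mode = cis_mode,
                 cis_window_bp = cis_window_bp,
                 exclusion_list = as.character(exclusion_list),
                 palindromic_policy = palindromic_policy,
                 af_window = af_window, infer_strand = infer_strand),
            class = "selection_config")
}

#' Select instrumental variables for one exposure
#'
#' Applies the selection cascade in order: exposure significance threshold,
#' optional cis window, exclusion list, greedy LD clumping, harmonization
#' onto the outcome, per-variant F filter (k = 1, each variant's own
#' R-squared and the exposure sample size), and the Steiger directionality
#' filter.  Counts surviving each stage are reported.
#'
#' @param exposure,outcome validated variant records.
#' @param ld optional \code{ld_table}.
#' @param config \code{\link{selection_config}}.
#' @param locus optional gene locus (list or one-row data frame with
#'   \code{chromosome} and \code{start_position}) for cis filtering.
#' @return list with \code{instruments} (harmonized, surviving all filters),
#'   \code{report} (stage counts), \code{steiger} (per-variant detail) and
#'   \code{audit} (harmonization audit).
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               config = selection_config(), locus = NULL) {
  report <- data.frame(stage = character(), n = integer(),
                       stringsAsFactors = FALSE)
  note <- function(stage, n) {
    report <<- rbind(report, data.frame(stage = stage, n = n,
                                        stringsAsFactors = FALSE))
  }
  note("input", nrow(exposure))

  p <- exposure$pvalue
  miss <- is.na(p)
  if (any(miss))
    p[miss] <- 2 * stats::pnorm(-abs(exposure$beta[miss] / exposure$se[miss]))
  x <- exposure[p < config$p_threshold, , drop = FALSE]
  note("p_threshold", nrow(x))

  if (config$cis_mode == "cis_only") {
    if (is.null(locus)) stop("cis_mode = 'cis_only' requires a gene locus")
    keep <- x$chromosome == as.character(locus$chromosome) &
      abs(x$position - locus$start_position) <= config$cis_window_bp
    x <- x[!is.na(keep) & keep, , drop = FALSE]
    note("cis_window", nrow(x))
  }

  x <- x[!x$variant_id %in% config$exclusion_list, , drop = FALSE]
  note("exclusion_list", nrow(x))

  x <- ld_clump(x, ld, config$clump_r2, config$clump_window_kb)
  note("ld_clump", nrow(x))

  h <- harmonize(x, outcome, palindromic_policy = config$palindromic_policy,
                 af_window = config$af_window,
                 infer_strand = config$infer_strand)
  inst <- h$instruments
  note("harmonized", nrow(inst))

  if (nrow(inst)) {
    maf <- pmin(inst$eaf_exp, 1 - inst$eaf_exp)
    r2 <- variant_r2(inst$beta_exp, maf)
    f <- ((inst$n_exp - 2) / 1) * (r2 / (1 - r2))
    inst$f_stat <- f
    inst <- inst[f >= config$f_min, , drop = FALSE]
    rownames(inst) <- NULL
  }
  note("f_filter", nrow(inst))

  steiger <- NULL
  # steiger_alpha >= 1 disables the filter (keep-everything limit)
  if (nrow(inst) && config$steiger_alpha < 1) {
    sf <- steiger_filter(inst, alpha = config$steiger_alpha)
    inst <- sf$instruments
    steiger <- sf$detail
  }
  note("steiger_filter", nrow(inst))

  list(instruments = inst, report = report, steiger = steiger,
       audit = h$audit)
}
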