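#' Default summary-statistics column mapping
#'
#' Maps the canonical internal field names onto the column names found in a
#' summary-statistics file.  Defaults follow GWAS-SSF-style headers.  Override
#' individual entries to read files with other dialects, e.g.
#' \code{sumstats_dialect(beta = "Effect", se = "StdErr")}.
#'
#' @param variant_id,chromosome,position,effect_allele,other_allele,eaf,beta,se,pvalue,n,n_cases
#'   column name in the file holding each field.  \code{pvalue}, \code{n_cases}
#'   and \code{eaf} may be \code{NA} to mark the column as absent.
#' @return named character vector mapping internal names to file columns.
#' @export
sumstats_dialect <- function(variant_id = "variant_id",
                             chromosome = "chromosome",
                             position = "base_pair_location",
                             effect_allele = "effect_allele",
                             other_allele = "other_allele",
                             eaf = "effect_allele_frequency",
                             beta = "beta",
                             se = "standard_error",
                             pvalue = "p_value",
                             n = "n",
                             n_cases = NA_character_) {
  c(variant_id = variant_id, chromosome = chromosome, position = position,
    effect_allele = effect_allele, other_allele = other_allele, eaf = eaf,
    beta = beta, se = se, pvalue = pvalue, n = n, n_cases = n_cases)
}

.sumstats_cols <- c("variant_id", "chromosome", "position", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "pvalue", "n",
                    "n_cases")

#' Validate variant records
#'
#' Applies the per-variant invariants (distinct alleles over {A,C,G,T},
#' se > 0, eaf in [0,1] or missing, position >= 1, p in (0,1] or missing,
#' n a positive integer) and drops violating rows.
#'
#' @param x data frame with the canonical summary-statistics columns.
#' @return the valid rows, with a \code{"drop_report"} attribute counting the
#'   rows removed per reason.
#' @export
validate_sumstats <- function(x) {
  stopifnot(is.data.frame(x))
  for (col in setdiff(.sumstats_cols, names(x))) x[[col]] <- NA
  x <- x[, .sumstats_cols]
  x$variant_id <- as.character(x$variant_id)
  x$chromosome <- as.character(x$chromosome)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("position", "eaf", "beta", "se", "pvalue", "n", "n_cases"))
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))

  bases <- c("A", "C", "G", "T")
  bad <- list(
    missing_id     = is.na(x$variant_id) | x$variant_id == "",
    bad_allele     = !(x$effect_allele %in% bases) | !(x$other_allele %in% bases),
    same_alleles   = !is.na(x$effect_allele) & !is.na(x$other_allele) &
                     x$effect_allele == x$other_allele,
    bad_se         = is.na(x$se) | x$se <= 0,
    missing_beta   = is.na(x$beta),
    bad_eaf        = !is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1),
    bad_position   = !is.na(x$position) & x$position < 1,
    bad_pvalue     = !is.na(x$pvalue) & (x$pvalue <= 0 | x$pvalue > 1),
    bad_n          = is.na(x$n) | x$n < 1 | x$n != round(x$n)
  )
  drop <- Reduce(`|`, bad)
  report <- vapply(bad, function(b) sum(b & !is.na(b)), integer(1))
  out <- x[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_report") <- report
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Read GWAS summary statistics
#'
#' Reads a tab-delimited (optionally gzip-compressed) summary-statistics file,
#' renames columns per the dialect, normalizes alleles to uppercase, and drops
#' rows violating the record invariants.
#'
#' @param path file path.
#' @param dialect column mapping from \code{\link{sumstats_dialect}}.
#' @return data frame of validated variant records (canonical columns), with a
#'   \code{"drop_report"} attribute.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect()) {
  if (!file.exists(path)) stop("summary-statistics file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("variant_id", "effect_allele", "other_allele", "beta", "se", "n")
  for (field in names(dialect)) {
    col <- dialect[[field]]
    if (is.na(col) || !col %in% names(raw)) {
      if (field %in% required)
        stop("required column '", col, "' (", field, ") absent in ", path)
      next
    }
    names(raw)[names(raw) == col] <- field
  }
  out <- validate_sumstats(raw)
  if (nrow(out) == 0L) stop("no valid variant records in ", path)
  out
}

#' Write GWAS summary statistics
#'
#' Writes records as a tab-delimited file using the dialect's column names.
#' \code{read_sumstats(write_sumstats(x, path))} reproduces \code{x}
#' field-for-field (numeric values to full double precision).
#'
#' @param records validated records (canonical columns).
#' @param path output path; \code{.gz} suffix writes gzip-compressed.
#' @param dialect column mapping used for the output header.
#' @return \code{path}, invisibly.
#' @export
write_sumstats <- function(records, path, dialect = sumstats_dialect()) {
  stopifnot(is.data.frame(records))
  out <- records[, intersect(.sumstats_cols, names(records)), drop = FALSE]
  # drop wholly-missing optional columns so the header mirrors the content
  for (col in c("n_cases", "pvalue", "eaf", "position", "chromosome"))
    if (col %in% names(out) && all(is.na(out[[col]]))) out[[col]] <- NULL
  header <- names(out)
  for (i in seq_along(header)) {
    mapped <- dialect[[header[i]]]
    if (!is.null(mapped) && !is.na(mapped)) header[i] <- mapped
  }
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    s <- formatC(v, digits = 17, format = "g")
    s[is.na(v)] <- NA
    trimws(s)
  })
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(out))
    utils::write.table(out, con, sep = "\t", quote = FALSE, na = "NA",
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.complement <- function(allele) chartr("ACGT", "TGCA", allele)

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every shared variant onto the exposure's
#' effect allele.  When the outcome's alleles are swapped relative to the
#' exposure, the outcome beta is negated and its allele frequency mirrored.
#' Non-palindromic variants whose alleles match only after complementing both
#' outcome alleles are treated as strand-flipped and aligned the same way
#' (controlled by \code{infer_strand}).  Palindromic variants (A/T or C/G)
#' cannot be strand-resolved from alleles alone and are handled per
#' \code{palindromic_policy}: under \code{"drop_intermediate_af"} (the
#' default) they are dropped when either allele frequency lies within
#' \code{af_window} of 0.5 or is missing; \code{"drop_all"} drops every
#' palindromic variant; \code{"keep"} keeps them as matched.
#'
#' @param exposure,outcome validated variant records; \code{variant_id} must be
#'   unique within each table.
#' @param palindromic_policy one of \code{"drop_intermediate_af"},
#'   \code{"drop_all"}, \code{"keep"}.
#' @param af_window half-width of the ambiguous allele-frequency band around
#'   0.5; must lie in [0, 0.5).
#' @param infer_strand attempt complementary-base matching for non-palindromic
#'   variants before dropping (default \code{TRUE}).
#' @return list with \code{instruments} (one row per kept variant: exposure and
#'   outcome betas/SEs/frequencies on the common effect allele, sample sizes,
#'   \code{palindromic} and \code{flipped} flags) and \code{audit} (one row per
#'   exposure variant: disposition \code{kept}, \code{flipped},
#'   \code{dropped_palindromic}, \code{dropped_allele_mismatch} or
#'   \code{dropped_missing_in_outcome}, with reason text).
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_policy = c("drop_intermediate_af",
                                             "drop_all", "keep"),
                      af_window = 0.08, infer_strand = TRUE) {
  palindromic_policy <- match.arg(palindromic_policy)
  stopifnot(af_window >= 0, af_window < 0.5)
  if (anyDuplicated(exposure$variant_id))
    stop("duplicate variant_id in exposure table")
  if (anyDuplicated(outcome$variant_id))
    stop("duplicate variant_id in outcome table")

  oidx <- match(exposure$variant_id, outcome$variant_id)
  n <- nrow(exposure)
  disposition <- character(n)
  reason <- character(n)
  keep <- logical(n)
  flipped <- logical(n)
  palin <- logical(n)
  beta_out <- se_out <- eaf_out <- n_out <- n_cases_out <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    j <- oidx[i]
    if (is.na(j)) {
      disposition[i] <- "dropped_missing_in_outcome"
      reason[i] <- "variant absent from outcome table"
      next
    }
    ea_x <- exposure$effect_allele[i]; oa_x <- exposure$other_allele[i]
    ea_y <- outcome$effect_allele[j];  oa_y <- outcome$other_allele[j]
    palin[i] <- .is_palindromic(ea_x, oa_x)

    flip <- NA  # FALSE = same orientation, TRUE = swapped, NA = no match
    if (ea_y == ea_x && oa_y == oa_x) flip <- FALSE
    else if (ea_y == oa_x && oa_y == ea_x) flip <- TRUE
    else if (infer_strand && !palin[i]) {
      cea <- .complement(ea_y); coa <- .complement(oa_y)
      if (cea == ea_x && coa == oa_x) flip <- FALSE
      else if (cea == oa_x && coa == ea_x) flip <- TRUE
    }
    if (is.na(flip)) {
      disposition[i] <- "dropped_allele_mismatch"
      reason[i] <- sprintf("exposure %s/%s vs outcome %s/%s irreconcilable",
                           ea_x, oa_x, ea_y, oa_y)
      next
    }

    eaf_y <- if (flip) 1 - outcome$eaf[j] else outcome$eaf[j]
    if (palin[i] && palindromic_policy != "keep") {
      ambiguous <- palindromic_policy == "drop_all" ||
        is.na(exposure$eaf[i]) || is.na(eaf_y) ||
        abs(exposure$eaf[i] - 0.5) <= af_window ||
        abs(eaf_y - 0.5) <= af_window
      if (ambiguous) {
        disposition[i] <- "dropped_palindromic"
        reason[i] <- if (palindromic_policy == "drop_all")
          "palindromic variant (policy drop_all)"
        else "palindromic variant with intermediate or missing allele frequency"
        next
      }
    }

    keep[i] <- TRUE
    flipped[i] <- flip
    disposition[i] <- if (flip) "flipped" else "kept"
    reason[i] <- if (flip) "outcome alleles swapped; effect aligned" else "alleles concordant"
    beta_out[i] <- if (flip) -outcome$beta[j] else outcome$beta[j]
    se_out[i] <- outcome$se[j]
    eaf_out[i] <- eaf_y
    n_out[i] <- outcome$n[j]
    n_cases_out[i] <- if ("n_cases" %in% names(outcome)) outcome$n_cases[j] else NA_real_
  }

  instruments <- data.frame(
    variant_id = exposure$variant_id[keep],
    chromosome = exposure$chromosome[keep],
    position = exposure$position[keep],
    effect_allele = exposure$effect_allele[keep],
    other_allele = exposure$other_allele[keep],
    beta_exp = exposure$beta[keep],
    se_exp = exposure$se[keep],
    eaf_exp = exposure$eaf[keep],
    pvalue_exp = exposure$pvalue[keep],
    n_exp = exposure$n[keep],
    beta_out = beta_out[keep],
    se_out = se_out[keep],
    eaf_out = eaf_out[keep],
    n_out = n_out[keep],
    n_cases_out = n_cases_out[keep],
    palindromic = palin[keep],
    flipped = flipped[keep],
    stringsAsFactors = FALSE
  )
  rownames(instruments) <- NULL
  audit <- data.frame(variant_id = exposure$variant_id,
                      disposition = disposition, reason = reason,
                      stringsAsFactors = FALSE)
  list(instruments = instruments, audit = audit)
}
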