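# Fixture builders and independent oracles shared across the suite.

# a minimal valid variant-record table
make_records <- function(n = 3, variant_id = sprintf("rs%d", seq_len(n)),
                         chromosome = "1",
                         position = seq_len(n) * 1e6,
                         effect_allele = rep_len(c("A", "C", "G"), n),
                         other_allele = rep_len(c("G", "T", "A"), n),
                         eaf = rep_len(0.3, n), beta = rep_len(0.1, n),
                         se = rep_len(0.01, n), pvalue = rep_len(1e-10, n),
                         n_sample = rep_len(10000, n),
                         n_cases = rep_len(NA_real_, n)) {
  chromosome <- rep_len(chromosome, n)
  position <- rep_len(position, n)
  data.frame(variant_id = variant_id, chromosome = chromosome,
             position = position, effect_allele = effect_allele,
             other_allele = other_allele, eaf = eaf, beta = beta, se = se,
             pvalue = pvalue, n = n_sample, n_cases = n_cases,
             stringsAsFactors = FALSE)
}

# a harmonized-instrument table built directly (bypasses harmonize)
make_insts <- function(beta_exp, beta_out, se_out,
                       se_exp = rep_len(1e-4, length(beta_exp)),
                       eaf = rep_len(0.3, length(beta_exp)),
                       n_exp = rep_len(1e5, length(beta_exp)),
                       n_out = rep_len(1e5, length(beta_exp))) {
  k <- length(beta_exp)
  data.frame(variant_id = sprintf("rs%d", seq_len(k)),
             beta_exp = beta_exp, se_exp = se_exp, beta_out = beta_out,
             se_out = se_out, eaf_exp = eaf, eaf_out = eaf,
             n_exp = n_exp, n_out = n_out, palindromic = FALSE,
             flipped = FALSE, stringsAsFactors = FALSE)
}

# independent IVW oracle: weighted least squares through the origin by
# direct normal-equations solve (not the package's sum formulas)
wls_origin_oracle <- function(bx, by, w) {
  X <- matrix(bx, ncol = 1)
  A <- t(X) %*% (w * X)
  theta <- solve(A, t(X) %*% (w * by))[1, 1]
  list(theta = theta, se = sqrt(solve(A)[1, 1]))
}

# independent WLS-with-intercept oracle via normal equations
wls_intercept_oracle <- function(bx, by, w) {
  X <- cbind(1, bx)
  A <- t(X) %*% (w * X)
  beta <- solve(A, t(X) %*% (w * by))
  resid <- by - X %*% beta
  sigma2 <- sum(w * resid^2) / (length(by) - 2)
  ses <- sqrt(diag(solve(A)) * sigma2)
  list(intercept = unname(beta[1, 1]), slope = unname(beta[2, 1]),
       intercept_se = unname(ses[1]), slope_se = unname(ses[2]))
}

# independent Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# independent re-statement of the greedy clumping rule, naive quadratic form
clump_oracle <- function(records, ld_pairs, r2_threshold, window_kb) {
  r2_of <- function(a, b) {
    if (is.null(ld_pairs) || nrow(ld_pairs) == 0) return(0)
    hit <- (ld_pairs$id_a == a & ld_pairs$id_b == b) |
           (ld_pairs$id_a == b & ld_pairs$id_b == a)
    if (any(hit)) ld_pairs$r2[which(hit)[1]] else 0
  }
  remaining <- records[order(records$pvalue, records$variant_id), , drop = FALSE]
  kept_ids <- character()
  while (nrow(remaining) > 0) {
    idx <- remaining[1, ]
    kept_ids <- c(kept_ids, idx$variant_id)
    drop <- vapply(seq_len(nrow(remaining)), function(i) {
      r <- remaining[i, ]
      r$variant_id == idx$variant_id ||
        (r$chromosome == idx$chromosome &&
         abs(r$position - idx$position) <= window_kb * 1000 &&
         r2_of(r$variant_id, idx$variant_id) > r2_threshold)
    }, logical(1))
    remaining <- remaining[!drop, , drop = FALSE]
  }
  records$variant_id[records$variant_id %in% kept_ids]
}

# independent Fisher-z two-correlation test
fisher_z_oracle <- function(r1, r2, n1, n2) {
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

expect_files_identical <- function(a, b) {
  expect_identical(readBin(a, "raw", file.size(a)),
                   readBin(b, "raw", file.size(b)))
}
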