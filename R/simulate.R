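#' Configuration for the two-sample summary-statistics simulator
#'
#' Defaults define the standard validation scenario: 50 independent strong
#' instruments, an exposure GWAS of 35,559 (the scale of a large
#' proteogenomic cohort), a rare-disease case-control outcome GWAS of 228
#' cases among 344,912 (biobank scale, log-odds effects; set
#' \code{n_cases_out = NULL} for a quantitative outcome), a causal effect of 0.5, SNP-exposure effects drawn
#' from N(0.15, 0.05), no pleiotropy, 10\% palindromic variants, and allele
#' frequencies uniform on (0.05, 0.45).
#'
#' @param n_snps number of variants.
#' @param n_exp,n_out exposure and outcome GWAS sample sizes.
#' @param n_cases_out optional case count; when given, outcome sampling
#'   variance uses the case-control analogue (see
#'   \code{\link{simulate_two_sample}}).
#' @param theta_true causal effect of exposure on outcome.
#' @param gamma_mean,gamma_sd normal distribution of true SNP-exposure
#'   effects, or \code{gamma_fixed} for an explicit vector (recycled).
#' @param gamma_fixed optional fixed SNP-exposure effects.
#' @param pleiotropy_mode \code{"none"}, \code{"balanced"} (mean-zero direct
#'   effects on the invalid fraction), \code{"directional"} (direct effects
#'   N(alpha_scale, alpha_scale/2)), or \code{"inside_violating"} (direct
#'   effects proportional to instrument strength plus noise).
#' @param alpha_scale scale of pleiotropic direct effects.
#' @param prop_invalid fraction of variants carrying pleiotropic effects.
#' @param prop_palindromic fraction assigned A/T or C/G allele pairs.
#' @param prop_reverse_causal fraction of reverse-causal contaminants: large
#'   direct outcome effect \code{delta ~ N(reverse_delta_mean,
#'   reverse_delta_sd)} with observed exposure effect
#'   \code{reverse_kappa * delta}, so they explain far more outcome than
#'   exposure variance.
#' @param reverse_kappa,reverse_delta_mean,reverse_delta_sd reverse-causal
#'   contaminant parameters.
#' @param eaf_min,eaf_max uniform bounds for effect-allele frequencies.
#' @param ld_block_size,ld_block_r2 optional LD structure: consecutive blocks
#'   of this size share the given pairwise r-squared (co-located within 100 kb
#'   on one chromosome).
#' @param seed RNG seed; the simulation is deterministic given the seed.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_snps = 50, n_exp = 35559, n_out = 344912,
                              n_cases_out = 228, theta_true = 0.5,
                              gamma_mean = 0.15, gamma_sd = 0.05,
                              gamma_fixed = NULL,
                              pleiotropy_mode = c("none", "balanced",
                                                  "directional",
                                                  "inside_violating"),
                              alpha_scale = 0.1, prop_invalid = 0,
                              prop_palindromic = 0.1,
                              prop_reverse_causal = 0, reverse_kappa = 0.3,
                              reverse_delta_mean = 0.3,
                              reverse_delta_sd = 0.05,
                              eaf_min = 0.05, eaf_max = 0.45,
                              ld_block_size = NULL, ld_block_r2 = NULL,
                              seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, n_exp > 2, n_out > 2,
            prop_invalid >= 0, prop_invalid <= 1,
            prop_palindromic >= 0, prop_palindromic <= 1,
            prop_reverse_causal >= 0, prop_reverse_causal <= 1,
            eaf_min >= 0.01, eaf_min < eaf_max, eaf_max < 0.5)
  structure(as.list(environment()), class = "simulation_config")
}

.sampling_se <- function(n, eaf, n_cases = NULL) {
  v <- 1 / (2 * n * eaf * (1 - eaf))
  if (!is.null(n_cases) && !all(is.na(n_cases))) {
    phi <- n_cases / n
    v <- v / (phi * (1 - phi))
  }
  sqrt(v)
}

#' Simulate a two-sample GWAS summary-statistics study
#'
#' Generative model: true SNP-exposure effects \eqn{\gamma_j}; observed
#' \eqn{\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj})} and
#' \eqn{\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj})} with
#' independent noise in the two (non-overlapping) samples and sampling
#' variance \eqn{\sigma^2 = 1/(2 n \, \mathrm{eaf}(1-\mathrm{eaf}))} for
#' quantitative traits, divided additionally by \eqn{\phi(1-\phi)} (case
#' fraction \eqn{\phi}) for a case-control outcome.  Pleiotropic direct
#' effects \eqn{\alpha_j}, palindromic allele pairs, reverse-causal
#' contaminants and LD blocks are injected per the configuration.  Per-variant
#' p-values are two-sided normal from beta/se.
#'
#' @param config a \code{\link{simulation_config}}.
#' @param seed optional override of \code{config$seed}.
#' @return list of class \code{mr_sim} with \code{exposure} and
#'   \code{outcome} variant-record tables (readable by every consumer of
#'   \code{\link{read_sumstats}} output), \code{ld} (an \code{ld_table}),
#'   \code{truth} (per-variant \code{gamma}, \code{alpha},
#'   \code{is_invalid}, \code{is_reverse_causal}, plus \code{theta_true}),
#'   and \code{config}.
#' @export
simulate_two_sample <- function(config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed)) seed <- config$seed
  with_preserved_seed(seed, .simulate_two_sample_impl(config))
}

.simulate_two_sample_impl <- function(cfg) {
  m <- cfg$n_snps
  id <- sprintf("rs%06d", seq_len(m))
  eaf <- stats::runif(m, cfg$eaf_min, cfg$eaf_max)

  # genome layout: round-robin chromosomes, well-separated positions,
  # unless LD blocks co-locate consecutive variants
  if (!is.null(cfg$ld_block_size)) {
    block <- (seq_len(m) - 1) %/% cfg$ld_block_size
    chromosome <- as.character(block %% 22 + 1)
    position <- 1e6 + block * 5e6 + ((seq_len(m) - 1) %% cfg$ld_block_size) * 1e4
  } else {
    chromosome <- as.character((seq_len(m) - 1) %% 22 + 1)
    position <- 1e6 + ((seq_len(m) - 1) %/% 22) * 2e6 +
      ((seq_len(m) - 1) %% 22) * 1e4
  }

  # allele pairs: palindromic fraction first (deterministic count), shuffled
  n_palin <- round(cfg$prop_palindromic * m)
  palin_idx <- if (n_palin > 0) sample.int(m, n_palin) else integer()
  ea <- oa <- character(m)
  pal_pairs <- matrix(c("A", "T", "C", "G"), ncol = 2, byrow = TRUE)
  nonpal <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                  c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  for (i in seq_len(m)) {
    if (i %in% palin_idx) {
      pr <- pal_pairs[sample.int(2, 1), ]
      if (stats::runif(1) < 0.5) pr <- rev(pr)
    } else {
      pr <- nonpal[sample.int(nrow(nonpal), 1), ]
    }
    ea[i] <- pr[1]; oa[i] <- pr[2]
  }

  gamma <- if (!is.null(cfg$gamma_fixed)) rep_len(cfg$gamma_fixed, m)
           else stats::rnorm(m, cfg$gamma_mean, cfg$gamma_sd)

  n_rev <- round(cfg$prop_reverse_causal * m)
  rev_idx <- if (n_rev > 0) sample.int(m, n_rev) else integer()
  is_rev <- seq_len(m) %in% rev_idx
  delta <- numeric(m)
  if (n_rev > 0) {
    delta[is_rev] <- stats::rnorm(n_rev, cfg$reverse_delta_mean,
                                  cfg$reverse_delta_sd)
    gamma[is_rev] <- cfg$reverse_kappa * delta[is_rev]
  }

  n_inv <- round(cfg$prop_invalid * m)
  inv_idx <- if (n_inv > 0) sample(setdiff(seq_len(m), rev_idx),
                                   min(n_inv, m - n_rev)) else integer()
  is_inv <- seq_len(m) %in% inv_idx
  alpha <- numeric(m)
  if (cfg$pleiotropy_mode != "none" && any(is_inv)) {
    k <- sum(is_inv)
    alpha[is_inv] <- switch(cfg$pleiotropy_mode,
      balanced = stats::rnorm(k, 0, cfg$alpha_scale),
      directional = stats::rnorm(k, cfg$alpha_scale, cfg$alpha_scale / 2),
      inside_violating = 0.5 * cfg$alpha_scale / max(abs(gamma)) *
        gamma[is_inv] * sign(cfg$alpha_scale) +
        stats::rnorm(k, 0, abs(cfg$alpha_scale) / 4))
  }

  se_x <- .sampling_se(cfg$n_exp, eaf)
  se_y <- .sampling_se(cfg$n_out, eaf, cfg$n_cases_out)
  mu_y <- cfg$theta_true * gamma + alpha
  mu_y[is_rev] <- delta[is_rev]
  beta_x <- stats::rnorm(m, gamma, se_x)
  beta_y <- stats::rnorm(m, mu_y, se_y)

  mk <- function(beta, se, n, n_cases = NA_real_) {
    data.frame(variant_id = id, chromosome = chromosome, position = position,
               effect_allele = ea, other_allele = oa, eaf = eaf,
               beta = beta, se = se,
               pvalue = pmax(2 * stats::pnorm(-abs(beta / se)),
                             .Machine$double.xmin),
               n = n, n_cases = n_cases, stringsAsFactors = FALSE)
  }
  exposure <- mk(beta_x, se_x, cfg$n_exp)
  outcome <- mk(beta_y, se_y, cfg$n_out,
                if (is.null(cfg$n_cases_out)) NA_real_ else cfg$n_cases_out)

  ld_pairs <- NULL
  if (!is.null(cfg$ld_block_size) && !is.null(cfg$ld_block_r2)) {
    block <- (seq_len(m) - 1) %/% cfg$ld_block_size
    pairs <- list()
    for (b in unique(block)) {
      members <- which(block == b)
      if (length(members) < 2) next
      cmb <- utils::combn(members, 2)
      pairs[[length(pairs) + 1]] <-
        data.frame(id_a = id[cmb[1, ]], id_b = id[cmb[2, ]],
                   r2 = cfg$ld_block_r2, stringsAsFactors = FALSE)
    }
    if (length(pairs)) ld_pairs <- do.call(rbind, pairs)
  }

  truth <- data.frame(variant_id = id, gamma = gamma, alpha = alpha,
                      is_invalid = is_inv, is_reverse_causal = is_rev,
                      theta_true = cfg$theta_true, stringsAsFactors = FALSE)
  structure(list(exposure = exposure, outcome = outcome,
                 ld = as_ld_table(ld_pairs), truth = truth, config = cfg),
            class = "mr_sim")
}

#' @export
print.mr_sim <- function(x, ...) {
  cat(sprintf("Simulated two-sample study: %d variants, theta_true = %g\n",
              nrow(x$exposure), x$config$theta_true))
  cat(sprintf("  invalid: %d, reverse-causal: %d, palindromic: %d, LD pairs: %d\n",
              sum(x$truth$is_invalid), sum(x$truth$is_reverse_causal),
              sum(.is_palindromic(x$exposure$effect_allele,
                                  x$exposure$other_allele)),
              nrow(x$ld)))
  invisible(x)
}

#' Write the ground-truth table of a simulated study
#'
#' Tab-delimited per-variant truth (gamma, alpha, invalid and reverse-causal
#' flags, theta_true) for downstream recovery scoring.
#'
#' @param study an \code{mr_sim}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
truth_report <- function(study, path) {
  stopifnot(inherits(study, "mr_sim"))
  utils::write.table(study$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by \code{truth_report}
#' @param path file path.
#' @return data frame.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Simulate a screening panel of many exposures against one outcome
#'
#' Builds \code{n_exposures} independent exposure GWAS tables over disjoint
#' variant sets, of which \code{n_causal} have causal effect
#' \code{theta_causal} on the shared outcome and the rest are null, plus the
#' combined outcome table.  The default per-exposure structure emulates a
#' cis-pQTL screen: one strong cis-like signal (gamma = 0.35) per exposure
#' plus clearly sub-significant background variants (gamma = 0.002), against a
#' well-powered quantitative outcome GWAS, so most exposures contribute a
#' single Wald-ratio instrument.  Each exposure uses its own derived seed, so
#' the panel is reproducible from the one top-level seed.
#'
#' @param n_exposures panel size.
#' @param n_causal number of truly causal exposures (placed first in causal
#'   id order but shuffled across exposure ids).
#' @param snps_per_exposure instruments simulated per exposure.
#' @param theta_causal causal effect of the causal exposures.
#' @param seed top-level seed.
#' @param config_fn optional function(exposure index, theta) returning the
#'   \code{simulation_config} to use; default standard scenario at the given
#'   theta with \code{snps_per_exposure} variants.
#' @return list with \code{exposures} (named list of record tables),
#'   \code{outcome} (combined record table), \code{truth} (exposure_id,
#'   theta_true, is_causal).
#' @export
simulate_screen_panel <- function(n_exposures = 100, n_causal = 5,
                                  snps_per_exposure = 12, theta_causal = 0.5,
                                  seed = 1, config_fn = NULL) {
  stopifnot(n_causal <= n_exposures)
  causal <- with_preserved_seed(derive_seed(seed, 0L),
                                sample.int(n_exposures, n_causal))
  exposures <- list()
  outcome_parts <- list()
  ids <- sprintf("EXP%03d", seq_len(n_exposures))
  for (i in seq_len(n_exposures)) {
    theta <- if (i %in% causal) theta_causal else 0
    cfg <- if (is.null(config_fn))
      simulation_config(n_snps = snps_per_exposure, theta_true = theta,
                        n_cases_out = NULL, prop_palindromic = 0,
                        gamma_fixed = c(0.35, rep(0.002, snps_per_exposure - 1)),
                        seed = derive_seed(seed, i))
    else config_fn(i, theta)
    sim <- simulate_two_sample(cfg)
    # disjoint variant namespaces so the combined outcome table is valid
    tag <- function(df) {
      df$variant_id <- paste0(ids[i], "_", df$variant_id)
      df
    }
    exposures[[ids[i]]] <- tag(sim$exposure)
    outcome_parts[[i]] <- tag(sim$outcome)
  }
  outcome <- do.call(rbind, outcome_parts)
  rownames(outcome) <- NULL
  truth <- data.frame(exposure_id = ids,
                      theta_true = ifelse(seq_len(n_exposures) %in% causal,
                                          theta_causal, 0),
                      is_causal = seq_len(n_exposures) %in% causal,
                      stringsAsFactors = FALSE)
  list(exposures = exposures, outcome = outcome, truth = truth)
}
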