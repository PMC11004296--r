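test_that("variant_r2 matches direct evaluation of 2*b^2*maf*(1-maf)", {
  expect_equal(variant_r2(1, 0.5), 0.5)
  expect_equal(variant_r2(0, 0.3), 0)
  expect_equal(variant_r2(0.3, 0.1), 2 * 0.09 * 0.1 * 0.9, tolerance = 1e-15)
  expect_error(variant_r2(0.1, 0.6), "maf")
  expect_error(variant_r2(0.1, -0.1), "maf")
  set.seed(101)
  b <- rnorm(50); m <- runif(50, 0, 0.5)
  expect_equal(variant_r2(b, m), 2 * b^2 * m * (1 - m), tolerance = 1e-12)
})

test_that("f_statistic matches the (N-K-1)/K * R2/(1-R2) formula", {
  expect_equal(f_statistic(1000, 10, 0), 0)
  expect_equal(f_statistic(1000, 10, 0.1), (989 / 10) * (0.1 / 0.9),
               tolerance = 1e-15)
  expect_gt(f_statistic(2000, 10, 0.1), f_statistic(1000, 10, 0.1))
  expect_gt(f_statistic(1000, 10, 0.2), f_statistic(1000, 10, 0.1))
  expect_error(f_statistic(10, 10, 0.1), "exceed")
  expect_error(f_statistic(1000, 10, 1), "r2_total")
  set.seed(102)
  n <- sample(100:10000, 50); r2 <- runif(50, 0, 0.5)
  expect_equal(f_statistic(n, 1, r2), (n - 2) * r2 / (1 - r2),
               tolerance = 1e-12)
})

test_that("ld_clump follows the greedy smallest-p rule", {
  expect_equal(nrow(ld_clump(make_records(0))), 0)

  rec <- make_records(3, position = c(1e6, 2e6, 3e6),
                      pvalue = c(1e-10, 1e-9, 1e-20))
  ld <- as_ld_table(data.frame(id_a = c("rs1", "rs2"), id_b = c("rs3", "rs3"),
                               r2 = c(0.5, 0.0005)))
  kept <- ld_clump(rec, ld, r2_threshold = 0.001, window_kb = 10000)
  expect_setequal(kept$variant_id, c("rs3", "rs2"))
  # output preserves input order
  expect_equal(kept$variant_id, c("rs2", "rs3"))

  # independent variants all kept
  expect_equal(nrow(ld_clump(rec, NULL, 0.001, 10000)), 3)

  # outside the window, correlation is ignored
  rec2 <- rec
  rec2$position <- c(1e6, 2e6, 2e10)
  expect_equal(nrow(ld_clump(rec2, ld, 0.001, 10000)), 3)
})

test_that("greedy clump matches a brute-force oracle on small instances", {
  set.seed(103)
  for (rep in 1:60) {
    k <- sample(2:8, 1)
    rec <- make_records(k, position = sort(sample.int(2e7, k)),
                        pvalue = runif(k, 1e-12, 1e-2))
    pairs <- t(combn(k, 2))
    ld_pairs <- data.frame(id_a = rec$variant_id[pairs[, 1]],
                           id_b = rec$variant_id[pairs[, 2]],
                           r2 = runif(nrow(pairs))^2,
                           stringsAsFactors = FALSE)
    ld_pairs <- ld_pairs[runif(nrow(ld_pairs)) < 0.7, ]
    thr <- sample(c(0.001, 0.1, 0.5), 1)
    kept <- ld_clump(rec, as_ld_table(ld_pairs), thr, 10000)
    expect_equal(kept$variant_id, clump_oracle(rec, ld_pairs, thr, 10000))
    # independence at threshold within the window
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        if (abs(kept$position[i] - kept$position[j]) <= 1e7) {
          hit <- (ld_pairs$id_a == kept$variant_id[i] &
                  ld_pairs$id_b == kept$variant_id[j]) |
                 (ld_pairs$id_b == kept$variant_id[i] &
                  ld_pairs$id_a == kept$variant_id[j])
          if (any(hit)) expect_lte(ld_pairs$r2[which(hit)[1]], thr)
        }
      }
    }
  }
})

test_that("steiger_filter keeps correct-direction significant variants", {
  # hand-evaluated Fisher-z oracle: R2_exp 0.02, R2_out 0.0001, n = 10000
  beta_exp <- sqrt(0.02 / (2 * 0.3 * 0.7))
  beta_out <- sqrt(0.0001 / (2 * 0.3 * 0.7))
  inst <- make_insts(beta_exp, beta_out, se_out = 0.01,
                     n_exp = 10000, n_out = 10000)
  sf <- steiger_filter(inst, alpha = 0.05)
  expect_equal(nrow(sf$instruments), 1)
  oracle <- fisher_z_oracle(sqrt(0.02), sqrt(0.0001), 10000, 10000)
  expect_equal(sf$detail$steiger_p, oracle$p, tolerance = 1e-12)
  expect_true(sf$detail$correct_direction)

  # equal variance explained fails the strict "larger" requirement
  inst_eq <- make_insts(0.1, 0.1, se_out = 0.01, n_exp = 1e4, n_out = 1e4)
  expect_equal(nrow(steiger_filter(inst_eq)$instruments), 0)

  # reversed variance ordering is removed regardless of p
  inst_rev <- make_insts(0.01, 0.5, se_out = 0.01, n_exp = 1e6, n_out = 1e6)
  expect_equal(nrow(steiger_filter(inst_rev)$instruments), 0)

  inst_na <- inst
  inst_na$eaf_out <- NA_real_
  expect_error(steiger_filter(inst_na), "eaf")
})

test_that("select_instruments applies the cascade in order", {
  sim <- simulate_two_sample(simulation_config(n_snps = 30, seed = 21,
                                               prop_palindromic = 0))
  # pass-through: thresholds defused -> all shared variants returned
  cfg0 <- selection_config(p_threshold = 1 - 1e-12, f_min = 0,
                           steiger_alpha = 1)
  sel0 <- select_instruments(sim$exposure, sim$outcome, sim$ld, cfg0)
  expect_equal(nrow(sel0$instruments), 30)

  # exclusion list removes the named variant
  cfg1 <- selection_config(p_threshold = 1 - 1e-12, f_min = 0,
                           steiger_alpha = 1,
                           exclusion_list = "rs000001")
  sel1 <- select_instruments(sim$exposure, sim$outcome, sim$ld, cfg1)
  expect_equal(nrow(sel1$instruments), 29)
  expect_false("rs000001" %in% sel1$instruments$variant_id)

  # stage counts are non-increasing
  sel <- select_instruments(sim$exposure, sim$outcome, sim$ld,
                            selection_config())
  expect_true(all(diff(sel$report$n) <= 0))
})

test_that("a fixture with exactly 3 independent significant variants yields 3 instruments", {
  # 3 strong variants + 2 below genome-wide significance, no LD
  exp <- make_records(5, beta = c(0.3, 0.3, 0.3, 0.01, 0.01),
                      se = rep(0.01, 5),
                      pvalue = c(1e-50, 1e-50, 1e-50, 0.3, 0.3),
                      n_sample = rep(50000, 5))
  out <- exp
  out$beta <- c(0.15, 0.15, 0.15, 0, 0)
  out$se <- rep(0.05, 5)
  out$pvalue <- rep(0.01, 5)
  out$n <- rep(300000, 5)
  sel <- select_instruments(exp, out, NULL, selection_config())
  expect_equal(nrow(sel$instruments), 3)
  expect_equal(sel$report$n[sel$report$stage == "p_threshold"], 3)
})

test_that("cis filtering keeps only variants within the window", {
  exp <- make_records(3, chromosome = c("1", "1", "2"),
                      position = c(1e6, 5e6, 1e6))
  out <- exp
  locus <- list(chromosome = "1", start_position = 1.5e6)
  cfg <- selection_config(p_threshold = 1 - 1e-12, f_min = 0,
                          steiger_alpha = 1, cis_mode = "cis_only",
                          cis_window_bp = 1e6)
  sel <- select_instruments(exp, out, NULL, cfg, locus)
  expect_equal(sel$instruments$variant_id, "rs1")
  expect_error(select_instruments(exp, out, NULL, cfg), "locus")

  # cis_and_trans applies no positional filter
  cfg2 <- selection_config(p_threshold = 1 - 1e-12, f_min = 0,
                           steiger_alpha = 1, cis_mode = "cis_and_trans")
  expect_equal(nrow(select_instruments(exp, out, NULL, cfg2)$instruments), 3)
})

test_that("the per-variant F filter removes weak instruments", {
  # two strong variants and one engineered with F < 10
  n <- 10000
  weak_beta <- 0.01  # R2 ~ 4.2e-5 -> F ~ 0.42
  exp <- make_records(3, beta = c(0.3, 0.3, weak_beta), se = rep(0.005, 3),
                      pvalue = rep(1e-20, 3), n_sample = rep(n, 3))
  out <- exp
  out$beta <- rep(0, 3); out$se <- rep(0.05, 3); out$pvalue <- rep(0.9, 3)
  cfg <- selection_config(p_threshold = 1 - 1e-12, steiger_alpha = 1)
  sel <- select_instruments(exp, out, NULL, cfg)
  expect_setequal(sel$instruments$variant_id, c("rs1", "rs2"))
  f_expected <- (n - 2) * variant_r2(weak_beta, 0.3) /
    (1 - variant_r2(weak_beta, 0.3))
  expect_lt(f_expected, 10)
})

test_that("LD tables read from file and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id_a\tid_b\tr2", "rs1\trs2\t0.4"), path)
  ld <- read_ld_table(path)
  expect_s3_class(ld, "ld_table")
  expect_equal(ld$r2, 0.4)
  expect_error(as_ld_table(data.frame(id_a = "a", id_b = "b", r2 = 1.2)),
               "r2")
})
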