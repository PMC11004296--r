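test_that("wald_ratio matches the printed formulas", {
  inst <- make_insts(0.1, 0.2, 0.05)
  est <- wald_ratio(inst)
  expect_equal(est$theta, 2.0)
  expect_equal(est$se, 0.5)
  expect_equal(est$n_snps, 1)
  expect_equal(est$or_point, exp(2))

  est0 <- wald_ratio(make_insts(0.1, 0, 0.05))
  expect_equal(est0$theta, 0)
  expect_equal(est0$or_point, 1)

  # simultaneous sign flip leaves theta unchanged
  est_neg <- wald_ratio(make_insts(-0.1, -0.2, 0.05))
  expect_equal(est_neg$theta, est$theta)
  expect_equal(est_neg$se, est$se)

  expect_error(wald_ratio(make_insts(0, 0.2, 0.05)), "beta_exp")
})

test_that("ivw matches the printed closed forms", {
  inst <- make_insts(c(1, 1), c(0.1, 0.3), c(0.1, 0.1))
  est <- ivw(inst)
  # equal weights: theta is the plain average of the two ratios
  expect_equal(est$theta, 0.2)
  expect_equal(est$se, 1 / sqrt(sum(1^2 / 0.1^2 * 2)))
  expect_equal(est$method, "ivw_fixed")

  # identical-ratio convexity: theta = c for any weights
  inst_c <- make_insts(c(0.5, 1, 2), c(0.5, 1, 2) * 0.7,
                       c(0.05, 0.2, 0.01))
  expect_equal(ivw(inst_c)$theta, 0.7, tolerance = 1e-12)

  # a duplicated single instrument degenerates to its Wald ratio
  one <- make_insts(0.2, 0.1, 0.04)
  expect_equal(ivw(rbind(one, one))$theta, wald_ratio(one)$theta)

  expect_error(ivw(one), "at least 2")
  expect_error(ivw(make_insts(c(0, 1), c(0.1, 0.2), c(0.1, 0.1))), "beta_exp")
})

test_that("ivw multiplicative random effects inflates se by sqrt(max(1, Q/(J-1)))", {
  set.seed(7)
  inst <- make_insts(runif(10, 0.5, 1.5), rnorm(10, 0.2, 0.3),
                     runif(10, 0.05, 0.2))
  fe <- ivw(inst, "fixed")
  mre <- ivw(inst, "multiplicative_random")
  q <- cochran_q(inst, fe$theta)
  expect_equal(mre$theta, fe$theta)
  expect_equal(mre$se, fe$se * sqrt(max(1, q$q / 9)), tolerance = 1e-12)

  # homogeneous instruments: no inflation below 1
  inst_h <- make_insts(c(1, 1, 1), c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.1))
  expect_equal(ivw(inst_h, "multiplicative_random")$se, ivw(inst_h)$se)
})

test_that("ivw equals a weighted-least-squares-through-origin oracle", {
  set.seed(8)
  for (rep in 1:50) {
    J <- sample(3:40, 1)
    inst <- make_insts(runif(J, -1, 1) + 0.1, rnorm(J), runif(J, 0.01, 0.5))
    est <- ivw(inst)
    orc <- wls_origin_oracle(inst$beta_exp, inst$beta_out, inst$se_out^-2)
    expect_equal(est$theta, orc$theta, tolerance = 1e-10)
    expect_equal(est$se, orc$se, tolerance = 1e-10)
  }
})

test_that("weighted_median follows the percentile-interpolation convention", {
  # equal weights, ratios 1, 2, 9 -> the middle value carries the 50% mass
  inst <- make_insts(c(1, 1, 1), c(1, 2, 9), c(1, 1, 1))
  expect_equal(weighted_median(inst, seed = 1)$theta, 2)

  # all ratios equal c -> c
  inst_c <- make_insts(c(1, 2, 4), 0.3 * c(1, 2, 4), c(0.1, 0.1, 0.1))
  expect_equal(weighted_median(inst_c, seed = 1)$theta, 0.3)

  # determinism: identical seed gives bit-identical se
  a <- weighted_median(inst, n_boot = 200, seed = 42)
  b <- weighted_median(inst, n_boot = 200, seed = 42)
  expect_identical(a$se, b$se)
  c <- weighted_median(inst, n_boot = 200, seed = 43)
  expect_false(identical(a$se, c$se))

  # estimate lies between the extreme ratios
  set.seed(9)
  for (rep in 1:20) {
    J <- sample(3:15, 1)
    inst_r <- make_insts(runif(J, 0.2, 2), rnorm(J), runif(J, 0.05, 0.5))
    ratios <- inst_r$beta_out / inst_r$beta_exp
    wm <- weighted_median(inst_r, n_boot = 10, seed = rep)$theta
    expect_gte(wm, min(ratios)); expect_lte(wm, max(ratios))
  }

  expect_error(weighted_median(make_insts(c(1, 1), c(1, 2), c(1, 1)),
                               seed = 1), "at least 3")
  expect_error(weighted_median(inst), "seed")
})

test_that("mr_egger recovers slope and intercept exactly on noiseless data", {
  bx <- c(0.1, 0.2, 0.35, 0.5)
  inst <- make_insts(bx, 0.03 + 0.4 * bx, c(0.05, 0.1, 0.02, 0.08))
  est <- mr_egger(inst)
  expect_equal(est$theta, 0.4, tolerance = 1e-10)
  expect_equal(est$intercept, 0.03, tolerance = 1e-10)

  inst0 <- make_insts(bx, 0.4 * bx, rep(0.05, 4))
  expect_equal(mr_egger(inst0)$intercept, 0, tolerance = 1e-10)

  expect_error(mr_egger(make_insts(c(1, 1), c(1, 2), c(1, 1))), "at least 3")
  expect_error(mr_egger(make_insts(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1))),
               "degenerate")
})

test_that("mr_egger matches a generic WLS oracle with t-based inference", {
  set.seed(10)
  for (rep in 1:50) {
    J <- sample(3:40, 1)
    inst <- make_insts(abs(rnorm(J, 0.3, 0.2)) + 0.01, rnorm(J),
                       runif(J, 0.01, 0.5))
    est <- mr_egger(inst)
    orc <- wls_intercept_oracle(inst$beta_exp, inst$beta_out,
                                inst$se_out^-2)
    expect_equal(est$theta, orc$slope, tolerance = 1e-8)
    expect_equal(est$intercept, orc$intercept, tolerance = 1e-8)
    expect_equal(est$se, orc$slope_se, tolerance = 1e-8)
    expect_equal(est$intercept_se, orc$intercept_se, tolerance = 1e-8)
    expect_equal(est$pvalue,
                 2 * pt(-abs(orc$slope / orc$slope_se), J - 2),
                 tolerance = 1e-8)
  }
})

test_that("estimate_auto selects Wald for 1 IV and IVW for more", {
  one <- make_insts(0.2, 0.1, 0.05)
  expect_equal(estimate_auto(one)$method, "wald_ratio")
  two <- make_insts(c(0.2, 0.3), c(0.1, 0.15), c(0.05, 0.05))
  expect_equal(estimate_auto(two)$method, "ivw_fixed")
  expect_error(estimate_auto(two[0, ]), "at least 1")
})

test_that("all estimators are scale-equivariant in the exposure", {
  set.seed(11)
  inst <- make_insts(runif(8, 0.2, 1), rnorm(8, 0.3, 0.2),
                     runif(8, 0.05, 0.2))
  for (cc in c(0.5, 3)) {
    scaled <- inst
    scaled$beta_exp <- inst$beta_exp * cc
    scaled$se_exp <- inst$se_exp * cc
    expect_equal(ivw(scaled)$theta, ivw(inst)$theta / cc, tolerance = 1e-12)
    expect_equal(mr_egger(scaled)$theta, mr_egger(inst)$theta / cc,
                 tolerance = 1e-10)
    expect_equal(weighted_median(scaled, n_boot = 5, seed = 2)$theta,
                 weighted_median(inst, n_boot = 5, seed = 2)$theta / cc,
                 tolerance = 1e-12)
  }
})

test_that("with zero pleiotropy and vanishing noise every estimator finds the true ratio", {
  sim <- simulate_two_sample(simulation_config(
    n_snps = 20, n_exp = 1e9, n_out = 1e9, n_cases_out = NULL,
    theta_true = 0.5, prop_palindromic = 0, seed = 30))
  h <- harmonize(sim$exposure, sim$outcome)
  expect_equal(ivw(h$instruments)$theta, 0.5, tolerance = 1e-3)
  expect_equal(mr_egger(h$instruments)$theta, 0.5, tolerance = 1e-2)
  expect_equal(weighted_median(h$instruments, n_boot = 10, seed = 1)$theta,
               0.5, tolerance = 1e-3)
})

test_that("mr_fit bundles estimators with model-object methods", {
  sim <- simulate_two_sample(simulation_config(n_snps = 25, seed = 31))
  h <- harmonize(sim$exposure, sim$outcome)
  fit <- mr_fit(h$instruments, seed = 5)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$table$method, c("ivw_fixed", "weighted_median",
                                      "mr_egger"))
  expect_true(all(fit$table$n_snps == nrow(h$instruments)))
  expect_equal(unname(coef(fit)["ivw_fixed"]), ivw(h$instruments)$theta)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < ci[, 2]))
  expect_equal(fit$table$or, exp(fit$table$theta))
  expect_s3_class(summary(fit), "summary.mr_fit")
  expect_output(print(fit), "ivw_fixed")
  expect_length(residuals(fit), nrow(h$instruments))
  # single instrument falls back to the Wald ratio, no sensitivity block
  fit1 <- mr_fit(h$instruments[1, ], seed = 5)
  expect_equal(fit1$table$method, "wald_ratio")
  expect_null(fit1$sensitivity)
})
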