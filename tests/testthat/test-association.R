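test_that("joint regression matches a closed-form OLS oracle on one covariate", {
  z <- c(0.3, -1.2, 2.4, 0.9)
  brainage <- c(1.0, -0.5, 3.2, 0.4)
  oracle <- ols_hand(z, brainage)
  tab <- regress_joint(brainage, cbind(Z1 = z), include_age = FALSE)
  expect_equal(tab$estimate, oracle$beta, tolerance = 1e-10)
  expect_equal(tab$std_error, oracle$se, tolerance = 1e-10)
  expect_equal(tab$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(tab$neg_log_p, -log(oracle$p), tolerance = 1e-10)
})

test_that("null responses are rejected at close to the nominal rate", {
  set.seed(1)
  nrep <- 400
  p <- replicate(nrep, {
    Z <- matrix(rnorm(60 * 3), 60, 3)
    regress_joint(rnorm(60), Z, include_age = FALSE)$p_value[1]
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nrep) + 1e-9)
  # and the p-values look uniform
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("rank deficiency and undersized samples are rejected with clear errors", {
  Z <- cbind(Z1 = rnorm(30), Z2 = rnorm(30))
  Z <- cbind(Z, Z3 = Z[, 1] + Z[, 2])
  expect_error(regress_joint(rnorm(30), Z, include_age = FALSE),
               "collinear")
  expect_error(regress_joint(rnorm(5), matrix(rnorm(5 * 4), 5), NULL, FALSE))
})

test_that("the two age-adjustment routes give identical covariate coefficients", {
  for (out in shared_replicates()[1:3]) {
    test <- out$split$test
    p <- out$prediction
    chk <- fwl_equivalence_check(p$brainage, p$brainager,
                                 out$cohort$Z[test, ], out$cohort$ages[test])
    expect_true(chk$pass)
    expect_lt(chk$max_deviation, 1e-8)
  }
  # deliberate violation: residualize on age^2 instead of age
  out <- shared_replicates()[[1]]
  test <- out$split$test
  ages <- out$cohort$ages[test]
  bad <- resid(lm(out$prediction$brainage ~ I(ages^2)))
  chk <- fwl_equivalence_check(out$prediction$brainage, bad,
                               out$cohort$Z[test, ], ages)
  expect_false(chk$pass)
  expect_gt(chk$max_deviation, 1e-8)
})

test_that("fdr_adjust implements Benjamini-Hochberg step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  # adjusted >= raw, capped at 1, monotone in ranks
  p <- runif(30)
  a <- fdr_adjust(p)
  expect_true(all(a >= p & a <= 1))
  expect_true(all(diff(a[order(p)]) >= -1e-12))
})

test_that("screen_covariates reports correlations, adjusted p-values and age links", {
  set.seed(3)
  n <- 300
  ages <- runif(n, 20, 80)
  brainage <- -0.2 * scale(ages)[, 1] * 5 + rnorm(n, 0, 4)
  brainager <- residualize(brainage, ages)
  Z <- cbind(self = brainage,
             agecov = ages + rnorm(n, 0, 10),
             noise = rnorm(n))
  tab <- screen_covariates(ages, brainage, brainager, Z)
  expect_equal(tab$covariate, c("self", "agecov", "noise"))
  expect_equal(tab$r_brainage[1], 1, tolerance = 1e-12)
  expect_lt(tab$p_brainage[1], 1e-10)
  expect_true(all(tab$r_brainage >= -1 & tab$r_brainage <= 1))
  # an age-tracking covariate: large |r| with BrainAGE, small with BrainAGER
  expect_gt(abs(tab$r_brainage[2]), abs(tab$r_brainager[2]))
  expect_gt(tab$r_age[2], 0.7)
  # constant covariate is flagged, not fatal
  expect_warning(
    tab2 <- screen_covariates(ages, brainage, brainager,
                              cbind(flat = rep(1, n), ok = rnorm(n))),
    "constant")
  expect_true(is.na(tab2$r_brainage[1]))
  expect_false(is.na(tab2$r_brainage[2]))
})

test_that("screening many independent covariates yields ~no FDR discoveries", {
  set.seed(4)
  n <- 200
  ages <- runif(n, 20, 80)
  brainage <- rnorm(n, 0, 5)
  brainager <- residualize(brainage, ages)
  hits <- replicate(10, {
    Z <- matrix(rnorm(n * 154), n, 154)
    tab <- screen_covariates(ages, brainage, brainager, Z)
    sum(tab$p_brainage < 0.05)
  })
  # BH controls FDR at 5% under the global null: expected discoveries ~ 0.05/run
  expect_lt(mean(hits), 1)
})

test_that("replicate summaries turn p-values into positive rates by truth label", {
  set.seed(5)
  mk <- function(p_contrib, p_non) {
    data.frame(
      covariate = c("Z1", "Z9"),
      estimate = 0, std_error = 1,
      p_value = c(p_contrib, p_non),
      neg_log_p = -log(c(p_contrib, p_non)),
      model = "with_age",
      truth_label = c("contributing", "non_contributing"))
  }
  tables <- list(mk(0.01, 0.2), mk(0.03, 0.01), mk(0.04, 0.6))
  s <- summarize_replicates(tables, alpha = 0.05)
  expect_equal(unname(s$aggregate$tp_rate["with_age"]), 1)
  expect_equal(unname(s$aggregate$fp_rate["with_age"]), 1 / 3)
  expect_true(all(s$rates$positive_rate >= 0 & s$rates$positive_rate <= 1))
  expect_error(summarize_replicates(tables[1]))
})
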