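abfs <- abf_set()

test_that("age draws respect the range, the sample size, and the seed", {
  set.seed(1)
  a <- draw_ages(1000, 20, 80)
  expect_length(a, 1000)
  expect_true(all(a >= 20 & a <= 80))
  set.seed(1)
  expect_identical(draw_ages(1000, 20, 80), a)
  expect_error(draw_ages(1, 20, 80))
  expect_warning(draw_ages(10, 50, 50 + 1e-8), "degenerate")
})

test_that("the covariate design enumerates all ABF subsets twice with negative weights", {
  set.seed(2)
  d <- build_design(abfs)
  expect_s3_class(d, "covariate_design")
  expect_equal(d$n_covariates, 16)
  # subsets 1..8 are all 8 subsets of {1,2,3}; 9..16 repeat them
  sizes <- vapply(d$membership, length, integer(1))
  expect_equal(sizes[1:8], c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L))
  expect_identical(d$membership[1:8], d$membership[9:16])
  expect_identical(d$membership[[2]], 1L)   # Z2 from f1 only
  expect_identical(d$membership[[10]], 1L)  # Z10 matches but does not contribute
  expect_identical(d$contributes, rep(c(TRUE, FALSE), each = 8))
  # alpha is zero exactly off-membership, U(-2,-1) on it
  for (j in 1:16) {
    on <- d$membership[[j]]
    expect_true(all(d$alpha[setdiff(1:3, on), j] == 0))
    expect_true(all(d$alpha[on, j] > -2 & d$alpha[on, j] < -1))
  }
  expect_true(all(d$noise_sd > 0))
})

test_that("simulated covariates have the designed age dependence", {
  set.seed(3)
  ages <- draw_ages(1000)
  d <- build_design(abfs)
  Z <- simulate_covariates(ages, d, abfs)
  expect_equal(dim(Z), c(1000, 16))
  r <- cor(ages, Z)
  # empty-subset covariates are pure noise: null correlation ~ N(0, 1/n)
  expect_lt(abs(r[1]), 0.1)
  expect_lt(abs(r[9]), 0.1)
  # age-dependent covariates land in the intended moderate range
  expect_true(all(abs(r[-c(1, 9)]) > 0.12 & abs(r[-c(1, 9)]) < 0.45))
  # negative alpha on decreasing ABFs makes them increase with age
  expect_true(all(r[-c(1, 9)] > 0))
  # noiseless single-ABF covariate is an exact transform of age
  d0 <- d
  d0$noise_sd[2] <- 0
  Z0 <- simulate_covariates(ages, d0, abfs)
  expect_equal(Z0[, 2], d$alpha[1, 2] * eval_abf(abfs, 1, ages),
               tolerance = 1e-12)
})

test_that("departures sum the contributing covariates only", {
  set.seed(4)
  d <- build_design(abfs)
  Z <- matrix(rnorm(5 * 16), 5, 16)
  expect_equal(compute_departures(Z, d, gamma = 0), rep(0, 5))
  expect_equal(compute_departures(Z, d, gamma = 0.5),
               0.5 * rowSums(Z[, 1:8]))
  # hand example: 2 participants x first two covariates
  Zh <- matrix(0, 2, 16)
  Zh[, 1] <- c(1, 2); Zh[, 2] <- c(3, -1); Zh[, 9] <- c(100, 100)
  expect_equal(compute_departures(Zh, d, gamma = 0.5), c(2, 0.5))
})

test_that("voxel features follow the weight-departure model and include background", {
  set.seed(5)
  ages <- draw_ages(400)
  vm <- voxel_model(n_voxels = 100, sigma_v = 1.7)
  V <- simulate_voxels(ages, vm, D = 0, abfs)
  expect_equal(dim(V), c(400, 125))
  expect_equal(colnames(V)[c(1, 100, 101, 125)], c("V1", "V100", "bg1", "bg25"))
  # noiseless single-voxel case reduces to the weighted ABF sum
  vm1 <- voxel_model(n_voxels = 1, sigma_v = 1e-12, background_fraction = 0)
  W <- matrix(c(1, 0, 0), nrow = 3)
  V1 <- simulate_voxels(ages, vm1, D = 0, abfs, base_weights = W)
  expect_equal(drop(V1), eval_abf(abfs, 1, ages), tolerance = 1e-6,
               ignore_attr = TRUE)
  # departures shift every voxel by D * sum_m f_m
  D <- rnorm(400)
  Vd <- simulate_voxels(ages, vm1, D = D, abfs, base_weights = W)
  expect_equal(drop(Vd) - drop(V1),
               D * rowSums(abf_matrix(abfs, ages)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # background columns are independent of age
  r_bg <- cor(ages, V[, 101:125])
  expect_true(all(abs(r_bg) < 4 / sqrt(400)))
})

test_that("voxel variance decomposes into signal plus noise variance", {
  set.seed(6)
  ages <- draw_ages(1000)
  vm <- voxel_model(n_voxels = 200, sigma_v = 1.7, background_fraction = 0)
  W <- draw_base_weights(vm)
  V <- simulate_voxels(ages, vm, D = 0, abfs, base_weights = W)
  signal <- abf_matrix(abfs, ages) %*% W
  # per-voxel: Var(v) = Var(f(A)) + sigma_v^2, averaged over voxels
  emp <- mean(apply(V, 2, var))
  expected <- mean(apply(signal, 2, var)) + vm$sigma_v^2
  se <- sd(apply(V, 2, var)) / sqrt(ncol(V))
  expect_lt(abs(emp - expected), 3 * se + 3 * vm$sigma_v^2 * sqrt(2 / 999))
})

test_that("fold change is linear in gamma and calibration round-trips", {
  set.seed(7)
  ages <- draw_ages(500)
  d <- build_design(abfs)
  Z <- simulate_covariates(ages, d, abfs)
  vm <- voxel_model()
  expect_equal(fold_change(vm, rep(0, 500)), 1)
  g1 <- calibrate_gamma(1.255, Z, d, vm)
  D1 <- compute_departures(Z, d, g1)
  expect_equal(fold_change(vm, D1), 1.255, tolerance = 1e-10)
  # doubling gamma doubles FC - 1
  D2 <- compute_departures(Z, d, 2 * g1)
  expect_equal(fold_change(vm, D2) - 1, 2 * (1.255 - 1), tolerance = 1e-10)
  g2 <- calibrate_gamma(1.170, Z, d, vm)
  expect_equal(fold_change(vm, compute_departures(Z, d, g2)), 1.170,
               tolerance = 1e-10)
  expect_equal(calibrate_gamma(1, Z, d, vm), 0)
})

test_that("generate_cohort is reproducible and structurally complete", {
  cfg <- sim_config(n = 200, n_voxels = 20)
  c1 <- generate_cohort(cfg, seed = 11)
  c2 <- generate_cohort(cfg, seed = 11)
  expect_identical(c1$Z, c2$Z)
  expect_identical(c1$V, c2$V)
  expect_identical(c1$ages, c2$ages)
  expect_equal(length(c1$ages), 200)
  expect_equal(dim(c1$Z), c(200, 16))
  expect_equal(dim(c1$V), c(200, 25))
  expect_equal(length(c1$D), 200)
  expect_equal(c1$fold_change, 1.255, tolerance = 1e-10)
  c3 <- generate_cohort(cfg, seed = 12)
  expect_false(identical(c1$Z, c3$Z))
})

test_that("contributing covariates reach the voxels through the departure channel", {
  # with gamma calibrated, a contributing covariate correlates with voxels
  # beyond what its non-contributing twin shows
  set.seed(8)
  cors <- replicate(5, {
    co <- generate_cohort(sim_config(n = 600))
    # partial out age by residualizing both sides on the ABF matrix
    Fm <- abf_matrix(co$abfs, co$ages)
    rz <- resid(lm(co$Z[, 2] ~ Fm))
    rz10 <- resid(lm(co$Z[, 10] ~ Fm))
    rv <- resid(lm(rowMeans(co$V[, 1:100]) ~ Fm))
    c(contrib = abs(cor(rz, rv)), noncontrib = abs(cor(rz10, rv)))
  })
  expect_gt(mean(cors["contrib", ]), mean(cors["noncontrib", ]))
})

test_that("cohort export writes readable delimited text with ground truth", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(sim_config(n = 50, n_voxels = 10), seed = 3)
  write_cohort(co, dir)
  part <- read.csv(file.path(dir, "participants.csv"), comment.char = "#")
  expect_equal(nrow(part), 50)
  expect_equal(part$age, co$ages)
  feat <- read.csv(file.path(dir, "features.csv"), comment.char = "#")
  expect_equal(unname(as.matrix(feat)), unname(co$V), tolerance = 1e-12,
               ignore_attr = TRUE)
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$gamma, co$gamma, tolerance = 1e-9)
  expect_equal(truth$seed, 3)
})
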