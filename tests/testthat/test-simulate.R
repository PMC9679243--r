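test_that("same seed gives bit-identical synthetic censuses", {
  p <- simParams(initial_n = 150L)
  a <- simulateCensus(p, seed = 7)
  b <- simulateCensus(p, seed = 7)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$year_dev, b$truth$year_dev)
  c <- simulateCensus(p, seed = 8)
  expect_false(identical(a$records, c$records))
})

test_that("generated data pass the census validators and cleaning", {
  fx <- fixture_clean_census(initial_n = 300L, seed = 5L)
  expect_silent(validateCensus(fx$records))
  expect_s3_class(fx$clean, "census_clean")
  # every plant has a full year grid (leading/trailing zeros preserved)
  counts <- table(fx$records$plant_id)
  expect_true(all(counts == length(simParams()$years)))
})

test_that("disabling dormancy removes all reincarnation patterns", {
  p <- simParams(initial_n = 300L, trans_ND = c(-30), trans_BD = c(-30))
  sim <- simulateCensus(p, seed = 3)
  cs <- summarizeCohort(cleanCensus(sim$records))
  expect_equal(cs$n_reincarnates, 0L)
  # default parameters do produce dormancy
  cs2 <- summarizeCohort(fixture_clean_census(300L, 5L)$clean)
  expect_gt(cs2$n_reincarnates, 0L)
})

test_that("a closed immortal population keeps a constant census count", {
  p <- simParams(initial_n = 200L, surv_N = c(20), surv_B = c(20),
                 surv_D = c(20), trans_NB = c(-20), trans_ND = c(-20),
                 recruit_rate = 0, year_sd = c(surv_N = 0))
  sim <- simulateCensus(p, seed = 2)
  cs <- summarizeCohort(cleanCensus(sim$records))
  expect_true(all(cs$alive_by_year == 200L))
  expect_equal(cs$n_plants, 200L)
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(simParams(initial_n = 0), "initial_n")
  expect_error(simParams(years = c(1990, 1992)), "consecutive")
  expect_error(simParams(recruit_rate = -1), "recruit_rate")
  expect_error(simParams(year_sd = c(bogus = 1)), "unknown year_sd")
  expect_error(simParams(year_sd = c(surv_N = -1)), "year_sd")
})

test_that("truth kernel requires a homogeneous environment", {
  p <- simParams()  # default has nonzero year SDs
  mesh <- buildMesh(50, 30)
  expect_error(truthKernel(p, mesh), "zero year-effect SDs")
  p0 <- simParams(year_sd = c(surv_N = 0))
  expect_s3_class(truthKernel(p0, mesh), "ipm_kernel")
})

test_that("doubling fecundity exactly doubles the recruitment pathway", {
  mesh <- buildMesh(50, 40)
  p1 <- simParams(year_sd = c(surv_N = 0))
  p2 <- p1; p2$coefs$fec_N[1] <- p2$coefs$fec_N[1] + log(2)
  p2$coefs$fec_B[1] <- p2$coefs$fec_B[1] + log(2)
  K1 <- truthKernel(p1, mesh); K2 <- truthKernel(p2, mesh)
  # survival/growth part cancels in the difference; fecundity part doubles
  F1 <- kernelBlock(K1, "NORMAL", "NORMAL") -
    (kernelBlock(K1, "NORMAL", "NORMAL") - outer(
      ipmviability:::.recruit_density(mesh, p1$recruit_mu, p1$recruit_sd),
      plogis(ipmviability:::.lp(p1$coefs$pfl_N, mesh$z)) *
        exp(ipmviability:::.lp(p1$coefs$fec_N, mesh$z)) * p1$recruit_rate))
  diffK <- kernelBlock(K2, "NORMAL", "NORMAL") - kernelBlock(K1, "NORMAL", "NORMAL")
  expect_equal(diffK, F1, tolerance = 1e-12)
})

test_that("identity-like truth parameters give a block-identity kernel", {
  mesh <- buildMesh(50, 25)
  p <- simParams(surv_N = c(30), surv_B = c(30), surv_D = c(30),
                 growth = c(0, 1), growth_sd = 0,
                 trans_NB = c(-30), trans_ND = c(-30), trans_BN = c(-30),
                 trans_BD = c(-30), trans_DN = c(-30), trans_DB = c(-30),
                 pfl_N = c(-30), pfl_B = c(-30), recruit_rate = 0,
                 year_sd = c(surv_N = 0))
  K <- truthKernel(p, mesh)
  expect_equal(kernelBlock(K, "NORMAL", "NORMAL"), diag(25), tolerance = 1e-9)
  expect_equal(dominantLambda(K), 1, tolerance = 1e-9)
})

test_that("realized per-year growth of a large population matches the kernel", {
  # individual-based oracle: after the size/state structure converges, the
  # realized annual growth of a large homogeneous-environment population
  # should match the truth kernel's dominant eigenvalue. Aboveground census
  # counts lag slightly behind total (dormants are invisible), so compare
  # the geometric-mean decline over the post-burn-in years.
  p0 <- agreement_params(n = 100000L)
  mesh <- buildMesh(46, 80)
  K <- truthKernel(p0, mesh)
  lam <- dominantLambda(K)
  # start the cohort at the kernel's stable size distribution so the
  # size-structure transient (weakly damped here) does not bias the ratio
  v <- rep(1, 3 * mesh$n_points)
  for (i in 1:500) { v <- applyKernel(K, v); v <- v / sum(v) }
  wN <- v[seq_len(mesh$n_points)]
  set.seed(1)
  p0$initial_sizes <- sample(mesh$z, 3e5, replace = TRUE, prob = wN) +
    runif(3e5, -mesh$h / 2, mesh$h / 2)
  sim <- simulateCensus(p0, seed = 31)
  cs <- summarizeCohort(cleanCensus(sim$records))
  a <- unname(cs$alive_by_year)
  realized <- (a[8] / a[4])^(1 / 4)  # post burn-in of the state mix
  expect_lt(abs(realized - lam) / lam, 0.02)
})
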