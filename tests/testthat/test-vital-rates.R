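test_that("AICc parsimony rule picks the simplest model within 2 units", {
  # unique minimum separated by >= 2: it wins
  expect_equal(selectModel(c(quadratic = 100.0, linear = 105.0)), "quadratic")
  # a simpler model within 2 of the minimum wins
  expect_equal(selectModel(c(quadratic = 100.0, linear = 101.5,
                             intercept = 108.0)), "linear")
  # all within 2: fewest effects wins
  expect_equal(selectModel(c(quadratic = 100.0, linear = 100.5,
                             intercept = 101.9)), "intercept")
  # invariant to ordering
  expect_equal(selectModel(c(intercept = 101.9, quadratic = 100.0,
                             linear = 100.5)), "intercept")
  # linear and quadratic_only tie on effect count: lower AICc breaks the tie
  expect_equal(selectModel(c(linear = 100.4, quadratic_only = 100.0)),
               "quadratic_only")
  expect_error(selectModel(c(a = Inf)), "no finite")
  expect_error(selectModel(numeric(0)), "no finite")
})

test_that("link-scale prediction matches hand-computed values", {
  mk <- function(beta, family, resid_sd = NA_real_)
    structure(list(beta = beta, family = family, resid_sd = resid_sd,
                   size_range = c(-Inf, Inf)),
              class = "fitted_vital_rate")
  expect_equal(predictRate(mk(c(0, 0, 0), "binomial"), 12.7), 0.5)
  expect_equal(predictRate(mk(c(-1, 0.2, -0.005), "binomial"), 10),
               plogis(0.5), tolerance = 1e-12)
  expect_equal(plogis(0.5), 0.6225, tolerance = 1e-4)
  expect_equal(predictRate(mk(c(log(3), 0, 0), "poisson"), c(1, 50)),
               c(3, 3))
  g <- predictRate(mk(c(2, 0.9, 0), "gaussian", resid_sd = 3), 10)
  expect_equal(g$mean, 11)
  expect_equal(g$sd, 3)
})

test_that("coefficient draws reproduce the fitted MVN distribution", {
  fit <- structure(list(
    name = "surv", family = "binomial",
    beta = c(-1, 0.2, -0.005),
    vcov = matrix(c(0.04, 0.01, 0, 0.01, 0.02, 0.001, 0, 0.001, 0.0005), 3, 3),
    sigma_year = 0.5, year_df = 6L, resid_sd = NA_real_,
    size_range = c(0, 50)), class = "fitted_vital_rate")
  set.seed(88)
  draws <- t(vapply(1:8000, function(i) drawCoefficients(fit, 1)$beta,
                    numeric(3)))
  se <- sqrt(diag(fit$vcov) / nrow(draws))
  expect_true(all(abs(colMeans(draws) - fit$beta) < 3 * se))
  expect_equal(stats::cov(draws), fit$vcov, tolerance = 0.1)
  # same seed -> identical draw
  d1 <- drawCoefficients(fit, 5, seed = 4)
  d2 <- drawCoefficients(fit, 5, seed = 4)
  expect_identical(d1, d2)
  expect_length(d1$delta, 5L)
})

test_that("degenerate uncertainty collapses draws to the point estimate", {
  fit <- structure(list(
    name = "x", family = "binomial", beta = c(0.3, 0, 0),
    vcov = matrix(0, 3, 3), sigma_year = 0, year_df = 6L,
    resid_sd = NA_real_, size_range = c(-Inf, Inf)),
    class = "fitted_vital_rate")
  d <- drawCoefficients(fit, 7, seed = 1)
  expect_identical(d$beta, fit$beta)
  expect_identical(d$delta, rep(0, 7))
})

test_that("non-PSD covariance is repaired by eigenvalue clipping", {
  V <- matrix(c(1, 0, 0, 0, 1, 1.2, 0, 1.2, 1), 3, 3)  # indefinite
  fit <- structure(list(
    name = "x", family = "binomial", beta = c(0, 1, 1),
    vcov = V, sigma_year = 0, year_df = 6L, resid_sd = NA_real_,
    size_range = c(-Inf, Inf)), class = "fitted_vital_rate")
  expect_warning(drawCoefficients(fit, 1, seed = 2), "clipping")
})

test_that("constant binomial response falls back to a penalized intercept", {
  d <- data.frame(response = rep(1L, 40), size = runif(40, 0, 30),
                  year = rep(1990:1993, 10))
  expect_warning(fit <- fitVitalRate(d, "binomial", "surv"), "Jeffreys")
  expect_equal(fit$structure, "intercept")
  expect_gt(plogis(fit$beta[1]), 0.95)
})

test_that("mixed-model fits recover known coefficients for each family", {
  # simulate grouped regression data directly from known coefficients
  set.seed(202)
  n <- 4000
  years <- 1990:1996
  size <- runif(n, 0, 40)
  year <- sample(years, n, replace = TRUE)
  ydev <- setNames(rnorm(length(years), 0, 0.4), years)
  eta <- -1 + 0.15 * size - 0.003 * size^2 + ydev[as.character(year)]

  db <- data.frame(response = rbinom(n, 1, plogis(eta)), size = size,
                   year = year)
  fb <- suppressWarnings(
    fitVitalRate(db, "binomial", "s", candidates = "quadratic"))
  seb <- sqrt(diag(fb$vcov))
  expect_true(all(abs(fb$beta - c(-1, 0.15, -0.003)) < 2.5 * seb))
  expect_equal(fb$sigma_year, 0.4, tolerance = 0.6)

  dp <- data.frame(response = rpois(n, exp(0.5 + 0.03 * size +
                                             ydev[as.character(year)])),
                   size = size, year = year)
  fp <- suppressWarnings(
    fitVitalRate(dp, "poisson", "f", candidates = "linear"))
  sep <- sqrt(diag(fp$vcov))[1:2]
  expect_true(all(abs(fp$beta[1:2] - c(0.5, 0.03)) < 2.5 * sep))

  dg <- data.frame(response = rnorm(n, 4 + 0.9 * size +
                                      ydev[as.character(year)], 3),
                   size = size, year = year)
  fg <- suppressWarnings(
    fitVitalRate(dg, "gaussian", "g", candidates = "linear"))
  seg <- sqrt(diag(fg$vcov))[1:2]
  expect_true(all(abs(fg$beta[1:2] - c(4, 0.9)) < 2.5 * seg))
  expect_equal(fg$resid_sd, 3, tolerance = 0.15)
})

test_that("structure selection finds a strong quadratic size effect", {
  # survival generated with pronounced curvature; selection should retain
  # the quadratic structure in most replicates
  hits <- 0L
  n_rep <- 10L
  for (s in seq_len(n_rep)) {
    set.seed(300 + s)
    n <- 5000
    size <- runif(n, 0, 45)
    year <- sample(1990:1996, n, replace = TRUE)
    ydev <- setNames(rnorm(7, 0, 0.3), 1990:1996)
    eta <- -3 + 0.30 * size - 0.005 * size^2 + ydev[as.character(year)]
    d <- data.frame(response = rbinom(n, 1, plogis(eta)), size = size,
                    year = year)
    fit <- suppressWarnings(fitVitalRate(d, "binomial", "s"))
    hits <- hits + (fit$structure == "quadratic")
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("transition table pairs consecutive years with latent sizes", {
  fx <- fixture_clean_census(300L, 5L)
  tr <- transitionTable(fx$clean)
  expect_true(all(tr$state_t %in% c("NORMAL", "BOLTER", "DORMANT")))
  # latent size for sizeless states equals the last measured diameter
  bolt <- tr[tr$state_t == "BOLTER" & !is.na(tr$size_t), ]
  if (nrow(bolt)) expect_true(all(bolt$size_t > 0))
  # survival response is the corrected record, so dormant years count alive
  dorm_next <- tr[tr$state_t1 == "DORMANT", ]
  if (nrow(dorm_next)) expect_true(all(dorm_next$surv_t1 == 1))
})

test_that("population-level fitting returns every rate and recruitment", {
  r <- fixture_population_rates(1000L, 11L)
  for (nm in ipmviability:::.rate_names)
    expect_s3_class(r[[nm]], "fitted_vital_rate")
  expect_gt(r$recruit_rate, 0)
  expect_gt(r$recruit_mu, 0)
  expect_equal(r$n_intervals, 7L)
  # recruit size estimate close to the generating truncated Normal
  expect_equal(r$recruit_mu, 6, tolerance = 0.3)
  expect_equal(r$recruit_sd, 2, tolerance = 0.4)
})

test_that("truncated-normal ML corrects the moment estimator's bias", {
  set.seed(14)
  x <- ipmviability:::.rtruncnorm(15000, 8, 4)
  tn <- ipmviability:::.fit_truncnorm(x)
  expect_equal(tn$mu, 8, tolerance = 0.15)
  expect_equal(tn$sd, 4, tolerance = 0.15)
  expect_lt(sd(x), 4)  # naive estimator is biased low under truncation
})
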