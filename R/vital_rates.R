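# Vital-rate regressions.
#
# Every size-dependent rate is fitted as a mixed model with a random year
# intercept (optionally quadrat nested in transect), comparing four fixed
# structures -- intercept + size + size^2, intercept + size,
# intercept + size^2, intercept only -- by AICc with the parsimony rule:
# the most parsimonious model among those within 2 AICc units of the
# minimum. Sizes are standardized internally for numerical stability and
# coefficients are returned on the raw mm scale.

.candidate_terms <- list(
  quadratic      = c("size_s", "size2_s"),
  linear         = c("size_s"),
  quadratic_only = c("size2_s"),
  intercept      = character(0))

.candidate_nfix <- vapply(.candidate_terms, length, integer(1)) + 1L

#' Small-sample corrected AIC
#'
#' @param ll Log-likelihood (ML).
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return AICc; \code{Inf} when \code{n <= k + 1} (correction undefined).
#' @export
aicc <- function(ll, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select a fixed-effect structure from an AICc table
#'
#' Implements the parsimony rule: the structure with the lowest AICc wins
#' unless other structures lie within 2 AICc units of the minimum, in which
#' case the one with fewest fixed effects among those is chosen (ties on
#' effect count broken by lower AICc). Invariant to the ordering of the
#' table.
#'
#' @param aicc_table Named numeric vector of AICc scores.
#' @param n_effects Named integer vector of fixed-effect counts for the same
#'   names; defaults to the package's standard candidate set
#'   (\code{quadratic}, \code{linear}, \code{quadratic_only},
#'   \code{intercept}).
#' @return The chosen structure name.
#' @export
selectModel <- function(aicc_table, n_effects = NULL) {
  aicc_table <- aicc_table[is.finite(aicc_table)]
  if (!length(aicc_table)) stop("no finite AICc scores to select among")
  if (is.null(n_effects)) {
    unknown <- setdiff(names(aicc_table), names(.candidate_nfix))
    if (length(unknown))
      stop("unknown candidate names (supply n_effects): ",
           paste(unknown, collapse = ", "))
    n_effects <- .candidate_nfix[names(aicc_table)]
  } else {
    n_effects <- n_effects[names(aicc_table)]
    if (anyNA(n_effects)) stop("n_effects must cover all candidates")
  }
  near <- which(aicc_table - min(aicc_table) < 2)
  pick <- near[order(n_effects[near], aicc_table[near])][1L]
  names(aicc_table)[pick]
}

# raw-scale transform of standardized-size coefficients:
# beta_raw = A %*% beta_std for eta = b0 + b1 (z-m)/s + b2 ((z-m)/s)^2
.std_to_raw <- function(m, s) {
  rbind(c(1, -m / s, m^2 / s^2),
        c(0, 1 / s, -2 * m / s^2),
        c(0, 0, 1 / s^2))
}

#' Fit one vital rate with AICc structure selection
#'
#' Fits all candidate fixed structures with an identical random-intercept
#' structure, computes AICc for each, applies [selectModel()], and returns
#' the chosen model's coefficients and fixed-effect covariance on the raw
#' size (mm) scale together with the year-effect SD and its effective
#' degrees of freedom (number of grouping years minus 1, used when
#' propagating uncertainty in the year variance).
#'
#' @param data Data frame with columns \code{response}, \code{size} (may be
#'   all-\code{NA} for intrinsically sizeless rates), \code{year}, and
#'   optionally \code{transect}, \code{quadrat}.
#' @param family \code{"binomial"}, \code{"gaussian"} or \code{"poisson"}.
#' @param name,population Labels stored on the fit.
#' @param re Random-intercept terms: \code{"year"} or
#'   \code{c("year", "quadrat")} for quadrat nested in transect.
#' @param candidates Subset of candidate structure names to consider.
#' @param fast If \code{TRUE}, GLMM candidates use \code{nAGQ = 0}
#'   (penalized-least-squares fixed effects), a standard speed/accuracy
#'   trade-off for very large samples.
#' @return Object of class \code{fitted_vital_rate}.
#' @export
fitVitalRate <- function(data, family, name = "rate", population = NA_character_,
                         re = "year", candidates = names(.candidate_terms),
                         fast = FALSE) {
  stopifnot(all(c("response", "year") %in% names(data)),
            family %in% c("binomial", "gaussian", "poisson"),
            all(candidates %in% names(.candidate_terms)))
  data <- data[!is.na(data$response), , drop = FALSE]
  has_size <- "size" %in% names(data) && any(!is.na(data$size))
  if (has_size) data <- data[!is.na(data$size), , drop = FALSE]
  n <- nrow(data)
  if (n < 2L) stop("too few observations to fit vital rate '", name, "'")
  if (!has_size) candidates <- "intercept"
  note <- character(0)

  # degenerate binomial response: penalized intercept (Jeffreys prior)
  if (family == "binomial" && length(unique(data$response)) == 1L) {
    k <- sum(data$response)
    p_hat <- (k + 0.5) / (n + 1)
    warning("constant ", name, " response: intercept-only Jeffreys estimate")
    return(.fvr(name, population, family, "intercept",
                beta = c(qlogis(p_hat), 0, 0),
                vcov = diag(c(1 / (n * p_hat * (1 - p_hat)), 0, 0)),
                sigma_year = 0, year_df = length(unique(data$year)) - 1L,
                year_devs = NULL, resid_sd = NA_real_,
                aicc = setNames(NA_real_, "intercept"), n_obs = n,
                note = "complete separation: Jeffreys intercept fallback"))
  }

  m_sz <- if (has_size) mean(data$size) else 0
  s_sz <- if (has_size && sd(data$size) > 0) sd(data$size) else 1
  data$size_s <- if (has_size) (data$size - m_sz) / s_sz else 0
  data$size2_s <- data$size_s^2
  data$year <- factor(data$year)
  re_terms <- "(1 | year)"
  if ("quadrat" %in% re) {
    data$quad_id <- interaction(data$transect, data$quadrat, drop = TRUE)
    re_terms <- c(re_terms, "(1 | quad_id)")
  }

  fits <- list(); scores <- setNames(rep(Inf, length(candidates)), candidates)
  for (cand in candidates) {
    rhs <- paste(c("1", .candidate_terms[[cand]], re_terms), collapse = " + ")
    fml <- as.formula(paste("response ~", rhs))
    fit <- tryCatch(suppressMessages(
      if (family == "gaussian")
        lme4::lmer(fml, data = data, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
      else
        lme4::glmer(fml, data = data, family = family,
                    nAGQ = if (fast) 0L else 1L,
                    control = lme4::glmerControl(check.conv.singular = "ignore"))),
      error = function(e) e, warning = function(w) {
        # refit capturing the result; convergence warnings are tolerated
        suppressWarnings(suppressMessages(
          if (family == "gaussian")
            lme4::lmer(fml, data = data, REML = FALSE,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))
          else
            lme4::glmer(fml, data = data, family = family,
                        nAGQ = if (fast) 0L else 1L,
                        control = lme4::glmerControl(check.conv.singular = "ignore"))))
      })
    if (inherits(fit, "error")) {
      note <- c(note, paste0(cand, ": failed (", conditionMessage(fit), ")"))
      next
    }
    k <- length(lme4::fixef(fit)) + length(re_terms) +
      as.integer(family == "gaussian")
    scores[cand] <- aicc(as.numeric(logLik(fit)), k, n)
    fits[[cand]] <- fit
  }
  if (!length(fits)) stop("all candidate fits failed for '", name, "'")
  chosen <- selectModel(scores)
  fit <- fits[[chosen]]

  fe <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  terms3 <- c("(Intercept)", "size_s", "size2_s")
  beta_std <- setNames(numeric(3), terms3)
  V_std <- matrix(0, 3, 3, dimnames = list(terms3, terms3))
  beta_std[names(fe)] <- fe
  V_std[names(fe), names(fe)] <- V[names(fe), names(fe)]
  A <- .std_to_raw(m_sz, s_sz)
  beta_raw <- drop(A %*% beta_std)
  V_raw <- A %*% V_std %*% t(A)

  vc <- lme4::VarCorr(fit)
  sigma_year <- if ("year" %in% names(vc)) sqrt(vc$year[1, 1]) else 0
  yd <- tryCatch(setNames(lme4::ranef(fit)$year[, 1],
                          rownames(lme4::ranef(fit)$year)),
                 error = function(e) NULL)
  .fvr(name, population, family, chosen,
       beta = unname(beta_raw), vcov = unname(V_raw),
       sigma_year = sigma_year, year_df = nlevels(data$year) - 1L,
       year_devs = yd,
       resid_sd = if (family == "gaussian") stats::sigma(fit) else NA_real_,
       aicc = scores, n_obs = n, note = note,
       size_range = if (has_size) range(data$size) else c(-Inf, Inf))
}

.fvr <- function(name, population, family, structure, beta, vcov, sigma_year,
                 year_df, year_devs, resid_sd, aicc, n_obs, note,
                 size_range = c(-Inf, Inf)) {
  structure(list(name = name, population = population, family = family,
                 structure = structure, beta = beta, vcov = vcov,
                 sigma_year = sigma_year, year_df = max(year_df, 1L),
                 year_devs = year_devs, resid_sd = resid_sd,
                 aicc = aicc, n_obs = n_obs, note = note,
                 size_range = size_range),
            class = "fitted_vital_rate")
}

#' @export
print.fitted_vital_rate <- function(x, ...) {
  cat("Vital rate '", x$name, "'", sep = "")
  if (!is.na(x$population)) cat(" [", x$population, "]", sep = "")
  cat(": ", x$family, ", structure = ", x$structure,
      ", n = ", x$n_obs, "\n", sep = "")
  cat("  beta (intercept, size, size^2):",
      paste(signif(x$beta, 4), collapse = ", "), "\n")
  cat("  sigma_year =", signif(x$sigma_year, 4), "\n")
  if (length(x$note)) cat("  notes:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' Predict a vital rate at given sizes
#'
#' @param fit A \code{fitted_vital_rate} or \code{coefficient_draw}.
#' @param size Sizes (mm) at which to predict.
#' @param delta Link-scale year-intercept shift (default 0: population
#'   level, random effects at their mode).
#' @return For binomial rates a probability vector; for Poisson rates a mean
#'   vector; for Gaussian growth a list with \code{mean} and \code{sd}.
#' @export
predictRate <- function(fit, size, delta = 0) {
  rng <- fit$size_range
  if (!is.null(rng)) size <- pmin(pmax(size, rng[1]), rng[2])
  eta <- .lp(fit$beta, size) + delta
  switch(fit$family,
         binomial = plogis(eta),
         poisson = exp(eta),
         gaussian = list(mean = eta, sd = fit$resid_sd),
         stop("unknown family: ", fit$family))
}

#' Parametric-bootstrap draw of vital-rate coefficients
#'
#' Samples fixed effects from the multivariate Normal defined by the fitted
#' coefficients and their covariance matrix, samples the year variance from
#' a scaled chi-square with the fit's effective degrees of freedom, and then
#' draws one Normal year deviation per intercensus interval.
#'
#' @param fit A \code{fitted_vital_rate}.
#' @param n_intervals Number of intercensus intervals needing deviations.
#' @param seed Optional RNG seed for a reproducible draw.
#' @return Object of class \code{coefficient_draw} with \code{beta} (raw
#'   scale), \code{delta} (length \code{n_intervals}), \code{sigma_year_star}
#'   and the fit's family/name metadata.
#' @export
drawCoefficients <- function(fit, n_intervals, seed = NULL) {
  stopifnot(inherits(fit, "fitted_vital_rate"), n_intervals >= 1L)
  if (!is.null(seed)) set.seed(seed)
  V <- (fit$vcov + t(fit$vcov)) / 2
  active <- which(diag(V) > 0 | fit$beta != 0)
  beta <- fit$beta
  if (length(active)) {
    Va <- V[active, active, drop = FALSE]
    ev <- eigen(Va, symmetric = TRUE)
    if (any(ev$values < -1e-8 * max(abs(ev$values), 1))) {
      warning("fixed-effect covariance of '", fit$name,
              "' not PSD; clipping negative eigenvalues")
    }
    ev$values <- pmax(ev$values, 0)
    Va <- ev$vectors %*% diag(ev$values, length(active)) %*% t(ev$vectors)
    beta[active] <- MASS::mvrnorm(1L, fit$beta[active], Va)
  }
  if (fit$sigma_year > 0) {
    df <- fit$year_df
    sigma2_star <- fit$sigma_year^2 * stats::rchisq(1L, df) / df
  } else sigma2_star <- 0
  structure(list(name = fit$name, family = fit$family, beta = beta,
                 resid_sd = fit$resid_sd,
                 sigma_year_star = sqrt(sigma2_star),
                 delta = rnorm(n_intervals, 0, sqrt(sigma2_star))),
            class = "coefficient_draw")
}

# ---- whole-population fitting ---------------------------------------------

#' Build the transition table for vital-rate fitting
#'
#' Pairs every classified plant-year with the following census year. Sizeless
#' states (bolter, dormant) carry their latent size: the last measured
#' rosette diameter.
#'
#' @param clean A \code{census_clean} table ([cleanCensus()]).
#' @return \code{data.table} with one row per plant per intercensus interval
#'   in which the plant was alive at the start: source state and (latent)
#'   size, survival to t+1, destination state and size, and the fruit count
#'   and flowering indicator of the source year.
#' @export
transitionTable <- function(clean) {
  stopifnot(inherits(clean, "census_clean"))
  dt <- data.table::as.data.table(clean)
  data.table::setorder(dt, plant_uid, year)
  dt[, latent_size := data.table::nafill(
        data.table::fifelse(state == "NORMAL", diameter_mm, NA_real_),
        type = "locf"), by = plant_uid]
  dt[, `:=`(state_t1 = data.table::shift(state, -1L),
            size_t1 = data.table::shift(diameter_mm, -1L),
            surv_t1 = data.table::shift(survival_corrected, -1L)), by = plant_uid]
  tr <- dt[state %in% c("NORMAL", "BOLTER", "DORMANT") & !is.na(state_t1)]
  tr <- tr[, .(population, transect, quadrat, plant_uid, year,
               state_t = state, size_t = latent_size, fruits_t = fruits,
               flowered_t = !is.na(fruits) & fruits > 0,
               surv_t1, state_t1, size_t1)]
  tr[]
}

#' Fit all vital rates of one population
#'
#' Runs the full fitting plan -- survival by state, growth, flowering and
#' fruit counts by aboveground state, the six between-state transitions,
#' recruitment rate and recruit sizes -- and returns everything needed to
#' assemble annual kernels.
#'
#' @param clean A \code{census_clean} table for one population (other
#'   populations are dropped with a message).
#' @param population Population label to fit.
#' @param re Random-intercept structure passed to [fitVitalRate()].
#' @param fast Passed to [fitVitalRate()].
#' @return Object of class \code{population_rates}: list of
#'   \code{fitted_vital_rate}s keyed by rate name, plus \code{recruit_rate},
#'   \code{recruit_mu}, \code{recruit_sd}, \code{max_size}, \code{n_intervals}.
#' @export
fitPopulationRates <- function(clean, population = NULL, re = "year",
                               fast = FALSE) {
  stopifnot(inherits(clean, "census_clean"))
  pops <- unique(clean$population)
  if (is.null(population)) {
    if (length(pops) > 1L)
      stop("multiple populations present; supply `population`")
    population <- pops
  }
  cl <- clean[clean$population == population]
  if (!nrow(cl)) stop("no records for population ", population)
  tr <- transitionTable(cl)
  years <- sort(unique(cl$year))
  n_intervals <- length(years) - 1L

  fit1 <- function(d, family, name, candidates = names(.candidate_terms)) {
    fitVitalRate(d, family = family, name = name, population = population,
                 re = re, candidates = candidates, fast = fast)
  }
  # binomial rates of sparse states: if the fit is impossible (e.g. the state
  # never occurs), fall back to a Jeffreys-style estimate from the raw counts
  fit_binom_safe <- function(d, name) {
    tryCatch(fit1(d, "binomial", name), error = function(e) {
      n <- sum(!is.na(d$response))
      k <- sum(d$response, na.rm = TRUE)
      p_hat <- (k + 0.5) / (n + 1)
      warning("rate '", name, "' unfittable (", conditionMessage(e),
              "); Jeffreys proportion fallback p = ", signif(p_hat, 3))
      .fvr(name, population, "binomial", "intercept",
           beta = c(qlogis(p_hat), 0, 0),
           vcov = diag(c(if (n > 0) 1 / ((n + 1) * p_hat * (1 - p_hat)) else 0,
                         0, 0)),
           sigma_year = 0, year_df = 1L, year_devs = NULL,
           resid_sd = NA_real_, aicc = setNames(NA_real_, "intercept"),
           n_obs = n, note = "sparse-state Jeffreys fallback")
    })
  }
  frame <- function(rows, resp, size) {
    data.frame(response = resp, size = size, year = rows$year,
               transect = rows$transect, quadrat = rows$quadrat)
  }
  fits <- list()
  nr <- tr[tr$state_t == "NORMAL", ]
  br <- tr[tr$state_t == "BOLTER", ]
  dr <- tr[tr$state_t == "DORMANT", ]
  fits$surv_N <- fit1(frame(nr, nr$surv_t1, nr$size_t), "binomial", "surv_N")
  fits$surv_B <- fit_binom_safe(frame(br, br$surv_t1, br$size_t), "surv_B")
  fits$surv_D <- tryCatch(
    fit1(frame(dr, dr$surv_t1, dr$size_t), "binomial", "surv_D"),
    error = function(e) {
      warning("dormant survival unfittable (", conditionMessage(e),
              "); falling back to intercept-only normal-state survival")
      fb <- fit1(frame(nr, nr$surv_t1, nr$size_t), "binomial", "surv_D",
                 candidates = "intercept")
      fb$note <- c(fb$note, "fallback: normal-state intercept survival")
      fb
    })
  gg <- nr[nr$surv_t1 == 1 & nr$state_t1 == "NORMAL" & !is.na(nr$size_t1), ]
  fits$growth <- fit1(frame(gg, gg$size_t1, gg$size_t), "gaussian", "growth")
  surv_n <- nr[nr$surv_t1 == 1, ]
  surv_b <- br[br$surv_t1 == 1, ]
  surv_d <- dr[dr$surv_t1 == 1, ]
  fits$trans_NB <- fit_binom_safe(frame(surv_n, as.integer(surv_n$state_t1 == "BOLTER"),
                                        surv_n$size_t), "trans_NB")
  fits$trans_ND <- fit_binom_safe(frame(surv_n, as.integer(surv_n$state_t1 == "DORMANT"),
                                        surv_n$size_t), "trans_ND")
  fits$trans_BN <- fit_binom_safe(frame(surv_b, as.integer(surv_b$state_t1 == "NORMAL"),
                                        surv_b$size_t), "trans_BN")
  fits$trans_BD <- fit_binom_safe(frame(surv_b, as.integer(surv_b$state_t1 == "DORMANT"),
                                        surv_b$size_t), "trans_BD")
  fits$trans_DN <- fit_binom_safe(frame(surv_d, as.integer(surv_d$state_t1 == "NORMAL"),
                                        surv_d$size_t), "trans_DN")
  fits$trans_DB <- fit_binom_safe(frame(surv_d, as.integer(surv_d$state_t1 == "BOLTER"),
                                        surv_d$size_t), "trans_DB")
  # flowering and fecundity use all classified plant-years, not just
  # transition rows, so the final census year contributes too
  ny <- cl[cl$state == "NORMAL", ]
  by <- cl[cl$state == "BOLTER", ]
  fl_n <- !is.na(ny$fruits) & ny$fruits > 0
  fl_b <- !is.na(by$fruits) & by$fruits > 0
  fits$pfl_N <- fit1(frame(ny, as.integer(fl_n), ny$diameter_mm),
                     "binomial", "pfl_N")
  fits$pfl_B <- fit_binom_safe(frame(by, as.integer(fl_b),
                                     transitionLatentSizes(cl, "BOLTER")),
                               "pfl_B")
  fn <- ny[fl_n, ]
  fits$fec_N <- fit1(frame(fn, fn$fruits, fn$diameter_mm), "poisson", "fec_N")
  fb_rows <- by[fl_b, ]
  fits$fec_B <- tryCatch(
    fit1(frame(fb_rows, fb_rows$fruits,
               transitionLatentSizes(cl, "BOLTER")[fl_b]),
         "poisson", "fec_B"),
    error = function(e) {
      warning("bolter fecundity unfittable (", conditionMessage(e),
              "); mean-fruit fallback")
      mu <- mean(fb_rows$fruits)
      if (!is.finite(mu) || mu <= 0) mu <- 1e-6
      .fvr("fec_B", population, "poisson", "intercept",
           beta = c(log(mu), 0, 0), vcov = matrix(0, 3, 3),
           sigma_year = 0, year_df = 1L, year_devs = NULL,
           resid_sd = NA_real_, aicc = setNames(NA_real_, "intercept"),
           n_obs = nrow(fb_rows), note = "sparse-state mean fallback")
    })

  rec <- estimateRecruitment(cl)
  structure(c(fits, list(recruit_rate = rec$rate,
                         recruit_mu = rec$mu, recruit_sd = rec$sd,
                         population = population,
                         max_size = max(cl$diameter_mm, na.rm = TRUE),
                         n_intervals = n_intervals, years = years)),
            class = "population_rates")
}

# latent sizes (last measured diameter) for rows of `state` in census order
transitionLatentSizes <- function(cl, state_label) {
  dt <- data.table::as.data.table(cl)
  data.table::setorder(dt, plant_uid, year)
  dt[, latent_size := data.table::nafill(
        data.table::fifelse(state == "NORMAL", diameter_mm, NA_real_),
        type = "locf"), by = plant_uid]
  dt[state == state_label, latent_size]
}

#' Estimate the recruitment loop of one population
#'
#' The recruitment rate is the ratio of new recruits appearing in year t+1
#' to total fruits produced in year t, averaged over intervals with nonzero
#' fruit production; recruit sizes are summarized by the mean and SD of
#' first-year diameters.
#'
#' @param cl A \code{census_clean} table for one population.
#' @return List with \code{rate}, \code{mu}, \code{sd},
#'   \code{recruits_by_year}, \code{fruits_by_year}.
#' @export
estimateRecruitment <- function(cl) {
  dt <- data.table::as.data.table(cl)
  years <- sort(unique(dt$year))
  fruits_by_year <- sapply(years, function(y)
    sum(dt$fruits[dt$year == y], na.rm = TRUE))
  names(fruits_by_year) <- years
  rec_rows <- dt[!is.na(recruit_year) & recruit_year > years[1] &
                   year == recruit_year]
  recruits_by_year <- sapply(years, function(y) sum(rec_rows$recruit_year == y))
  names(recruits_by_year) <- years
  ratios <- recruits_by_year[-1] / fruits_by_year[-length(years)]
  ratios <- ratios[is.finite(ratios)]
  sizes <- rec_rows$diameter_mm[!is.na(rec_rows$diameter_mm)]
  tn <- .fit_truncnorm(sizes)
  list(rate = if (length(ratios)) mean(ratios) else 0,
       mu = tn$mu, sd = tn$sd,
       recruits_by_year = recruits_by_year,
       fruits_by_year = fruits_by_year)
}

#' @export
print.population_rates <- function(x, ...) {
  cat("Fitted vital rates for population", x$population, "\n")
  for (nm in .rate_names)
    cat(sprintf("  %-9s %-9s structure=%-14s n=%d\n", nm, x[[nm]]$family,
                x[[nm]]$structure, x[[nm]]$n_obs))
  cat("  recruit_rate =", signif(x$recruit_rate, 4),
      "| recruit size ~ N(", signif(x$recruit_mu, 4), ",",
      signif(x$recruit_sd, 4), ")\n")
  invisible(x)
}

#' Assemble one annual kernel from fitted rates
#'
#' With \code{draws = NULL} the kernel uses the point estimates at the
#' population level (year deviations 0). With a list of
#' \code{coefficient_draw}s (one per rate, from [drawCoefficients()]) and an
#' interval index, it uses the sampled coefficients and that interval's
#' sampled year deviation -- one bootstrap replicate's kernel for one
#' intercensus interval.
#'
#' @param rates A \code{population_rates} object.
#' @param mesh A [buildMesh()] grid.
#' @param draws Optional named list of \code{coefficient_draw}s.
#' @param interval Intercensus interval index (1-based) selecting the year
#'   deviation from each draw; required when \code{draws} is given.
#' @return An \code{ipm_kernel}.
#' @export
buildAnnualKernel <- function(rates, mesh, draws = NULL, interval = NULL) {
  stopifnot(inherits(rates, "population_rates"))
  coefs <- lapply(setNames(.rate_names, .rate_names), function(nm) {
    beta <- if (is.null(draws)) rates[[nm]]$beta else draws[[nm]]$beta
    rng <- rates[[nm]]$size_range
    if (!is.null(rng) && any(is.finite(rng))) attr(beta, "size_range") <- rng
    beta
  })
  coefs$growth_sd <- if (is.null(draws)) rates$growth$resid_sd
                     else draws$growth$resid_sd
  coefs$recruit_rate <- rates$recruit_rate
  coefs$recruit_mu <- rates$recruit_mu
  coefs$recruit_sd <- rates$recruit_sd
  delta <- NULL
  if (!is.null(draws)) {
    if (is.null(interval)) stop("interval index required with draws")
    delta <- vapply(setNames(.rate_names, .rate_names),
                    function(nm) draws[[nm]]$delta[interval], numeric(1))
  }
  assembleKernel(coefs, mesh, delta = delta, population = rates$population,
                 label = if (is.null(interval)) "point" else
                   paste0("interval", interval))
}

utils::globalVariables(c("latent_size", "state_t1", "size_t1", "surv_t1",
                         "state_t", "size_t", "fruits_t", "flowered_t",
                         "quad_id"))

# ML fit of a Normal truncated below at 0 (recruit first-year sizes).
# Falls back to moments when the sample is tiny or optimization fails.
.fit_truncnorm <- function(x, lower = 0) {
  x <- x[!is.na(x)]
  if (!length(x)) return(list(mu = NA_real_, sd = 0))
  if (length(x) < 10L || sd(x) == 0)
    return(list(mu = mean(x), sd = if (length(x) > 1L) sd(x) else 0))
  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2])
    -sum(dnorm(x, mu, s, log = TRUE)) +
      length(x) * stats::pnorm(lower, mu, s, lower.tail = FALSE, log.p = TRUE)
  }
  opt <- tryCatch(stats::optim(c(mean(x), log(sd(x))), nll, method = "BFGS"),
                  error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0)
    return(list(mu = mean(x), sd = sd(x)))
  list(mu = opt$par[1], sd = exp(opt$par[2]))
}
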