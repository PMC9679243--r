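# Individual-based census simulator with known ground truth.
#
# The generator emulates the monitored-population design: several annual
# censuses of a few hundred tagged rosettes on 1 m^2 quadrats nested in
# transects; logit-quadratic size-dependent survival, Gaussian growth,
# a flowering/fruit-count reproduction hurdle, transitions into and out of
# the bolter and dormant states, and annual recruitment of small rosettes.
# Dormant plant-years are emitted as survival = 0 rows so the reincarnation
# pattern must be reconstructed downstream, exactly as in field data.

.rate_names <- c("surv_N", "surv_B", "surv_D", "growth",
                 "trans_NB", "trans_ND", "trans_BN", "trans_BD",
                 "trans_DN", "trans_DB",
                 "pfl_N", "pfl_B", "fec_N", "fec_B")

#' Simulation parameters for the synthetic census generator
#'
#' Coefficient vectors are \code{c(intercept, size, size^2)} on the link
#' scale (logit for probabilities, log for fruit counts, identity in mm for
#' growth); shorter vectors are padded with zeros. Defaults are fixed study
#' conditions chosen to produce a declining perennial with occasional
#' dormancy and bolting and a stochastic growth rate well below 1; see the
#' methods vignette for the rationale behind each value.
#'
#' @param population Population label.
#' @param years Consecutive census years (default 1990--1997, i.e. 8
#'   censuses and 7 transition intervals).
#' @param n_quadrats Number of 1 m^2 quadrats.
#' @param n_transects Number of transects the quadrats nest in.
#' @param initial_n Number of tagged plants alive at the first census.
#' @param surv_N,surv_B,surv_D Logit-scale survival coefficients by state.
#' @param growth Growth mean coefficients (mm scale); \code{growth_sd} is the
#'   residual SD of next-year diameter.
#' @param growth_sd Residual SD of growth (mm).
#' @param trans_NB,trans_ND,trans_BN,trans_BD,trans_DN,trans_DB Logit-scale
#'   coefficients of the between-state transition probabilities, conditional
#'   on survival (e.g. \code{trans_NB} = normal to bolter).
#' @param pfl_N,pfl_B Logit-scale flowering-probability coefficients.
#' @param fec_N,fec_B Log-scale fruit-count coefficients given flowering.
#' @param recruit_rate Expected recruits in year t+1 per fruit in year t.
#' @param recruit_mu,recruit_sd Mean and SD (mm) of first-year rosette
#'   diameters (Normal truncated at 0).
#' @param year_sd Named vector of year-random-intercept SDs, one per vital
#'   rate (names as the coefficient arguments above); missing names default
#'   to 0.
#' @param dormancy_max_duration Dormancy bouts longer than this are forced to
#'   re-emerge (geometric duration, capped).
#' @param initial_sizes Optional numeric vector of rosette diameters (mm) to
#'   draw the initial cohort's sizes from (sampled with replacement). By
#'   default initial sizes are one growth step from the recruit-size mean,
#'   which leaves a multi-year size-structure transient in the dynamics.
#' @param seed Optional RNG seed stored with the parameters.
#'
#' @return An object of class \code{sim_params}.
#' @export
simParams <- function(population = "P1",
                      years = 1990:1997,
                      n_quadrats = 40L,
                      n_transects = 4L,
                      initial_n = 400L,
                      surv_N = c(-1.0, 0.12, -0.0015),
                      surv_B = c(-0.85),
                      surv_D = c(2.2),
                      growth = c(4, 0.9, 0.0004),
                      growth_sd = 3,
                      trans_NB = c(-2.0, 0.02),
                      trans_ND = c(-1.8),
                      trans_BN = c(1.4),
                      trans_BD = c(-2.9),
                      trans_DN = c(1.4),
                      trans_DB = c(-2.2),
                      pfl_N = c(-4, 0.08),
                      pfl_B = c(2.2),
                      fec_N = c(1.0, 0.02),
                      fec_B = c(2.2),
                      recruit_rate = 0.05,
                      recruit_mu = 6,
                      recruit_sd = 2,
                      year_sd = c(surv_N = 2.0, surv_B = 0.3, surv_D = 0.3,
                                  growth = 1.5, trans_NB = 0.2, trans_ND = 0.2,
                                  trans_BN = 0.2, trans_BD = 0.2, trans_DN = 0.2,
                                  trans_DB = 0.2, pfl_N = 0.5, pfl_B = 0.2,
                                  fec_N = 0.3, fec_B = 0.2),
                      dormancy_max_duration = 3L,
                      initial_sizes = NULL,
                      seed = NULL) {
  years <- as.integer(years)
  if (length(years) < 2L || any(diff(years) != 1L))
    stop("years must be >= 2 consecutive integers")
  if (initial_n < 1L) stop("initial_n must be >= 1")
  if (n_quadrats < 1L || n_transects < 1L)
    stop("n_quadrats and n_transects must be >= 1")
  if (recruit_rate < 0) stop("recruit_rate must be >= 0")
  if (growth_sd < 0 || recruit_sd < 0) stop("SDs must be >= 0")
  if (!is.null(initial_sizes) &&
      (!is.numeric(initial_sizes) || !length(initial_sizes) ||
       any(initial_sizes <= 0)))
    stop("initial_sizes must be a vector of positive diameters")
  ysd <- setNames(numeric(length(.rate_names)), .rate_names)
  if (length(year_sd)) {
    bad <- setdiff(names(year_sd), .rate_names)
    if (length(bad)) stop("unknown year_sd names: ", paste(bad, collapse = ", "))
    if (any(year_sd < 0)) stop("year_sd must be >= 0")
    ysd[names(year_sd)] <- year_sd
  }
  p <- list(population = population, years = years,
            n_quadrats = as.integer(n_quadrats),
            n_transects = as.integer(n_transects),
            initial_n = as.integer(initial_n),
            coefs = list(surv_N = surv_N, surv_B = surv_B, surv_D = surv_D,
                         growth = growth,
                         trans_NB = trans_NB, trans_ND = trans_ND,
                         trans_BN = trans_BN, trans_BD = trans_BD,
                         trans_DN = trans_DN, trans_DB = trans_DB,
                         pfl_N = pfl_N, pfl_B = pfl_B,
                         fec_N = fec_N, fec_B = fec_B),
            growth_sd = growth_sd,
            recruit_rate = recruit_rate,
            recruit_mu = recruit_mu, recruit_sd = recruit_sd,
            year_sd = ysd,
            dormancy_max_duration = as.integer(dormancy_max_duration),
            initial_sizes = initial_sizes,
            seed = seed)
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic census parameters for population", x$population, "\n")
  cat(" ", length(x$years), "censuses", min(x$years), "-", max(x$years),
      "|", x$initial_n, "initial plants on", x$n_quadrats, "quadrats\n")
  cat("  recruit_rate", x$recruit_rate, "| growth_sd", x$growth_sd,
      "| nonzero year SDs:", sum(x$year_sd > 0), "\n")
  invisible(x)
}

# linear predictor for c(intercept, size, size^2) coefficients (padded)
.lp <- function(beta, z) {
  b <- c(beta, 0, 0)[1:3]
  b[1] + b[2] * z + b[3] * z * z
}

# Normal truncated below at `lower` (draws; vectorized over mu)
.rtruncnorm <- function(n, mu, sd, lower = 0) {
  if (sd == 0) return(pmax(rep_len(mu, n), lower))
  p0 <- stats::pnorm(lower, mu, sd)
  u <- runif(n, p0, 1)
  stats::qnorm(pmin(u, 1 - 1e-12), mu, sd)
}

#' Simulate a tagged-plant census with known ground truth
#'
#' Runs the individual-based process model forward over the census years and
#' emits a long-format census table on the full plant-by-year grid (so
#' survival histories have leading zeros before recruitment and trailing
#' zeros after death, and dormant years appear as apparent deaths).
#'
#' @param params A [simParams()] object.
#' @param seed RNG seed (overrides \code{params$seed}); the same seed gives
#'   bit-identical output.
#' @return List with \code{records} (census data.frame passing
#'   [validateCensus()]) and \code{truth} (class \code{sim_truth}: the
#'   parameters, the realized per-year random intercepts, and the seed).
#' @export
simulateCensus <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(seed)) set.seed(seed)
  years <- params$years
  n_years <- length(years)
  cf <- params$coefs
  # realized year random intercepts, one column per census year
  ydev <- matrix(rnorm(length(.rate_names) * n_years), length(.rate_names),
                 n_years, dimnames = list(.rate_names, years))
  ydev <- ydev * params$year_sd[.rate_names]

  n0 <- params$initial_n
  quad <- sample.int(params$n_quadrats, n0, replace = TRUE)
  plants <- data.frame(
    uid = seq_len(n0),
    quadrat = quad,
    transect = ((quad - 1L) %% params$n_transects) + 1L,
    recruit_year = years[1],
    stringsAsFactors = FALSE)
  state <- rep.int(1L, n0)          # 1 NORMAL, 2 BOLTER, 3 DORMANT, 0 DEAD
  size <- if (is.null(params$initial_sizes))
    .rtruncnorm(n0, .lp(cf$growth, params$recruit_mu),
                params$growth_sd)  # established plants, one growth step in
  else sample(params$initial_sizes, n0, replace = TRUE)
  dorm_dur <- integer(n0)
  next_uid <- n0 + 1L

  rows <- vector("list", n_years)
  for (t in seq_len(n_years)) {
    yr <- years[t]
    n <- nrow(plants)
    alive_above <- state %in% c(1L, 2L)
    diam <- ifelse(state == 1L, size, NA_real_)
    fruits <- rep(NA_real_, n)
    isN <- state == 1L
    isB <- state == 2L
    if (any(isN)) {
      pf <- plogis(.lp(cf$pfl_N, size[isN]) + ydev["pfl_N", t])
      fl <- rbinom(sum(isN), 1L, pf) == 1L
      fr <- numeric(sum(isN))
      fr[fl] <- rpois(sum(fl), exp(.lp(cf$fec_N, size[isN][fl]) + ydev["fec_N", t]))
      fruits[isN] <- fr
    }
    if (any(isB)) {
      pf <- plogis(.lp(cf$pfl_B, size[isB]) + ydev["pfl_B", t])
      fl <- rbinom(sum(isB), 1L, pf) == 1L
      fr <- numeric(sum(isB))
      fr[fl] <- rpois(sum(fl), exp(.lp(cf$fec_B, size[isB][fl]) + ydev["fec_B", t]))
      fruits[isB] <- fr
    }
    rows[[t]] <- data.frame(
      population = params$population,
      transect = paste0("T", plants$transect),
      quadrat = paste0("Q", plants$quadrat),
      plant_id = paste0("pl", plants$uid),
      year = yr,
      diameter_mm = diam,
      survival = as.integer(alive_above),
      fruits = fruits,
      stringsAsFactors = FALSE)
    total_fruits <- sum(fruits, na.rm = TRUE)

    if (t == n_years) break
    # ---- transition to the next census year ----
    new_state <- state
    new_size <- size
    for (s in 1:3) {
      idx <- which(state == s)
      if (!length(idx)) next
      z <- size[idx]
      sv_rate <- switch(s, "surv_N", "surv_B", "surv_D")
      p_surv <- plogis(.lp(cf[[sv_rate]], z) + ydev[sv_rate, t])
      died <- rbinom(length(idx), 1L, p_surv) == 0L
      new_state[idx[died]] <- 0L
      liv <- idx[!died]
      if (!length(liv)) next
      zl <- size[liv]
      tr <- switch(s,
        cbind(plogis(.lp(cf$trans_NB, zl) + ydev["trans_NB", t]),
              plogis(.lp(cf$trans_ND, zl) + ydev["trans_ND", t])),
        cbind(plogis(.lp(cf$trans_BN, zl) + ydev["trans_BN", t]),
              plogis(.lp(cf$trans_BD, zl) + ydev["trans_BD", t])),
        cbind(plogis(.lp(cf$trans_DN, zl) + ydev["trans_DN", t]),
              plogis(.lp(cf$trans_DB, zl) + ydev["trans_DB", t])))
      tot <- rowSums(tr)
      over <- tot > 1
      if (any(over)) tr[over, ] <- tr[over, ] / tot[over]
      u <- runif(length(liv))
      to_first <- u < tr[, 1]
      to_second <- !to_first & u < tr[, 1] + tr[, 2]
      dest <- switch(s,
        ifelse(to_first, 2L, ifelse(to_second, 3L, 1L)),   # from NORMAL
        ifelse(to_first, 1L, ifelse(to_second, 3L, 2L)),   # from BOLTER
        ifelse(to_first, 1L, ifelse(to_second, 2L, 3L)))   # from DORMANT
      if (s == 3L) {  # cap dormancy duration: forced re-emergence to NORMAL
        forced <- dest == 3L & dorm_dur[liv] >= params$dormancy_max_duration
        dest[forced] <- 1L
      }
      new_state[liv] <- dest
      grow <- dest == 1L
      if (any(grow)) {
        mu <- .lp(cf$growth, zl[grow]) + ydev["growth", t]
        new_size[liv[grow]] <- .rtruncnorm(sum(grow), mu, params$growth_sd,
                                           lower = 1e-6)
      }
      # entering/keeping B or D keeps the latent size unchanged
    }
    dorm_dur <- ifelse(new_state == 3L & state == 3L, dorm_dur + 1L,
                       ifelse(new_state == 3L, 1L, 0L))
    state <- new_state
    size <- new_size
    # ---- recruitment into year t+1 ----
    n_rec <- if (params$recruit_rate > 0 && total_fruits > 0)
      rpois(1L, params$recruit_rate * total_fruits) else 0L
    if (n_rec > 0L) {
      q <- sample.int(params$n_quadrats, n_rec, replace = TRUE)
      rec <- data.frame(uid = seq.int(next_uid, length.out = n_rec),
                        quadrat = q,
                        transect = ((q - 1L) %% params$n_transects) + 1L,
                        recruit_year = years[t + 1L],
                        stringsAsFactors = FALSE)
      next_uid <- next_uid + n_rec
      plants <- rbind(plants, rec)
      state <- c(state, rep.int(1L, n_rec))
      size <- c(size, .rtruncnorm(n_rec, params$recruit_mu, params$recruit_sd,
                                  lower = 1e-6))
      dorm_dur <- c(dorm_dur, integer(n_rec))
      # pad this year's emitted rows retroactively? recruits appear from t+1;
      # pre-recruitment rows are added on the full grid below.
    }
  }
  records <- do.call(rbind, rows)
  # full plant-by-year grid: add survival-0 rows for years before recruitment
  grid <- expand.grid(uid = plants$uid, year = years, KEEP.OUT.ATTRS = FALSE)
  grid <- merge(grid, plants, by = "uid")
  key_rec <- paste(records$plant_id, records$year)
  grid$plant_id <- paste0("pl", grid$uid)
  missing_rows <- grid[!paste(grid$plant_id, grid$year) %in% key_rec, ]
  if (nrow(missing_rows)) {
    pad <- data.frame(population = params$population,
                      transect = paste0("T", missing_rows$transect),
                      quadrat = paste0("Q", missing_rows$quadrat),
                      plant_id = missing_rows$plant_id,
                      year = missing_rows$year,
                      diameter_mm = NA_real_,
                      survival = 0L,
                      fruits = NA_real_,
                      stringsAsFactors = FALSE)
    records <- rbind(records, pad)
  }
  records <- records[order(records$plant_id, records$year), ]
  rownames(records) <- NULL
  truth <- structure(list(params = params, year_dev = ydev, seed = seed),
                     class = "sim_truth")
  list(records = records, truth = truth)
}

#' Simulate several populations in one study
#'
#' @param params_list List of [simParams()] objects (distinct population
#'   labels).
#' @param seed Master seed; population k is simulated with \code{seed + k}.
#' @return List with stacked \code{records} and a list of \code{truth}
#'   objects named by population.
#' @export
simulateStudy <- function(params_list, seed = 1L) {
  stopifnot(length(params_list) >= 1L)
  labs <- vapply(params_list, function(p) p$population, character(1))
  if (anyDuplicated(labs)) stop("population labels must be distinct")
  out <- lapply(seq_along(params_list), function(k)
    simulateCensus(params_list[[k]], seed = seed + k))
  records <- do.call(rbind, lapply(out, `[[`, "records"))
  rownames(records) <- NULL
  truths <- setNames(lapply(out, `[[`, "truth"), labs)
  list(records = records, truth = truths)
}

#' Exact projection kernel implied by generating parameters
#'
#' Builds the multistate kernel directly from the generating coefficient
#' functions, bypassing regression, for oracle comparisons against fitted
#' kernels. Only defined for the environment-homogeneous case.
#'
#' @param params [simParams()] object with all year-effect SDs zero.
#' @param mesh A [buildMesh()] grid.
#' @return An \code{ipm_kernel}.
#' @export
truthKernel <- function(params, mesh) {
  stopifnot(inherits(params, "sim_params"))
  if (any(params$year_sd > 0))
    stop("truth kernel is defined only for zero year-effect SDs")
  coefs <- c(params$coefs,
             list(growth_sd = params$growth_sd,
                  recruit_rate = params$recruit_rate,
                  recruit_mu = params$recruit_mu,
                  recruit_sd = params$recruit_sd))
  assembleKernel(coefs, mesh, population = params$population,
                 label = "truth")
}
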