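# Stochastic projection: long-run growth, transient trajectories,
# extinction risk, and bootstrap summaries.

#' Configuration for stochastic projections
#'
#' Defaults are the full study scale: 50,000 projection steps for the
#' stochastic growth rate, 5000 parametric-bootstrap replicates, 1000
#' trajectories per replicate over a 22-year horizon with extinction at 0
#' individuals. Scale these down for exploratory runs.
#'
#' @param n_steps Steps of the long-run growth-rate projection.
#' @param n_bootstrap Parametric-bootstrap replicates of the coefficients.
#' @param n_trajectories Transient trajectories per bootstrap replicate.
#' @param horizon_years Transient projection horizon (years).
#' @param extinction_threshold Population size at or below which a
#'   trajectory is extinct.
#' @param seed Master RNG seed.
#' @return List of class \code{stochastic_run_config}.
#' @export
runConfig <- function(n_steps = 50000L, n_bootstrap = 5000L,
                      n_trajectories = 1000L, horizon_years = 22L,
                      extinction_threshold = 0, seed = NULL) {
  stopifnot(n_steps >= 1L, n_bootstrap >= 1L, n_trajectories >= 1L,
            horizon_years >= 1L, extinction_threshold >= 0)
  structure(list(n_steps = as.integer(n_steps),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_trajectories = as.integer(n_trajectories),
                 horizon_years = as.integer(horizon_years),
                 extinction_threshold = extinction_threshold,
                 seed = seed),
            class = "stochastic_run_config")
}

.kernel_mats <- function(kernels) {
  if (inherits(kernels, "ipm_kernel") || is.matrix(kernels))
    kernels <- list(kernels)
  lapply(kernels, function(k) if (inherits(k, "ipm_kernel")) k$mat
         else as.matrix(k))
}

#' Long-run stochastic growth rate
#'
#' Projects a uniform state vector forward, at each step multiplying by one
#' of the annual kernels drawn uniformly at random (IID environments). The
#' annual growth rate is the ratio of vector sums before and after the
#' step; the vector is renormalized to sum 1 after every step to avoid
#' rounding error, and the stochastic growth rate is the geometric mean of
#' the annual rates over the whole sequence.
#'
#' @param kernels List of annual kernels (\code{ipm_kernel}s or plain square
#'   matrices of a common size).
#' @param n_steps Number of projection steps (default 50,000).
#' @param seed Optional RNG seed.
#' @param v0 Optional initial vector (default uniform over all cells).
#' @return The estimate of the stochastic growth rate lambda_S. If the
#'   population vector hits exact 0 the function returns 0.
#' @export
stochasticLambda <- function(kernels, n_steps = 50000L, seed = NULL,
                             v0 = NULL) {
  mats <- .kernel_mats(kernels)
  stopifnot(length(mats) >= 1L)
  dims <- vapply(mats, ncol, integer(1))
  if (length(unique(dims)) != 1L) stop("kernels differ in dimension")
  if (!is.null(seed)) set.seed(seed)
  n <- dims[1]
  v <- if (is.null(v0)) rep(1 / n, n) else v0 / sum(v0)
  picks <- sample.int(length(mats), n_steps, replace = TRUE)
  log_sum <- 0
  for (t in seq_len(n_steps)) {
    v <- drop(mats[[picks[t]]] %*% v)
    s <- sum(v)
    if (s <= 0) return(0)
    log_sum <- log_sum + log(s)
    v <- v / s
  }
  exp(log_sum / n_steps)
}

#' Transient population projections with integer rounding and extinction
#'
#' Each trajectory starts from a uniform state vector scaled to the observed
#' population size and runs \code{horizon_years} annual steps, drawing one
#' of the annual kernels uniformly at random each step. After every step the
#' projected total is rounded to the nearest integer (the stage vector is
#' rescaled to the rounded total, so extinction to zero is always possible);
#' a trajectory at or below the extinction threshold is extinct and stays at
#' zero.
#'
#' @param kernels List of annual kernels.
#' @param n0 Starting population size (final-census count).
#' @param config A [runConfig()]; uses \code{n_trajectories},
#'   \code{horizon_years}, \code{extinction_threshold}.
#' @param seed Optional RNG seed.
#' @return List with \code{sizes} (matrix horizon x trajectories of rounded
#'   totals), \code{extinct} (logical per trajectory),
#'   \code{median_by_year}, \code{prop_extinct}, and \code{median_final}.
#' @export
transientProject <- function(kernels, n0, config = runConfig(), seed = NULL) {
  stopifnot(n0 >= 0)
  mats <- .kernel_mats(kernels)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(mats[[1]])
  n_traj <- config$n_trajectories
  horizon <- config$horizon_years
  V <- matrix(round(n0) / n, n, n_traj)
  sizes <- matrix(0, horizon, n_traj)
  for (t in seq_len(horizon)) {
    pick <- sample.int(length(mats), n_traj, replace = TRUE)
    for (k in unique(pick)) {
      idx <- which(pick == k)
      V[, idx] <- mats[[k]] %*% V[, idx, drop = FALSE]
    }
    tot <- colSums(V)
    rounded <- round(tot)
    rounded[rounded <= config$extinction_threshold] <- 0
    scale <- ifelse(tot > 0, rounded / tot, 0)
    V <- sweep(V, 2L, scale, "*")
    sizes[t, ] <- rounded
  }
  extinct <- sizes[horizon, ] == 0
  list(sizes = sizes, extinct = extinct,
       median_by_year = apply(sizes, 1L, median),
       prop_extinct = mean(extinct),
       median_final = median(sizes[horizon, ]),
       mean_final = mean(sizes[horizon, ]))
}

#' Summarize bootstrap replicates of the projection outcomes
#'
#' @param boot List of per-replicate results, each a list with
#'   \code{lambda_s}, \code{prop_extinct}, \code{mean_final} (mean predicted
#'   final size across that replicate's trajectories) and
#'   \code{median_by_year}.
#' @param population Label carried into the summary.
#' @return Object of class \code{projection_summary}: median and 95\%
#'   percentile interval of lambda_S, mean and 95\% interval of the
#'   extinction probability, grand mean / median and 95\% interval of the
#'   predicted final population size, and the per-year median trajectory
#'   (median across replicates of within-replicate medians). Percentiles use
#'   the linear-interpolation quantile definition.
#' @export
summarizeBootstrap <- function(boot, population = NA_character_) {
  if (length(boot) < 2L) stop("need at least 2 bootstrap replicates")
  q95 <- function(x) unname(quantile(x, c(0.025, 0.975), type = 7))
  lam <- vapply(boot, `[[`, numeric(1), "lambda_s")
  pe <- vapply(boot, `[[`, numeric(1), "prop_extinct")
  pn <- vapply(boot, `[[`, numeric(1), "mean_final")
  med_traj <- apply(do.call(cbind, lapply(boot, `[[`, "median_by_year")),
                    1L, median)
  structure(list(population = population,
                 n_bootstrap = length(boot),
                 lambda_s = lam,
                 lambda_s_median = median(lam), lambda_s_ci = q95(lam),
                 pr_ext_mean = mean(pe), pr_ext_ci = q95(pe),
                 pred_n_mean = mean(pn), pred_n_median = median(pn),
                 pred_n_ci = q95(pn),
                 median_trajectory = med_traj),
            class = "projection_summary")
}

#' @export
print.projection_summary <- function(x, ...) {
  cat("Projection summary", if (!is.na(x$population))
    paste0("for population ", x$population) else "", "\n")
  cat(sprintf("  lambda_S median %.3f (95%% CI %.3f-%.3f) over %d bootstraps\n",
              x$lambda_s_median, x$lambda_s_ci[1], x$lambda_s_ci[2],
              x$n_bootstrap))
  cat(sprintf("  Pr(extinction) mean %.3f (95%% CI %.3f-%.3f)\n",
              x$pr_ext_mean, x$pr_ext_ci[1], x$pr_ext_ci[2]))
  cat(sprintf("  predicted final N mean %.2f, median %.2f (95%% CI %.2f-%.2f)\n",
              x$pred_n_mean, x$pred_n_median, x$pred_n_ci[1], x$pred_n_ci[2]))
  invisible(x)
}

#' Full bootstrap projection of one population
#'
#' For each bootstrap replicate: draw coefficient sets for every vital rate
#' ([drawCoefficients()]), assemble one kernel per intercensus interval,
#' estimate lambda_S over \code{n_steps} IID draws of those kernels, and run
#' the transient trajectories from the final-census population size.
#'
#' @param rates A \code{population_rates} object ([fitPopulationRates()]).
#' @param mesh A [buildMesh()] grid.
#' @param n0 Final-census population size (scales the transient start).
#' @param config A [runConfig()].
#' @return A \code{projection_summary}.
#' @export
projectPopulation <- function(rates, mesh, n0, config = runConfig()) {
  stopifnot(inherits(rates, "population_rates"))
  n_int <- rates$n_intervals
  base_seed <- if (is.null(config$seed)) NULL else as.integer(config$seed)
  boot <- vector("list", config$n_bootstrap)
  for (b in seq_len(config$n_bootstrap)) {
    if (!is.null(base_seed)) set.seed((base_seed + 7919L * b) %% .Machine$integer.max)
    draws <- lapply(setNames(.rate_names, .rate_names), function(nm)
      drawCoefficients(rates[[nm]], n_int))
    kernels <- lapply(seq_len(n_int), function(i)
      buildAnnualKernel(rates, mesh, draws = draws, interval = i))
    lam <- stochasticLambda(kernels, n_steps = config$n_steps)
    tp <- transientProject(kernels, n0, config)
    boot[[b]] <- list(lambda_s = lam, prop_extinct = tp$prop_extinct,
                      mean_final = tp$mean_final,
                      median_by_year = tp$median_by_year)
  }
  summarizeBootstrap(boot, population = rates$population)
}
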