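# Genetics-demography correlations, transformations, and the small-sample
# power analysis for Pearson correlations.

#' Transform a bounded quantity to a linear scale
#'
#' Natural-log transform for positive quantities (growth rates, population
#' sizes, densities) and logit transform for probabilities
#' (heterozygosity, inbreeding coefficient, extinction probability). A small
#' constant epsilon is applied only at the domain boundaries so that 0 (and,
#' for the logit, 1) values are not dropped: \code{ln} uses
#' \code{log(x + epsilon)} when \code{x = 0}, and \code{logit} shrinks exact
#' 0/1 to \code{epsilon} / \code{1 - epsilon}.
#'
#' @param x Numeric vector.
#' @param kind \code{"ln"} or \code{"logit"}.
#' @param epsilon Boundary adjustment (default 0.001; use e.g. 0.5
#'   individuals for predicted population sizes).
#' @return Transformed vector.
#' @export
transformValue <- function(x, kind = c("ln", "logit"), epsilon = 0.001) {
  kind <- match.arg(kind)
  if (kind == "ln") {
    x_adj <- ifelse(!is.na(x) & x == 0, x + epsilon, x)
    if (any(x_adj <= 0, na.rm = TRUE))
      stop("ln transform needs positive values (after boundary adjustment)")
    log(x_adj)
  } else {
    if (any(x < 0 | x > 1, na.rm = TRUE))
      stop("logit transform needs values in [0, 1]")
    x_adj <- ifelse(!is.na(x) & x <= 0, epsilon,
                    ifelse(!is.na(x) & x >= 1, 1 - epsilon, x))
    if (any(x_adj <= 0 | x_adj >= 1, na.rm = TRUE))
      stop("epsilon leaves no room inside (0, 1)")
    qlogis(x_adj)
  }
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (at least 3), both with
#'   nonzero variance.
#' @return List of class \code{correlation_result}: \code{r}, two-sided
#'   \code{p} from the t distribution with n - 2 df, and \code{n}.
#' @export
pearsonWithP <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in one of the inputs; correlation undefined")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.4f (n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Smallest detectable correlation for a given power
#'
#' Solves the bias-adjusted Fisher-z power equation
#' \deqn{atanh(r) + r / (2 (n - 1)) = (z_{1 - \alpha/2} + z_{power}) / \sqrt{n - 3}}
#' for \code{r} by bracketed root-finding. With only a handful of
#' populations this threshold is severe: at n = 5, power 0.75 and two-sided
#' alpha 0.05 it is about 0.94.
#'
#' @param n Sample size (>= 4).
#' @param power Target power, in (0, 1).
#' @param alpha Two-sided significance level, in (0, 1).
#' @return The critical correlation magnitude.
#' @export
criticalRForPower <- function(n, power = 0.75, alpha = 0.05) {
  if (n < 4) stop("n must be >= 4")
  if (power <= 0 || power >= 1 || alpha <= 0 || alpha >= 1)
    stop("power and alpha must lie in (0, 1)")
  target <- (qnorm(1 - alpha / 2) + qnorm(power)) / sqrt(n - 3)
  if (target <= 0) return(0)
  f <- function(r) atanh(r) + r / (2 * (n - 1)) - target
  uniroot(f, interval = c(1e-12, 1 - 1e-12), tol = 1e-9)$root
}

# ---- packaged summary tables ----------------------------------------------

.extdata <- function(file) {
  p <- system.file("extdata", file, package = "ipmviability")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)  # pre-install
  utils::read.csv(p, stringsAsFactors = FALSE)
}

#' Packaged population-genetics summary table
#'
#' Per-population microsatellite/SNP summary statistics for the five
#' monitored populations: percent polymorphic loci (P), observed and
#' effective allele numbers, observed heterozygosity, gene diversity,
#' allelic richness, inbreeding coefficient, and the East/West genetic
#' group.
#'
#' @return Data frame with one row per population.
#' @export
geneticsTable <- function() .extdata("table2_genetics.csv")

#' Packaged demographic-outcome summary table
#'
#' Published medians and intervals of the stochastic growth rate, mean
#' extinction probability, and mean predicted 2019 population size and
#' density for the five monitored populations.
#'
#' @return Data frame with one row per population.
#' @export
demographyTable <- function() .extdata("table3_demography.csv")

#' Packaged 2019 recensus density table
#'
#' Observed mean contemporary density (plants per square metre) at the five
#' historical census sites.
#'
#' @return Data frame with one row per population.
#' @export
recensusDensityTable <- function() .extdata("recensus2019_density.csv")

#' Correlate genetic statistics with demographic outcomes
#'
#' Computes Pearson correlations between each of the two focal genetic
#' variables (observed heterozygosity H_O and inbreeding coefficient F_IS,
#' both on the logit scale) and each demographic outcome (stochastic growth
#' rate and predicted 2019 size on the natural-log scale, extinction
#' probability on the logit scale, observed 2019 density on the natural-log
#' scale), for the full population set and the East-only subset.
#'
#' @param genetics Data frame like [geneticsTable()] (needs
#'   \code{population}, \code{group}, \code{H_O}, \code{F_IS}).
#' @param demography Data frame like [demographyTable()] (needs
#'   \code{population}, \code{lambda_s_median}, \code{pr_ext_mean},
#'   \code{pred_n2019_mean}).
#' @param densities Data frame like [recensusDensityTable()] (needs
#'   \code{population}, \code{density_2019}); may be \code{NULL} to skip
#'   density correlations.
#' @param epsilon_prob Boundary constant for logit-scale variables.
#' @param epsilon_n Constant (individuals) added to zero predicted sizes.
#' @return Data frame with one row per (genetic variable, demographic
#'   variable, subset): \code{r}, \code{p}, \code{n}, and a
#'   \code{computable} flag (FALSE with \code{NA} r when a subset is too
#'   small or degenerate).
#' @export
correlateAll <- function(genetics, demography, densities = NULL,
                         epsilon_prob = 0.001, epsilon_n = 0.5) {
  gd <- merge(genetics, demography, by = "population")
  if (!is.null(densities)) gd <- merge(gd, densities, by = "population")
  demo_vars <- c(lambda_s = "lambda_s_median", pr_ext = "pr_ext_mean",
                 pred_n2019 = "pred_n2019_mean")
  demo_kind <- c(lambda_s = "ln", pr_ext = "logit", pred_n2019 = "ln")
  if (!is.null(densities)) {
    demo_vars <- c(demo_vars, density_2019 = "density_2019")
    demo_kind <- c(demo_kind, density_2019 = "ln")
  }
  tx <- function(col, kind) {
    eps <- if (kind == "logit") epsilon_prob
           else if (col == "pred_n2019_mean") epsilon_n else epsilon_prob
    transformValue(gd[[col]], kind, eps)
  }
  out <- list()
  for (gvar in c("H_O", "F_IS")) {
    gx <- transformValue(gd[[gvar]], "logit", epsilon_prob)
    for (dv in names(demo_vars)) {
      dx <- tx(demo_vars[[dv]], demo_kind[[dv]])
      for (subset in c("all", "East")) {
        keep <- if (subset == "East") gd$group == "East" else rep(TRUE, nrow(gd))
        res <- tryCatch(pearsonWithP(gx[keep], dx[keep]), error = identity)
        ok <- !inherits(res, "error")
        out[[length(out) + 1L]] <- data.frame(
          genetic = gvar, demographic = dv, subset = subset,
          transform_genetic = "logit", transform_demographic = demo_kind[[dv]],
          r = if (ok) res$r else NA_real_,
          p = if (ok) res$p else NA_real_,
          n = if (ok) res$n else sum(keep),
          computable = ok,
          note = if (ok) "" else conditionMessage(res),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
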