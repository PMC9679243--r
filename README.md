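# ipmviability

Population viability analysis for long-lived perennial plants censused as
tagged individuals, built around a **multistate integral projection model
(IPM)**. The package is aimed at plant demographers and conservation
biologists who have long-format census tables — plant, year, rosette
diameter, survival, fruit count — and want stochastic growth rates,
extinction probabilities and their uncertainty, plus correlations of those
outcomes with population-genetic summary statistics.

## What it does

1. **Census cleaning.** Plants with vegetative dormancy produce
   "reincarnation" records (alive, apparently dead, alive). The correction
   flips every 0 between the first and last 1 of the survival history —
   `00011101` becomes `00011111` — and dormancy is scored where the two
   records differ. Alive plant-years with no measurable rosette (diameter 0
   or missing) are bolters, a separate discrete state.
2. **Vital rates.** Survival, growth, flowering, fecundity and the six
   between-state transitions are fitted per population as mixed models with
   a random year intercept, comparing intercept/linear/quadratic size
   structures by AICc with a parsimony rule (lowest AICc unless rivals are
   within 2 units, then fewest effects).
3. **Kernels.** An annual kernel is a 3×3 block matrix over
   {NORMAL, BOLTER, DORMANT}, each block 150×150 over a midpoint-rule mesh
   from 0 mm to 110% of the largest observed diameter; sizeless states
   remember their last measured size (latent-size memory).
4. **Projection.** The stochastic growth rate λ_S is the geometric mean of
   annual ratios along 50,000 projection steps with a kernel drawn uniformly
   at random per step; transient 22-year projections with integer rounding
   give extinction probabilities; parametric bootstrap of all regression
   coefficients and year deviations propagates uncertainty.
5. **Genetics link.** Pearson correlations (after ln/logit transforms)
   between demographic outcomes and heterozygosity / inbreeding
   coefficients, with an exact small-sample power analysis: at n = 5
   populations, detecting a correlation with power 0.75 at α = 0.05
   requires |r| > 0.94.

A synthetic-data generator (`simParams()`, `simulateCensus()`) produces
censuses with known ground truth — including dormancy emitted as apparent
deaths — so the whole pipeline is testable end to end.

## Worked example

```r
library(ipmviability)

# simulate an 8-census study of one population, clean and summarize it
sim   <- simulateCensus(simParams(initial_n = 1000), seed = 11)
clean <- cleanCensus(sim$records)
cs <- summarizeCohort(clean)
cs[c("n_plants", "n_reincarnates", "n_bolters")]
#> $n_plants
#> [1] 1027
#> $n_reincarnates
#> [1] 29
#> $n_bolters
#> [1] 70

# fit all vital rates, build kernels, project with bootstrap uncertainty
# from the final-census population size (12 plants left after 8 years)
rates <- fitPopulationRates(clean)
mesh  <- buildMesh(rates$max_size, 100)
cfg   <- runConfig(n_steps = 2000, n_bootstrap = 100,
                   n_trajectories = 200, horizon_years = 22, seed = 99)
projectPopulation(rates, mesh, n0 = 12, cfg)
#> Projection summary for population P1
#>   lambda_S median 0.728 (95% CI 0.509-0.858) over 100 bootstraps
#>   Pr(extinction) mean 0.473 (95% CI 0.000-1.000)
#>   predicted final N mean 0.60, median 0.53 (95% CI 0.00-1.87)
```

This census realization crashed from 1000 to 12 plants over eight years;
the fitted model predicts continued decline (λ_S well below 1) and a coin-
flip 22-year extinction risk, with intervals wide enough to show how much
parameter uncertainty such a census leaves.

Correlating published demographic outcomes with the packaged genetics
table:

```r
res <- runPipeline(fixture_mode = TRUE)
subset(res$correlations, genetic == "H_O" & demographic == "lambda_s")
#>   genetic demographic subset ...     r      p n
#>       H_O    lambda_s    all ... 0.815 0.0931 5
#>       H_O    lambda_s   East ... 0.863 0.1375 4
```

More genetically diverse populations have higher long-run growth rates,
but with five populations the relationship is at best marginal — exactly
what `criticalRForPower(5, 0.75, 0.05)` (≈ 0.94) predicts.

## Layout

```
R/                  census cleaning, simulator, vital rates, kernels,
                    projection, genetics, pipeline
inst/extdata/       packaged genetics / demography / recensus summary tables
tests/testthat/     unit, property and acceptance suites
vignettes/          methods vignette (model, assumptions, numerical choices)
scripts/            acceptance script
```
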