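# patchfr

Functional responses and predator–prey coexistence across patch sizes and
refuge availabilities.

Measuring how a predator's feeding rate depends on prey density (the
*functional response*) across wide gradients of habitat size and
complexity is practically impossible in the laboratory: a single response
curve takes dozens of trials, and a ten-fold larger arena needs ten times
the prey. `patchfr` runs those experiments *in silico*. It is aimed at
food-web and community ecologists who want a mechanistic, trait-based
bridge from individual feeding behaviour to population-level coexistence
predictions.

The package chains three layers:

1. **Individual-based feeding trials.** One predator forages on a square
   grid of 1 cm² cells with impenetrable walls; a chosen fraction of
   cells are prey refuges where no feeding can occur. Movement speed, gut
   capacity, digestion, handling time and attack success all follow
   empirical allometric rules (100 mg predator, 1 mg prey by default).
   Eaten prey are replaced immediately, keeping density constant.
2. **Functional-response fitting.** Feeding counts are modelled with
   Real's response
   `f(N) = fmax N^h / (N0^h + N^h)`,
   with the maximum feeding rate `fmax` fixed at its physiological
   ceiling (intercept-only Poisson GLM on non-spatial trials), and the
   half-saturation density `N0` and Hill exponent `h` depending on patch
   area `A` and refuge availability `R` through ln-linear predictors
   (`ln N0 ~ ln A + R`, `ln h ~ ln A + ln R`, interactions optional).
   Estimation is negative-binomial maximum likelihood; the dependency
   structure is chosen by BIC over the 25 admissible term sets (plus a
   16-model screen of power-law vs exponential forms).
3. **Population dynamics.** The fitted interaction enters an allometric
   Rosenzweig–MacArthur model with analytic isoclines and an extinction
   boundary of **two individuals per patch**, mapping predator–prey
   coexistence over patch size × refuge availability.

## Worked example

```r
library(patchfr)
set.seed(1)

# physiological ceiling: 50 non-spatial maximum-feeding trials
counts <- max_feeding_counts(50)
mf <- fit_max_feeding(counts)
mean(counts); mf$ln_fmax
#> [1] 7
#> [1] 1.945910

# reduced factorial in-silico experiment (five patch sizes, 8 refuge
# levels, ~2300 trials, about 1.5 min)
trials <- run_experiment(c(0.04, 0.16, 0.64, 1.44, 2.56),
                         seq(0.05, 0.75, by = 0.10),
                         reps = 5, fmax_mean = mean(counts), seed = 101)

# functional response with habitat-dependent half saturation
fit <- fr_fit(trials, scaling_spec(area = TRUE, refuge = TRUE),
              scaling_spec(), ln_fmax = mf$ln_fmax)
summary(fit)
#> Coefficients:
#>              Estimate Std. Error z value Pr(>|z|)
#> n0.intercept  4.75857    0.06528  72.894  < 2e-16 ***
#> n0.area       0.01222    0.01993   0.613     0.54
#> n0.refuge     1.63922    0.13141  12.474  < 2e-16 ***
#> h.intercept   0.15104    0.02494   6.057 1.39e-09 ***

hill_test(fit)$h
#> [1] 1.163038
```

The half-saturation density rises steeply with refuge availability
(`exp(1.64)` ≈ 5-fold from no refuge to full refuge cover) but is
unaffected by patch size; the Hill exponent is significantly above 1, a
sigmoid type III response that emerges purely from refuge geometry. The
BIC winner among all 25 scaling structures (`select_scaling_model(trials,
mf$ln_fmax)`) keeps only the refuge term and a habitat-free Hill
exponent.

Feeding the fit into the population layer:

```r
m <- coexistence_map(fit, areas = c(0.04, 0.64, 4, 36, 100),
                     refuge_fractions = seq(0.05, 0.75, 0.1))
subset(m, area_m2 == 36)[, c("refuge_fraction", "status", "N_star", "P_star")]
#>    refuge_fraction      status    N_star    P_star
#> 4             0.05 coexistence 0.1315868 0.1072366
#> 9             0.15 coexistence 0.1550248 0.1263361
#> 14            0.25 coexistence 0.1826376 0.1488369
#> 19            0.35 coexistence 0.2151686 0.1753448
#> 24            0.45 coexistence 0.2534941 0.2065733
#> 29            0.55 coexistence 0.2986460 0.2433627
#> 34            0.65 coexistence 0.3518403 0.2867030
#> 39            0.75 coexistence 0.4145094 0.3377602

table(m$status)
#>      coexistence predator_extinct
#>               16               24
```

Small patches cannot sustain the predator (its equilibrium density falls
below two individuals per patch); refuge availability *rescues* it by
raising the equilibrium prey density, moving the survival frontier to
smaller patches. `run_all(default_config("desk"))` runs the whole
pipeline and writes the trial table, model-selection table and
coexistence map as CSV.

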